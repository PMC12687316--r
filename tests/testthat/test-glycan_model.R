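test_that("composition strings parse to total counts including the core", {
  b11 <- parse_composition("(Hex)2 (HexNAc)2 (Deoxyhexose)1 (NeuAc)4 + (Man)3(GlcNAc)2")
  expect_equal(unname(b11$counts[c("Hex", "HexNAc", "Deoxyhexose", "NeuAc")]),
               c(5L, 4L, 1L, 4L))

  core_only <- parse_composition("+ (Man)3(GlcNAc)2")
  expect_equal(unname(core_only$counts[c("Hex", "HexNAc")]), c(3L, 2L))
  expect_equal(unname(core_only$counts[c("Deoxyhexose", "NeuAc")]), c(0L, 0L))

  man5 <- parse_composition("(Hex)2 + (Man)3(GlcNAc)2")
  expect_equal(unname(man5$counts[c("Hex", "HexNAc")]), c(5L, 2L))
  expect_equal(composition_mass(man5), 5 * 162.05282 + 2 * 203.07937,
               tolerance = 1e-9)

  # whitespace-free core separator is accepted
  expect_equal(parse_composition("(Hex)2+(Man)3(GlcNAc)2")$counts,
               man5$counts)
})

test_that("malformed or unknown composition tokens are rejected with the offender named", {
  expect_error(parse_composition("(Hex)2 (Foo)1"), "Foo")
  expect_error(parse_composition("(Hex)0 + (Man)3(GlcNAc)2"), "positive")
  expect_error(parse_composition("(Hex)2 garbage"), "malformed")
  expect_error(parse_composition(""), "empty")
  expect_error(parse_composition("(Hex)2 + (NeuAc)1"), "NeuAc")
})

test_that("parse and format are mutually inverse on a random composition corpus", {
  set.seed(42)
  for (i in 1:1000) {
    s <- random_comp_string()
    comp <- parse_composition(s)
    expect_identical(format_composition(comp), s)
    reparsed <- parse_composition(format_composition(comp))
    expect_identical(reparsed$counts, comp$counts)
    expect_identical(reparsed$acetyl, comp$acetyl)
    expect_identical(reparsed$core, comp$core)
  }
})

test_that("free-glycan and residue-sum masses follow the monosaccharide table", {
  expect_equal(composition_mass(glycan_composition()), 0)
  man5 <- parse_composition("(Hex)2 + (Man)3(GlcNAc)2")
  expect_equal(composition_mass(man5, as_free_glycan = TRUE), 1234.4334,
               tolerance = 1e-4)
  # one O-acetyl adds 42.0106 Da on any composition
  set.seed(7)
  for (i in 1:50) {
    base <- parse_composition(random_comp_string())
    if (base$counts[["NeuAc"]] <= base$acetyl) next
    plus <- glycan_composition(
      Hex = base$counts[["Hex"]], HexNAc = base$counts[["HexNAc"]],
      Deoxyhexose = base$counts[["Deoxyhexose"]], NeuAc = base$counts[["NeuAc"]],
      acetyl = base$acetyl + 1L,
      core_man = base$core[["Man"]], core_glcnac = base$core[["GlcNAc"]]
    )
    expect_equal(composition_mass(plus) - composition_mass(base), 42.0106,
                 tolerance = 1e-4)
  }
})

test_that("residue-sum mass is additive over composition unions", {
  set.seed(11)
  for (i in 1:100) {
    a <- parse_composition(random_comp_string())
    b <- parse_composition(random_comp_string())
    u <- glycan_composition(
      Hex = a$counts[["Hex"]] + b$counts[["Hex"]],
      HexNAc = a$counts[["HexNAc"]] + b$counts[["HexNAc"]],
      Deoxyhexose = a$counts[["Deoxyhexose"]] + b$counts[["Deoxyhexose"]],
      NeuAc = a$counts[["NeuAc"]] + b$counts[["NeuAc"]],
      acetyl = a$acetyl + b$acetyl
    )
    expect_equal(composition_mass(u), composition_mass(a) + composition_mass(b),
                 tolerance = 1e-9)
  }
})

test_that("glycan classification splits high-mannose from hybrid/complex", {
  man5 <- parse_composition("(Hex)2 + (Man)3(GlcNAc)2")
  cls <- classify_glycan(man5)
  expect_equal(cls$type_label, "high-mannose")
  expect_false(cls$fucosylated)
  expect_false(cls$sialylated)

  b11 <- parse_composition("(Hex)2 (HexNAc)2 (Deoxyhexose)1 (NeuAc)4 + (Man)3(GlcNAc)2")
  cls <- classify_glycan(b11)
  expect_equal(cls$type_label, "hybrid/complex")
  expect_true(cls$fucosylated)
  expect_true(cls$sialylated)

  # the bare core fails the Hex >= 5 bound
  bare <- parse_composition("+ (Man)3(GlcNAc)2")
  expect_equal(classify_glycan(bare)$type_label, "hybrid/complex")

  # totality and flag invariants over random compositions
  set.seed(3)
  for (i in 1:200) {
    comp <- parse_composition(random_comp_string())
    cls <- classify_glycan(comp)
    expect_true(cls$type_label %in% c("high-mannose", "hybrid/complex"))
    expect_identical(cls$fucosylated, comp$counts[["Deoxyhexose"]] >= 1L)
    expect_identical(cls$sialylated, comp$counts[["NeuAc"]] >= 1L)
    if (cls$type_label == "high-mannose") {
      expect_false(cls$fucosylated)
      expect_false(cls$sialylated)
    }
  }
})

test_that("sialic acid units are counted per composition", {
  expect_equal(neuac_count(parse_composition(
    "(Hex)2 (HexNAc)2 (Deoxyhexose)1 (NeuAc)4 + (Man)3(GlcNAc)2")), 4L)
  expect_equal(neuac_count(parse_composition(
    "(Hex)2 (HexNAc)2 (Deoxyhexose)1 (NeuAc)2 + (Man)3(GlcNAc)2")), 2L)
  expect_equal(neuac_count(parse_composition("(Hex)2 + (Man)3(GlcNAc)2")), 0L)
})

test_that("diagnostic oxonium ions reproduce the reported m/z values", {
  expect_equal(diagnostic_ion("neuac_dimer", 0), 583.198, tolerance = 1e-3)
  expect_equal(diagnostic_ion("neuac_dimer", 1), 565.188, tolerance = 1e-3)
  expect_equal(diagnostic_ion("neuac_dimer", 2), 547.177, tolerance = 1e-3)
  expect_equal(diagnostic_ion("acetyl_neuac", 0), 334.113, tolerance = 1e-3)
  expect_equal(diagnostic_ion("acetyl_neuac", 1), 316.103, tolerance = 1e-3)
  expect_equal(diagnostic_ion("neuac", 0), 291.09542 + 1.00728, tolerance = 1e-9)
  expect_error(diagnostic_ion("neuac", 3), "water")
})

test_that("each water loss lowers a diagnostic ion by exactly one water mass", {
  for (kind in c("neuac", "acetyl_neuac", "neuac_dimer")) {
    for (n in 1:2) {
      expect_equal(diagnostic_ion(kind, n - 1L) - diagnostic_ion(kind, n),
                   18.010565, tolerance = 1e-9)
    }
  }
})

test_that("glycan database round-trips through TSV with classes attached", {
  db <- tibble::tibble(
    id = c("A1", "B43"),
    composition = c("(Hex)2 + (Man)3(GlcNAc)2",
                    "(Hex)2 (HexNAc)2 (Deoxyhexose)1 (NeuAc)2 + (Man)3(GlcNAc)2")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(db, path)
  got <- read_glycan_db(path)
  expect_equal(got$id, db$id)
  expect_equal(got$composition, db$composition)
  expect_equal(got$type_label, c("high-mannose", "hybrid/complex"))
  expect_equal(got$neuac, c(0L, 2L))
})
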