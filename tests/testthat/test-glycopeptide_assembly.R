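test_that("peptide and glycopeptide neutral masses follow the residue tables", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-5)
  expect_equal(glycopeptide_neutral_mass("G", glycan_composition()),
               peptide_mass("G"))
  base <- parse_composition("(Hex)2 (HexNAc)2 (NeuAc)2 + (Man)3(GlcNAc)2")
  plus <- parse_composition("(Hex)2 (HexNAc)2 (NeuAc)2 (Acetyl)1 + (Man)3(GlcNAc)2")
  expect_equal(glycopeptide_neutral_mass("AANGTK", plus) -
                 glycopeptide_neutral_mass("AANGTK", base),
               42.0106, tolerance = 1e-4)
  expect_error(peptide_mass("AAZX"), "unknown")
  expect_equal(peptide_mass("C", carbamidomethyl = TRUE) - peptide_mass("C"),
               57.02146, tolerance = 1e-6)
})

.toy_intact <- function() {
  tibble::tibble(
    sample_id = "s1",
    peptide = "AANGTK", protein_id = "P1", site = 5L,
    composition = "(Hex)2 + (Man)3(GlcNAc)2",
    o_acetyl = 0L, neutral_mass = NA_real_, score = c(10, 20)
  )
}

test_that("assembly deduplicates on (sample, backbone, site, composition) keeping best score", {
  asm <- assemble_glycopeptides(.toy_intact(), toy_proteins())
  expect_equal(nrow(asm$records), 1L)
  expect_equal(asm$records$score, 20)
  expect_equal(asm$records$type_label, "high-mannose")
  expect_equal(asm$records$motif, "NXT")
})

test_that("assembly counts glycopeptides, backbones and compositions per sample", {
  rows <- tidyr::crossing(
    peptide = c("AANGTK", "LLPEPTIDENGTK"),
    composition = c("(Hex)2 + (Man)3(GlcNAc)2",
                    "(Hex)2 (HexNAc)2 (NeuAc)2 + (Man)3(GlcNAc)2")
  ) %>%
    dplyr::mutate(sample_id = "s1", protein_id = "P1",
                  site = ifelse(peptide == "AANGTK", 5L, 18L))
  mm <- tibble::tibble(sample_id = "s1", peptide = "MMNGSNGTK",
                       protein_id = "P2", site = 3L,
                       composition = "(Hex)2 + (Man)3(GlcNAc)2")
  asm <- assemble_glycopeptides(dplyr::bind_rows(rows, mm), toy_proteins())
  summ <- glycopeptide_summary(asm$records)
  expect_equal(summ$n_glycopeptides, 5L)  # 3 backbones x 2 comps - 1 not emitted
  expect_equal(summ$n_backbones, 3L)
  expect_equal(summ$n_sites, 3L)
  expect_equal(summ$n_compositions, 2L)
  # invariant chain: sites <= backbones <= glycopeptides
  expect_true(summ$n_sites <= summ$n_backbones)
  expect_true(summ$n_backbones <= summ$n_glycopeptides)
})

test_that("rows with bad compositions or sites are rejected with reasons", {
  bad <- tibble::tibble(
    sample_id = "s1",
    peptide = c("AANGTK", "AANGTK", "AANPTKR", "AANGTK"),
    protein_id = c("P1", "P1", "P1", "P1"),
    site = c(5L, 5L, 24L, 6L),
    composition = c("(Foo)1", "(Hex)2 + (Man)3(GlcNAc)2",
                    "(Hex)2 + (Man)3(GlcNAc)2", "(Hex)2 + (Man)3(GlcNAc)2"),
    o_acetyl = 0L
  )
  asm <- assemble_glycopeptides(bad, toy_proteins())
  expect_equal(nrow(asm$records), 1L)
  expect_equal(nrow(asm$rejected), 3L)
  expect_true(any(grepl("unparseable_composition", asm$rejected$reason)))
  # NPT asparagine and a non-sequon position both fail the canonical test
  expect_equal(sum(asm$rejected$reason == "site_not_canonical_sequon"), 2L)
})

test_that("an acetyl count above the NeuAc count is rejected", {
  row <- .toy_intact()[1, ]
  row$o_acetyl <- 1L  # Man5 has no NeuAc
  asm <- assemble_glycopeptides(row, toy_proteins())
  expect_equal(nrow(asm$records), 0L)
  expect_equal(asm$rejected$reason, "acetyl_count_exceeds_neuac")
})

test_that("neutral-mass validation catches planted 1 Da corruption", {
  bundle <- simulate_glyco_study(simulation_config(seed = 17, n_spectra = 0L))
  intact <- bundle$intact
  set.seed(17)
  corrupt <- sample(nrow(intact), 5L)
  intact$neutral_mass[corrupt] <- intact$neutral_mass[corrupt] + 1.0
  asm <- assemble_glycopeptides(intact, bundle$proteins, validate_mass = TRUE,
                                mass_tol_da = 0.05)
  expect_equal(sum(asm$rejected$reason == "neutral_mass_mismatch"), 5L)
  # without corruption everything validates
  asm_ok <- assemble_glycopeptides(bundle$intact, bundle$proteins,
                                   validate_mass = TRUE, mass_tol_da = 0.05)
  expect_equal(nrow(asm_ok$rejected), 0L)
})

test_that("expected-versus-identified site fractions are percentages of the expected set", {
  expected <- tibble::tibble(sample_id = "s1", protein_id = "P1",
                             position = c(5L, 18L))
  rec_all <- tibble::tibble(sample_id = "s1", protein_id = "P1",
                            site = c(5L, 18L))
  expect_equal(expected_vs_identified(expected, rec_all)$pct_identified, 100)
  rec_half <- rec_all[1, ]
  evi <- expected_vs_identified(expected, rec_half)
  expect_equal(evi$pct_identified, 50)
  expect_equal(evi$n_only_intact, 0L)
  expect_error(expected_vs_identified(expected[0, ], rec_all), "empty")
})

test_that("facet distributions split by toxin class and motif with marginal consistency", {
  ann <- tibble::tibble(protein_id = c("P1", "P2"),
                        toxin_class = c("SVMP", "SVSP"))
  recs <- tibble::tibble(
    sample_id = "s1",
    peptide = c(rep("AANGTK", 2), rep("LLPEPTIDENGTK", 2), rep("MMNGSNGTK", 2)),
    protein_id = c("P1", "P1", "P1", "P1", "P2", "P2"),
    site = c(5L, 5L, 18L, 18L, 3L, 3L),
    motif = c("NXT", "NXT", "NXT", "NXT", "NXS", "NXS"),
    composition = rep(c("(Hex)2 + (Man)3(GlcNAc)2",
                        "(Hex)3 + (Man)3(GlcNAc)2"), 3),
    acetyl = 0L
  )
  by_class <- class_distribution(recs, ann, facet = "toxin_class")
  expect_equal(sort(by_class$n, decreasing = TRUE), c(4L, 2L))
  expect_equal(sum(by_class$n), 6L)
  by_motif <- class_distribution(recs, facet = "motif")
  expect_equal(by_motif$n[by_motif$level == "NXT"], 4L)
  expect_equal(by_motif$n[by_motif$level == "NXS"], 2L)
  # missing annotation falls under "unannotated"
  by_class2 <- class_distribution(recs, ann[1, ], facet = "toxin_class")
  expect_true("unannotated" %in% by_class2$level)
})

test_that("O-acetyl fractions are per-sample percentages", {
  recs <- tibble::tibble(sample_id = "s1", acetyl = c(rep(0L, 8), 1L, 1L))
  expect_equal(o_acetyl_fraction(recs)$pct_acetylated, 20)
  recs0 <- tibble::tibble(sample_id = "s1", acetyl = rep(0L, 10))
  expect_equal(o_acetyl_fraction(recs0)$pct_acetylated, 0)
  expect_error(o_acetyl_fraction(recs0[0, ]), "no records")
})

test_that("acetylation probability is recovered within a binomial interval", {
  bundle <- simulate_glyco_study(simulation_config(seed = 23))
  asm <- assemble_glycopeptides(bundle$intact, bundle$proteins)
  sial <- asm$records[asm$records$sialylated, ]
  p_hat <- mean(sial$acetyl >= 1L)
  n <- nrow(sial)
  se <- sqrt(0.15 * 0.85 / n)
  expect_lt(abs(p_hat - 0.15), 3 * se)
})
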