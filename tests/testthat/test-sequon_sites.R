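test_that("canonical sequon scanning applies the N-X(!=P)-S/T rule", {
  hits <- find_sequons("AANGTK")
  expect_equal(hits$position, 3L)
  expect_equal(hits$motif, "NXT")

  expect_equal(nrow(find_sequons("AANPTK")), 0L)  # X = P excluded

  hits <- find_sequons("NGSNGT")
  expect_equal(hits$position, c(1L, 4L))
  expect_equal(hits$motif, c("NXS", "NXT"))
})

test_that("noncanonical motifs are reported flagged and non-countable", {
  hits <- find_sequons("AANGCAANGVATLNAA", include_noncanonical = TRUE)
  expect_setequal(hits$motif[!hits$canonical], c("NXC", "NXV", "reverse-S/TXN"))
  expect_false(any(hits$canonical))
  # default scan returns none of them
  expect_equal(nrow(find_sequons("AANGCAANGVATLNAA")), 0L)
  # an Asn that is both canonical and reverse-motif is reported once, canonical
  both <- find_sequons("TANGS", include_noncanonical = TRUE)
  expect_equal(sum(both$position == 3L), 1L)
  expect_true(both$canonical[both$position == 3L])
})

test_that("sequon scan agrees with a brute-force window oracle", {
  set.seed(99)
  total <- 0L
  while (total < 2e4) {
    len <- sample(50:300, 1)
    seqn <- paste(sample(c("A", "N", "P", "S", "T", "G", "K", "R", "L"),
                         len, replace = TRUE), collapse = "")
    hits <- find_sequons(seqn)
    expect_identical(hits$position, oracle_sequons(seqn))
    total <- total + len
  }
})

test_that("putative calls require canonical-sequon deamidation in enough replicates", {
  prot <- toy_proteins()
  # AANGTK maps into P1 at start 3 (positions 3..8), deamidated N at local 3 = protein 5
  ids <- dplyr::bind_rows(
    toy_id_row(replicate = 1L, peptide = "AANGTK", deam = "3",
               protein_id = "P1", start = 3L),
    toy_id_row(replicate = 2L, fraction = "dF2", peptide = "AANGTK", deam = "3",
               protein_id = "P1", start = 3L),
    # deamidation on the NPT asparagine (protein 24, local 3), 3 replicates
    toy_id_row(replicate = 1L, peptide = "AANPTKR", deam = "3",
               protein_id = "P1", start = 22L),
    toy_id_row(replicate = 2L, peptide = "AANPTKR", deam = "3",
               protein_id = "P1", start = 22L),
    toy_id_row(replicate = 3L, peptide = "AANPTKR", deam = "3",
               protein_id = "P1", start = 22L),
    # single-replicate deamidated sequon peptide
    toy_id_row(replicate = 1L, peptide = "MMNGSNGTK", deam = "3",
               protein_id = "P2", start = 1L),
    # unmodified background peptide
    toy_id_row(replicate = 1L, peptide = "LLPEPTIDENGTK", deam = "",
               protein_id = "P1", start = 9L)
  )
  res <- suppressWarnings(call_putative_glycopeptides(ids, prot))
  part <- res$partition
  cat_of <- function(pep) part$category[part$peptide == pep]
  expect_equal(cat_of("AANGTK"), "putative_glyco")
  expect_equal(cat_of("AANPTKR"), "deamidated_only")
  expect_equal(cat_of("MMNGSNGTK"), "deamidated_only")
  expect_equal(cat_of("LLPEPTIDENGTK"), "nonmodified")
  expect_equal(part$reason[part$peptide == "MMNGSNGTK"], "insufficient_replicates")
  expect_equal(res$putative$site_position, 5L)
  expect_equal(res$putative$motif, "NXT")
  # partition is exhaustive and disjoint over observed states
  expect_equal(nrow(part), 4L)
})

test_that("sequons truncated by the cleavage boundary are evaluated in protein context", {
  prot <- tibble::tibble(protein_id = "P3", sequence = "AAANGTKKK")
  # peptide ends right at the sequon Asn (position 4); S/T lies beyond it
  ids <- dplyr::bind_rows(
    toy_id_row(replicate = 1L, peptide = "AAAN", deam = "4", protein_id = "P3",
               start = 1L),
    toy_id_row(replicate = 2L, peptide = "AAAN", deam = "4", protein_id = "P3",
               start = 1L)
  )
  res <- call_putative_glycopeptides(ids, prot)
  expect_equal(res$partition$category, "putative_glyco")
  expect_equal(res$putative$site_position, 4L)
})

test_that("raising the replicate threshold never adds putative peptides", {
  set.seed(5)
  bundle <- simulate_glyco_study(simulation_config(seed = 5))
  sets <- lapply(1:4, function(k) {
    res <- call_putative_glycopeptides(bundle$deglyco, bundle$proteins,
                                       min_replicates = k)
    unique(paste(res$putative$sample_id, res$putative$peptide))
  })
  for (k in 2:4) {
    expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  }
})

test_that("unmappable rows are excluded with a reason and a warning", {
  prot <- toy_proteins()
  ids <- dplyr::bind_rows(
    toy_id_row(peptide = "AANGTK", deam = "3", protein_id = "P1", start = 3L),
    toy_id_row(peptide = "WRONGPEP", deam = "", protein_id = "P1", start = 1L),
    toy_id_row(peptide = "AANGTK", deam = "3", protein_id = "NOPE", start = 3L)
  )
  expect_warning(res <- call_putative_glycopeptides(ids, prot), "excluded")
  expect_equal(nrow(res$rejected), 2L)
  expect_setequal(res$rejected$reason,
                  c("peptide_does_not_match_protein", "unknown_protein"))
})

test_that("redundancy collapse removes exact substring peptides at a site", {
  put <- tibble::tibble(
    sample_id = "s1",
    peptide = c("PEPTIDENGTK", "TIDENGTK"),
    protein_id = "P1", site_position = 18L, motif = "NXT"
  )
  col <- collapse_redundancy(put)
  expect_equal(col$representatives$peptide, "PEPTIDENGTK")
  expect_equal(nrow(col$sites), 1L)
  expect_equal(col$sites$n_supporting_peptides, 2L)

  # peptides at different sites are kept apart
  put2 <- tibble::tibble(
    sample_id = "s1", peptide = c("AANGTK", "MMNGSK"),
    protein_id = c("P1", "P2"), site_position = c(5L, 3L),
    motif = c("NXT", "NXS")
  )
  expect_equal(nrow(collapse_redundancy(put2)$sites), 2L)

  # a lone peptide is its own representative
  put3 <- put2[1, ]
  expect_equal(collapse_redundancy(put3)$representatives$peptide, "AANGTK")
})

test_that("collapse matches the all-pairs substring oracle and is idempotent", {
  set.seed(21)
  for (i in 1:25) {
    base <- paste(sample(LETTERS[1:8], sample(8:20, 1), replace = TRUE),
                  collapse = "")
    peps <- unique(vapply(1:8, function(j) {
      a <- sample(1:3, 1); b <- sample(0:3, 1)
      substr(base, a, nchar(base) - b)
    }, character(1)))
    put <- tibble::tibble(sample_id = "s1", peptide = peps, protein_id = "PX",
                          site_position = 1L, motif = "NXT")
    col <- collapse_redundancy(put)
    expect_identical(sort(col$representatives$peptide), oracle_collapse(peps))
    # idempotence
    again <- collapse_redundancy(col$representatives %>%
                                   dplyr::rename(site_position = "site_position"))
    expect_identical(sort(again$representatives$peptide),
                     sort(col$representatives$peptide))
    # order independence
    perm <- put[sample(nrow(put)), ]
    expect_identical(sort(collapse_redundancy(perm)$representatives$peptide),
                     sort(col$representatives$peptide))
  }
})

test_that("site ratio is a percentage and undefined for empty peptide sets", {
  expect_equal(site_ratio(10, 20), 50)
  expect_equal(site_ratio(1, 1), 100)
  expect_error(site_ratio(1, 0), "undefined|empty")
})

test_that("synthetic redundancy reproduces a site/peptide ratio in the reported band", {
  bundle <- simulate_glyco_study(simulation_config(seed = 11, n_spectra = 0L))
  called <- call_putative_glycopeptides(bundle$deglyco, bundle$proteins)
  col <- collapse_redundancy(called$putative)
  ss <- site_peptide_summary(col$sites, called$putative)
  pooled <- 100 * sum(ss$n_sites) / sum(ss$n_peptides)
  expect_gte(pooled, 52)
  expect_lte(pooled, 77)
})

test_that("every called site is a canonical sequon of its protein", {
  bundle <- simulate_glyco_study(simulation_config(seed = 3))
  res <- call_putative_glycopeptides(bundle$deglyco, bundle$proteins)
  col <- collapse_redundancy(res$putative)
  seq_of <- stats::setNames(bundle$proteins$sequence, bundle$proteins$protein_id)
  for (r in seq_len(nrow(col$sites))) {
    s <- col$sites[r, ]
    canon <- find_sequons(seq_of[[s$protein_id]])
    expect_true(s$position %in% canon$position)
  }
})
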