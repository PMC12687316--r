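# Hand-built fixtures and independent brute-force oracles used across tests.

# --- tiny protein set -------------------------------------------------------
toy_proteins <- function() {
  tibble::tibble(
    protein_id = c("P1", "P2"),
    sequence = c(
      "MKAANGTKLLPEPTIDENGTKAANPTKR",  # sequons at 5 (NGT) and 18 (NGT); N24 (NPT) is not one
      "MMNGSNGTKAAAK"                  # sequons at 3 (NGS) and 6 (NGT)
    )
  )
}

toy_id_row <- function(sample_id = "s1", replicate = 1L, fraction = "dF1",
                       peptide, deam = "", protein_id, start,
                       missed_cleavages = 0L) {
  tibble::tibble(sample_id = sample_id, replicate = replicate,
                 fraction = fraction, peptide = peptide,
                 deamidation_sites = deam, protein_id = protein_id,
                 start = start, missed_cleavages = missed_cleavages)
}

# --- independent oracles ----------------------------------------------------

# brute-force sequon scan: explicit window loop, written independently of
# find_sequons' vectorised implementation
oracle_sequons <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  out <- integer(0)
  for (i in seq_along(chars)) {
    if (i + 2 <= length(chars) && chars[i] == "N" && chars[i + 1] != "P" &&
        chars[i + 2] %in% c("S", "T")) {
      out <- c(out, i)
    }
  }
  out
}

# brute-force all-pairs substring collapse within one site group
oracle_collapse <- function(peptides) {
  peptides <- unique(peptides)
  keep <- rep(TRUE, length(peptides))
  for (i in seq_along(peptides)) {
    for (j in seq_along(peptides)) {
      if (i != j && peptides[i] != peptides[j] &&
          grepl(peptides[i], peptides[j], fixed = TRUE)) {
        keep[i] <- FALSE
      }
    }
  }
  sort(peptides[keep])
}

# brute-force co-occurrence counting over (site, unordered pair)
oracle_cooccurrence <- function(site_comps) {
  # site_comps: list mapping site key -> character vector of compositions
  counts <- list()
  for (comps in site_comps) {
    comps <- unique(comps)
    if (length(comps) < 2) next
    for (i in seq_len(length(comps) - 1)) {
      for (j in seq((i + 1), length(comps))) {
        pair <- paste(sort(c(comps[i], comps[j])), collapse = "||")
        counts[[pair]] <- (counts[[pair]] %||% 0L) + 1L
      }
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force exclusive intersections by per-feature membership enumeration
oracle_intersections <- function(feature_sets) {
  feats <- unique(unlist(feature_sets, use.names = FALSE))
  patt <- vapply(feats, function(f) {
    paste(as.integer(vapply(feature_sets, function(s) f %in% s, logical(1))),
          collapse = "")
  }, character(1))
  table(patt)
}

# small random glycan composition string
random_comp_string <- function() {
  hex_extra <- sample(0:3, 1)
  hexnac_extra <- sample(0:3, 1)
  dhex <- sample(0:2, 1)
  neuac <- sample(0:4, 1)
  acetyl <- if (neuac > 0) sample(0:min(2, neuac), 1) else 0
  has_core <- stats::runif(1) < 0.8
  comp <- glycan_composition(
    Hex = hex_extra + if (has_core) 3L else 0L,
    HexNAc = hexnac_extra + if (has_core) 2L else 0L,
    Deoxyhexose = dhex, NeuAc = neuac, acetyl = acetyl,
    core_man = if (has_core) 3L else 0L,
    core_glcnac = if (has_core) 2L else 0L
  )
  # an all-zero composition has no string form; retry
  if (sum(comp$counts) == 0) return(random_comp_string())
  format_composition(comp)
}

zero_noise_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed, occupancy_p = 1, within_group_retention = 1,
                    deamidation_fp_rate = 0, replicate_dropout = 0,
                    missed_cleavage_rate = 0, semitryptic_rate = 0,
                    acetylation_p = 0, ppm_noise = 0, ...)
}
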