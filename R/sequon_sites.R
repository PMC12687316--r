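# N-glycosylation sequon scanning and putative glycopeptide calling from
# deamidation evidence in de-N-glycosylated peptide identification tables.

.TOXIN_CLASSES <- c("SVMP", "SVSP", "LAAO", "CTL", "PLA2", "5'-Nase", "APase",
                    "PDE", "PLB", "HYA", "CRISP", "other")

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of protein sequences; the record identifier (up to
#'   the first whitespace) becomes `protein_id`.
#' @return A tibble with columns `protein_id`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    protein_id = sub("\\s.*$", "", names(aa)),
    sequence   = unname(as.character(aa))
  )
}

#' Write protein sequences to FASTA
#'
#' @param proteins Tibble with `protein_id` and `sequence` columns.
#' @param path Output path.
#' @export
write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$protein_id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read protein annotations
#'
#' Tab-delimited annotation table mapping proteins to toxin classes and,
#' for SVMPs, to structural domains (pro, catalytic, disintegrin, Cys-rich).
#'
#' @param path TSV with columns `protein_id`, `toxin_class` and optionally
#'   `domain`, `start`, `end` (1-based inclusive).
#' @return A tibble.
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, comment = "#")
}

# Canonical sequon test at a single protein position (1-based Asn index).
# Looks past the position into the full protein, so a peptide truncated at the
# Asn is still evaluated against the parent sequence.
.sequon_at <- function(sequence, pos) {
  n <- nchar(sequence)
  if (pos < 1L || pos > n) return(NA_character_)
  if (substr(sequence, pos, pos) != "N") return(NA_character_)
  if (pos + 2L > n) return(NA_character_)
  x <- substr(sequence, pos + 1L, pos + 1L)
  st <- substr(sequence, pos + 2L, pos + 2L)
  if (x == "P") return(NA_character_)
  if (st == "S") return("NXS")
  if (st == "T") return("NXT")
  NA_character_
}

#' Scan a protein sequence for N-glycosylation sequons
#'
#' Canonical sequons are N-X-S/T with X any residue except proline. With
#' `include_noncanonical = TRUE`, N-X-C, N-X-V (same X != P constraint) and the
#' reverse motif S/T-X-N are also reported, flagged as non-countable: they are
#' described glycosylation-site variants but are not counted as putative sites.
#'
#' @param sequence A single amino-acid sequence string.
#' @param include_noncanonical Also report flagged noncanonical motifs.
#' @return A tibble with columns `position` (1-based Asn index), `motif`
#'   (`"NXS"`/`"NXT"` for canonical hits, otherwise the variant label),
#'   `canonical` (logical), sorted by position.
#' @examples
#' find_sequons("AANGTK")
#' @export
find_sequons <- function(sequence, include_noncanonical = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  hits <- tibble::tibble(position = integer(0), motif = character(0),
                         canonical = logical(0))
  if (n >= 3L) {
    idx <- which(chars[seq_len(n - 2L)] == "N" &
                   chars[seq(2L, n - 1L)] != "P" &
                   chars[seq(3L, n)] %in% c("S", "T"))
    if (length(idx) > 0) {
      hits <- tibble::tibble(
        position  = idx,
        motif     = ifelse(chars[idx + 2L] == "S", "NXS", "NXT"),
        canonical = TRUE
      )
    }
    if (include_noncanonical) {
      nc_idx <- which(chars[seq_len(n - 2L)] == "N" &
                        chars[seq(2L, n - 1L)] != "P" &
                        chars[seq(3L, n)] %in% c("C", "V"))
      rev_idx <- which(chars[seq_len(n - 2L)] %in% c("S", "T") &
                         chars[seq(3L, n)] == "N") + 2L
      nc <- tibble::tibble(
        position  = c(nc_idx, rev_idx),
        motif     = c(ifelse(chars[nc_idx + 2L] == "C", "NXC", "NXV"),
                      rep("reverse-S/TXN", length(rev_idx))),
        canonical = FALSE
      )
      # an Asn that is also a canonical sequon is reported once, as canonical
      nc <- nc[!(nc$position %in% hits$position), , drop = FALSE]
      nc <- nc[!duplicated(nc$position), , drop = FALSE]
      hits <- dplyr::bind_rows(hits, nc)
    }
  }
  dplyr::arrange(hits, .data$position)
}

.parse_positions <- function(x) {
  if (is.na(x) || trimws(x) == "") return(integer(0))
  as.integer(strsplit(trimws(x), "[;,]")[[1]])
}

#' Call putative N-glycosylated peptides from deamidation evidence
#'
#' Applies the calling rule for de-N-glycosylated peptide tables: a peptide is
#' a putative (formerly) N-glycosylated peptide when it was identified as
#' deamidated in at least `min_replicates` replicates (fractions pooled) and
#' at least one deamidated Asn falls on a canonical N-X(!=P)-S/T sequon,
#' evaluated in the context of the parent protein sequence so that sequons
#' truncated by the tryptic boundary are still recognised. Deamidated peptides
#' failing the sequon test (including those whose deamidation falls on a
#' noncanonical site variant) are classed `deamidated_only`; peptides without
#' deamidation are `nonmodified`.
#'
#' @param ids Identification tibble with columns `sample_id`, `replicate`,
#'   `fraction`, `peptide`, `deamidation_sites` (peptide-local 1-based Asn
#'   positions, `";"`-separated, `""` for none), `protein_id`, `start`
#'   (1-based peptide start in the protein) and optionally `missed_cleavages`.
#'   A peptide mapping to several proteins has one row per mapping.
#' @param proteins Tibble with `protein_id`, `sequence`.
#' @param min_replicates Minimum number of distinct replicates in which the
#'   deamidated form must be observed (default 2).
#' @return A list with:
#'   \describe{
#'     \item{partition}{one row per (sample, peptide, deamidation state) with
#'       `category` in `putative_glyco` / `deamidated_only` / `nonmodified`,
#'       a `reason` code and `n_replicates`;}
#'     \item{putative}{site-resolved putative rows: `sample_id`, `peptide`,
#'       `protein_id`, `site_position` (protein 1-based Asn), `motif`,
#'       `n_replicates`;}
#'     \item{rejected}{rows that could not be mapped or validated, with reasons.}
#'   }
#' @export
call_putative_glycopeptides <- function(ids, proteins, min_replicates = 2L) {
  req <- c("sample_id", "replicate", "fraction", "peptide", "deamidation_sites",
           "protein_id", "start")
  missing_cols <- setdiff(req, names(ids))
  if (length(missing_cols) > 0) {
    stop("identification table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  seq_of <- stats::setNames(proteins$sequence, proteins$protein_id)

  ids <- tibble::as_tibble(ids)
  ids$.row <- seq_len(nrow(ids))

  # mapping validation
  prot_seq <- unname(seq_of[ids$protein_id])
  mapped <- !is.na(prot_seq) &
    substr(prot_seq, ids$start, ids$start + nchar(ids$peptide) - 1L) == ids$peptide
  rejected <- ids[!mapped, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- ifelse(is.na(seq_of[rejected$protein_id]),
                              "unknown_protein", "peptide_does_not_match_protein")
    warning(sprintf("%d identification row(s) could not be mapped and were excluded",
                    nrow(rejected)), call. = FALSE)
  } else {
    rejected$reason <- character(0)
  }
  ids <- ids[mapped, , drop = FALSE]

  deam_list <- lapply(ids$deamidation_sites, .parse_positions)
  bad_deam <- purrr::map2_lgl(deam_list, ids$peptide, function(pos, pep) {
    length(pos) > 0 && (any(pos < 1L | pos > nchar(pep)) ||
                          any(substring(pep, pos, pos) != "N"))
  })
  if (any(bad_deam)) {
    bd <- ids[bad_deam, , drop = FALSE]
    bd$reason <- "deamidation_position_not_asn"
    rejected <- dplyr::bind_rows(rejected, bd)
    ids <- ids[!bad_deam, , drop = FALSE]
    deam_list <- deam_list[!bad_deam]
  }

  # per-row: protein-context sequon status of each deamidated position
  site_rows <- purrr::pmap_dfr(
    list(ids$.row, ids$sample_id, ids$peptide, ids$protein_id, ids$start,
         deam_list),
    function(row, sample_id, peptide, protein_id, start, dpos) {
      if (length(dpos) == 0) return(NULL)
      prot <- seq_of[[protein_id]]
      motif <- vapply(start + dpos - 1L, function(p) {
        m <- .sequon_at(prot, p)
        if (is.na(m)) "none" else m
      }, character(1))
      tibble::tibble(.row = row, sample_id = sample_id, peptide = peptide,
                     protein_id = protein_id,
                     site_position = start + dpos - 1L, motif = motif)
    }
  )

  if (nrow(site_rows) == 0) {
    site_rows <- tibble::tibble(.row = integer(0), sample_id = character(0),
                                peptide = character(0), protein_id = character(0),
                                site_position = integer(0), motif = character(0))
  }
  canonical_rows <- site_rows[site_rows$motif %in% c("NXS", "NXT"), , drop = FALSE]

  ids$deam_state <- vapply(deam_list, function(p) paste(sort(p), collapse = ";"),
                           character(1))
  ids$is_deamidated <- vapply(deam_list, length, integer(1)) > 0
  ids$has_canonical <- ids$.row %in% canonical_rows$.row

  obs <- ids %>%
    dplyr::group_by(.data$sample_id, .data$peptide, .data$deam_state) %>%
    dplyr::summarise(
      is_deamidated = any(.data$is_deamidated),
      has_canonical = any(.data$has_canonical),
      n_replicates  = dplyr::n_distinct(.data$replicate),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      category = dplyr::case_when(
        !.data$is_deamidated ~ "nonmodified",
        .data$has_canonical & .data$n_replicates >= min_replicates ~ "putative_glyco",
        TRUE ~ "deamidated_only"
      ),
      reason = dplyr::case_when(
        !.data$is_deamidated ~ "no_deamidation",
        .data$has_canonical & .data$n_replicates >= min_replicates ~ "canonical_sequon_deamidated",
        .data$has_canonical ~ "insufficient_replicates",
        TRUE ~ "no_canonical_sequon"
      )
    ) %>%
    dplyr::rename(deamidation_sites = "deam_state") %>%
    dplyr::select(-"is_deamidated")

  putative_keys <- obs[obs$category == "putative_glyco",
                       c("sample_id", "peptide", "n_replicates")]
  putative <- canonical_rows %>%
    dplyr::inner_join(putative_keys, by = c("sample_id", "peptide")) %>%
    dplyr::distinct(.data$sample_id, .data$peptide, .data$protein_id,
                    .data$site_position, .data$motif, .data$n_replicates)

  list(partition = obs, putative = putative,
       rejected = tibble::as_tibble(rejected))
}

#' Collapse redundant putative glycopeptides to nonredundant sites
#'
#' Bottom-up identification yields many peptides of different length covering
#' the same site (missed cleavages, semitryptic forms). Within each
#' (sample, protein, site), a peptide whose sequence is an exact substring of
#' another retained peptide covering the same site is removed; the survivors
#' are the site representatives.
#'
#' @param putative Site-resolved putative tibble as returned by
#'   [call_putative_glycopeptides()] (`$putative`).
#' @return A list with `representatives` (nonredundant peptide rows) and
#'   `sites` (one row per `sample_id`, `protein_id`, `position`, `motif`, with
#'   `n_supporting_peptides`, the number of putative peptides collapsed into
#'   the site).
#' @export
collapse_redundancy <- function(putative) {
  stopifnot(all(c("sample_id", "peptide", "protein_id", "site_position", "motif")
                %in% names(putative)))
  putative <- dplyr::distinct(
    putative, .data$sample_id, .data$peptide, .data$protein_id,
    .data$site_position, .data$motif
  )
  reps <- putative %>%
    dplyr::group_by(.data$sample_id, .data$protein_id, .data$site_position) %>%
    dplyr::group_modify(function(df, key) {
      peps <- unique(df$peptide)
      keep <- vapply(peps, function(p) {
        !any(nchar(peps) > nchar(p) & vapply(peps, grepl, logical(1),
                                             pattern = p, fixed = TRUE) &
               peps != p)
      }, logical(1))
      df[df$peptide %in% peps[keep], , drop = FALSE]
    }) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$sample_id, .data$protein_id, .data$site_position,
                   .data$peptide)
  sites <- putative %>%
    dplyr::group_by(.data$sample_id, .data$protein_id,
                    position = .data$site_position, .data$motif) %>%
    dplyr::summarise(n_supporting_peptides = dplyr::n_distinct(.data$peptide),
                     .groups = "drop") %>%
    dplyr::arrange(.data$sample_id, .data$protein_id, .data$position)
  list(representatives = reps, sites = sites)
}

#' Site-to-peptide ratio
#'
#' Number of nonredundant N-glycosylation sites as a percentage of the number
#' of putative N-glycopeptides; a value well below 100% indicates peptide
#' redundancy (proteoforms, missed cleavages, semitryptic forms).
#'
#' @param n_sites,n_peptides Non-negative counts; `n_peptides` must be > 0.
#' @return Percentage (0-100 scale, possibly above 100 if sites outnumber
#'   peptides across shared mappings).
#' @export
site_ratio <- function(n_sites, n_peptides) {
  if (length(n_peptides) != 1L || n_peptides <= 0) {
    stop("site_ratio is undefined for an empty peptide set", call. = FALSE)
  }
  100 * n_sites / n_peptides
}

#' Per-sample site/peptide ratio summary
#'
#' @param sites Sites tibble from [collapse_redundancy()].
#' @param putative Putative tibble from [call_putative_glycopeptides()].
#' @return A tibble with `sample_id`, `n_sites`, `n_peptides`, `ratio_pct`.
#' @export
site_peptide_summary <- function(sites, putative) {
  pep <- putative %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(n_peptides = dplyr::n_distinct(.data$peptide), .groups = "drop")
  st <- sites %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(n_sites = dplyr::n(), .groups = "drop")
  dplyr::inner_join(st, pep, by = "sample_id") %>%
    dplyr::mutate(ratio_pct = purrr::map2_dbl(.data$n_sites, .data$n_peptides,
                                              site_ratio))
}
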