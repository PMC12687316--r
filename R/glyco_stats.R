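# Site microheterogeneity and glycan distribution statistics.

.facet_levels <- function(records, annotations, grouping) {
  if (grouping == "global") {
    records$group <- "global"
  } else if (grouping == "toxin_class") {
    if (is.null(annotations)) stop("annotations required for toxin_class grouping",
                                   call. = FALSE)
    cls <- dplyr::distinct(annotations, .data$protein_id, .data$toxin_class)
    records <- dplyr::left_join(records, cls, by = "protein_id")
    records$group <- dplyr::coalesce(records$toxin_class, "unannotated")
  } else if (grouping == "svmp_domain") {
    if (is.null(annotations) || !all(c("domain", "start", "end") %in% names(annotations))) {
      stop("domain annotations required for svmp_domain grouping", call. = FALSE)
    }
    dom <- annotations[!is.na(annotations$domain), , drop = FALSE]
    records$group <- purrr::pmap_chr(records[c("protein_id", "site")],
                                     function(protein_id, site) {
      hit <- dom$domain[dom$protein_id == protein_id &
                          dom$start <= site & dom$end >= site]
      if (length(hit) == 0) "unannotated" else hit[1]
    })
  } else {
    stop("unknown grouping: ", grouping, call. = FALSE)
  }
  records
}

#' Site microheterogeneity ratio
#'
#' Ratio of the number of observed N-glycoforms to the number of occupied
#' N-glycosylation sites, per sample and group (toxin class, SVMP domain, or
#' globally). A ratio well above 1 means many different glycans decorate the
#' same sites. The numerator is, by default, the number of unique
#' (site, composition) pairs, which keeps the ratio >= 1; the alternative
#' reading (distinct compositions per group, which can fall below 1) is
#' available via `numerator = "compositions"` and both are carried in the
#' output.
#'
#' @param records Assembled intact records (see [assemble_glycopeptides()]).
#' @param annotations Annotation tibble, required for non-global groupings.
#' @param grouping `"global"`, `"toxin_class"` or `"svmp_domain"`.
#' @param numerator `"glycoforms"` (unique site x composition pairs, default)
#'   or `"compositions"` (distinct compositions in the group).
#' @return A tibble `sample_id`, `group`, `n_glycoforms`, `n_compositions`,
#'   `n_sites`, `ratio`; groups with zero sites are omitted.
#' @export
heterogeneity_ratio <- function(records, annotations = NULL,
                                grouping = c("global", "toxin_class", "svmp_domain"),
                                numerator = c("glycoforms", "compositions")) {
  grouping <- match.arg(grouping)
  numerator <- match.arg(numerator)
  df <- .facet_levels(records, annotations, grouping)
  out <- df %>%
    dplyr::group_by(.data$sample_id, .data$group) %>%
    dplyr::summarise(
      n_glycoforms = dplyr::n_distinct(paste(.data$protein_id, .data$site,
                                             .data$composition)),
      n_compositions = dplyr::n_distinct(.data$composition),
      n_sites = dplyr::n_distinct(paste(.data$protein_id, .data$site)),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_sites > 0)
  out$ratio <- if (numerator == "glycoforms") {
    out$n_glycoforms / out$n_sites
  } else {
    out$n_compositions / out$n_sites
  }
  out
}

#' Sialylation distribution
#'
#' Proportion of glycopeptide identifications per number of sialic acid units
#' on the glycan, binned as 0, 1, 2, 3 and >=4 NeuAc, per sample (and
#' optionally per toxin class). By default only hybrid/complex glycans are
#' counted and, following that restriction, the nonsialylated bin is dropped
#' so the proportions describe the sialylated repertoire.
#'
#' @param records Assembled intact records.
#' @param annotations Annotation tibble for `grouping = "toxin_class"`.
#' @param grouping `"sample"` or `"toxin_class"` (crossed with sample).
#' @param hybrid_complex_only Restrict to hybrid/complex glycans (default TRUE).
#' @param drop_nonsialylated Drop the NeuAc = 0 bin; defaults to the value of
#'   `hybrid_complex_only`.
#' @return A tibble `sample_id`, `group`, `neuac_bin` (factor
#'   `0,1,2,3,>=4`), `n`, `proportion`; proportions sum to 1 within each
#'   (sample, group); empty groups are omitted.
#' @export
sialylation_distribution <- function(records, annotations = NULL,
                                     grouping = c("sample", "toxin_class"),
                                     hybrid_complex_only = TRUE,
                                     drop_nonsialylated = hybrid_complex_only) {
  grouping <- match.arg(grouping)
  df <- if (grouping == "sample") {
    records$group <- "all"
    records
  } else {
    .facet_levels(records, annotations, "toxin_class")
  }
  if (hybrid_complex_only) df <- df[df$type_label == "hybrid/complex", , drop = FALSE]
  if (drop_nonsialylated) df <- df[df$neuac >= 1L, , drop = FALSE]
  bins <- c("0", "1", "2", "3", ">=4")
  df$neuac_bin <- factor(ifelse(df$neuac >= 4L, ">=4", as.character(df$neuac)),
                         levels = bins)
  df %>%
    dplyr::count(.data$sample_id, .data$group, .data$neuac_bin,
                 .drop = FALSE, name = "n") %>%
    dplyr::group_by(.data$sample_id, .data$group) %>%
    dplyr::mutate(total = sum(.data$n)) %>%
    dplyr::filter(.data$total > 0) %>%
    dplyr::mutate(proportion = .data$n / .data$total) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"total")
}

#' Ranked composition frequencies
#'
#' Identification counts per glycan composition, ranked most-frequent first
#' (the tabular equivalent of a composition word cloud). Ties are broken
#' lexicographically by the canonical composition string.
#'
#' @param records Assembled intact records.
#' @param annotations Annotation tibble for `grouping = "toxin_class"`.
#' @param grouping `"sample"` or `"toxin_class"`.
#' @param glycan_db Optional glycan database tibble (from [read_glycan_db()])
#'   used to attach catalogue ids to compositions.
#' @return A tibble `sample_id`, `group`, `composition`, `id` (if resolvable),
#'   `n`, `rank`.
#' @export
composition_frequency <- function(records, annotations = NULL,
                                  grouping = c("sample", "toxin_class"),
                                  glycan_db = NULL) {
  grouping <- match.arg(grouping)
  df <- if (grouping == "sample") {
    records$group <- "all"
    records
  } else {
    .facet_levels(records, annotations, "toxin_class")
  }
  out <- df %>%
    dplyr::count(.data$sample_id, .data$group, .data$composition, name = "n") %>%
    dplyr::arrange(.data$sample_id, .data$group, dplyr::desc(.data$n),
                   .data$composition) %>%
    dplyr::group_by(.data$sample_id, .data$group) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup()
  if (!is.null(glycan_db)) {
    ids <- dplyr::distinct(glycan_db, .data$composition, .data$id)
    out <- dplyr::left_join(out, ids, by = "composition")
  }
  out
}
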