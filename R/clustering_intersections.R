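# Binary feature matrices, hierarchical sample clustering, and exclusive
# (UpSet-style) set intersections.

#' Build a binary sample x feature matrix
#'
#' Three feature kinds mirror the cross-sample comparisons used for venom
#' glyco-phenotyping: `"glycopeptide"` (backbone + canonical composition),
#' `"backbone"` (peptide sequence alone), and `"neutral_mass"` (precursor
#' neutral masses merged across samples by single-linkage within
#' `mass_bin_da`, each merged group one feature). Features present in no
#' sample cannot arise by construction; columns are sorted by feature label.
#'
#' @param records Assembled intact records.
#' @param feature_kind `"glycopeptide"`, `"neutral_mass"` or `"backbone"`.
#' @param mass_bin_da Single-linkage merge tolerance for neutral-mass
#'   features, in Da (default 0.02).
#' @param mass_column Which mass to use for `"neutral_mass"` features:
#'   `"computed_mass"` (default) or `"neutral_mass"` (as reported).
#' @return A binary integer matrix, samples in rows (sorted), features in
#'   columns.
#' @export
build_feature_matrix <- function(records,
                                 feature_kind = c("glycopeptide", "neutral_mass",
                                                  "backbone"),
                                 mass_bin_da = 0.02,
                                 mass_column = "computed_mass") {
  feature_kind <- match.arg(feature_kind)
  if (nrow(records) == 0) stop("no records to build a feature matrix from",
                               call. = FALSE)
  df <- tibble::as_tibble(records)
  if (feature_kind == "glycopeptide") {
    df$feature <- paste0(df$peptide, "|", df$composition)
  } else if (feature_kind == "backbone") {
    df$feature <- df$peptide
  } else {
    masses <- df[[mass_column]]
    if (any(is.na(masses))) stop("missing masses in column ", mass_column,
                                 call. = FALSE)
    grp <- mass_bin_groups(masses, mass_bin_da)
    centers <- tapply(masses, grp, mean)
    df$feature <- sprintf("m%.4f", centers[as.character(grp)])
  }
  samples <- sort(unique(df$sample_id))
  features <- sort(unique(df$feature))
  mat <- matrix(0L, nrow = length(samples), ncol = length(features),
                dimnames = list(samples, features))
  mat[cbind(match(df$sample_id, samples), match(df$feature, features))] <- 1L
  mat
}

#' Single-linkage 1-D mass binning
#'
#' Merges sorted masses into groups wherever consecutive values are within
#' `tol` of each other (single linkage: a chain of close values forms one
#' group).
#'
#' @param masses Numeric vector.
#' @param tol Merge tolerance in Da.
#' @return Integer group index per input mass.
#' @export
mass_bin_groups <- function(masses, tol) {
  o <- order(masses)
  sorted <- masses[o]
  grp_sorted <- cumsum(c(1L, as.integer(diff(sorted) > tol)))
  grp <- integer(length(masses))
  grp[o] <- grp_sorted
  grp
}

#' Hierarchical clustering of samples
#'
#' Complete-linkage agglomeration on Euclidean distances between binary
#' feature rows (for binary vectors the squared Euclidean distance is the
#' number of differing features). Samples are sorted lexicographically before
#' clustering so the result is reproducible regardless of input order.
#'
#' @param mat Binary matrix from [build_feature_matrix()].
#' @param linkage Agglomeration method (default `"complete"`).
#' @param metric Distance metric (default `"euclidean"`).
#' @return An `hclust` object.
#' @export
cluster_samples <- function(mat, linkage = "complete", metric = "euclidean") {
  if (nrow(mat) < 2L) stop("clustering requires >= 2 samples", call. = FALSE)
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  stats::hclust(stats::dist(mat, method = metric), method = linkage)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths derive from the merge heights of the hierarchical
#' clustering.
#'
#' @param hc An `hclust` object.
#' @param path Optional path; when given, the tree is also written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Exclusive set intersections (UpSet semantics)
#'
#' For every nonempty subset of samples, counts the features present in
#' exactly that subset of samples and no other. Counts over all membership
#' patterns sum to the size of the feature union.
#'
#' @param feature_sets Named list of character vectors (features per sample),
#'   or a binary matrix as from [build_feature_matrix()].
#' @return A tibble `members` (sample names joined by `"&"`), `pattern`
#'   (0/1 membership string in sample order), `degree`, `n`, sorted by
#'   descending count; zero-count patterns are omitted.
#' @export
feature_intersections <- function(feature_sets) {
  if (is.matrix(feature_sets)) {
    feature_sets <- apply(feature_sets, 1, function(r) {
      colnames(feature_sets)[r > 0]
    }, simplify = FALSE)
  }
  stopifnot(length(feature_sets) >= 1L, !is.null(names(feature_sets)))
  samples <- names(feature_sets)
  all_features <- unique(unlist(feature_sets, use.names = FALSE))
  if (length(all_features) == 0) {
    return(tibble::tibble(members = character(0), pattern = character(0),
                          degree = integer(0), n = integer(0)))
  }
  membership <- vapply(feature_sets, function(s) all_features %in% s,
                       logical(length(all_features)))
  membership <- matrix(membership, nrow = length(all_features),
                       dimnames = list(all_features, samples))
  pattern <- apply(membership, 1, function(r) paste(as.integer(r), collapse = ""))
  tab <- table(pattern)
  out <- tibble::tibble(
    pattern = names(tab),
    n = as.integer(tab)
  )
  out$members <- vapply(out$pattern, function(p) {
    paste(samples[strsplit(p, "")[[1]] == "1"], collapse = "&")
  }, character(1), USE.NAMES = FALSE)
  out$degree <- vapply(out$pattern, function(p) {
    sum(strsplit(p, "")[[1]] == "1")
  }, integer(1), USE.NAMES = FALSE)
  out <- out[out$degree > 0, , drop = FALSE]
  dplyr::arrange(out[c("members", "pattern", "degree", "n")],
                 dplyr::desc(.data$n), .data$pattern)
}
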