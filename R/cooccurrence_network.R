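# Glycan co-occurrence networks: which compositions decorate the same
# N-glycosylation sites.

#' Glycan co-occurrence edges
#'
#' For every N-glycosylation site, each unordered pair of distinct glycan
#' compositions observed at that site contributes one co-occurrence,
#' regardless of how many glycopeptide records at the site carry the pair
#' (set semantics per site). Pairs seen at fewer than `min_weight` sites are
#' dropped. Sites are keyed by (protein, position); networks are computed per
#' sample unless `pooled = TRUE`.
#'
#' @param records Assembled intact records.
#' @param min_weight Minimum number of sites at which a pair must co-occur
#'   (default 3).
#' @param pooled Pool sites across samples into a single network.
#' @return A list with `edges` (tibble `sample_id`, `comp_a`, `comp_b`,
#'   `weight`, with `comp_a < comp_b` lexicographically) and `nodes`
#'   (compositions incident to retained edges, with glycan class and degree).
#' @export
glycan_cooccurrence <- function(records, min_weight = 3L, pooled = FALSE) {
  df <- tibble::as_tibble(records)
  df$sample_key <- if (pooled) "pooled" else df$sample_id
  site_comps <- df %>%
    dplyr::distinct(.data$sample_key, .data$protein_id, .data$site,
                    .data$composition)
  edges <- site_comps %>%
    dplyr::group_by(.data$sample_key, .data$protein_id, .data$site) %>%
    dplyr::group_modify(function(d, key) {
      comps <- sort(unique(d$composition))
      if (length(comps) < 2L) {
        return(tibble::tibble(comp_a = character(0), comp_b = character(0)))
      }
      pairs <- utils::combn(comps, 2L)
      tibble::tibble(comp_a = pairs[1, ], comp_b = pairs[2, ])
    }) %>%
    dplyr::ungroup() %>%
    dplyr::count(.data$sample_key, .data$comp_a, .data$comp_b, name = "weight") %>%
    dplyr::filter(.data$weight >= min_weight) %>%
    dplyr::rename(sample_id = "sample_key") %>%
    dplyr::arrange(.data$sample_id, dplyr::desc(.data$weight), .data$comp_a,
                   .data$comp_b)
  nodes <- dplyr::bind_rows(
    edges %>% dplyr::select("sample_id", composition = "comp_a"),
    edges %>% dplyr::select("sample_id", composition = "comp_b")
  ) %>%
    dplyr::count(.data$sample_id, .data$composition, name = "degree")
  if (nrow(nodes) > 0) {
    cls <- purrr::map(nodes$composition, ~ classify_glycan(parse_composition(.x)))
    nodes$type_label <- purrr::map_chr(cls, "type_label")
    nodes$fucosylated <- purrr::map_lgl(cls, "fucosylated")
    nodes$sialylated <- purrr::map_lgl(cls, "sialylated")
  } else {
    nodes$type_label <- character(0)
    nodes$fucosylated <- logical(0)
    nodes$sialylated <- logical(0)
  }
  list(edges = edges, nodes = nodes)
}

#' Ego network around one composition
#'
#' Subsets a co-occurrence edge list to the edges incident to a chosen
#' composition and annotates each neighbour with its glycan class (the edge
#' colouring used in co-occurrence network figures).
#'
#' @param edges Edge tibble from [glycan_cooccurrence()].
#' @param center Canonical composition string at the centre.
#' @param sample_id Optional sample restriction.
#' @return A tibble `sample_id`, `neighbor`, `weight`, `neighbor_type`,
#'   `neighbor_fucosylated`, `neighbor_sialylated`; empty when the centre is
#'   absent from the node set.
#' @export
ego_network <- function(edges, center, sample_id = NULL) {
  df <- edges
  if (!is.null(sample_id)) df <- df[df$sample_id %in% sample_id, , drop = FALSE]
  inc <- df[df$comp_a == center | df$comp_b == center, , drop = FALSE]
  if (nrow(inc) == 0) {
    return(tibble::tibble(sample_id = character(0), neighbor = character(0),
                          weight = integer(0), neighbor_type = character(0),
                          neighbor_fucosylated = logical(0),
                          neighbor_sialylated = logical(0)))
  }
  inc$neighbor <- ifelse(inc$comp_a == center, inc$comp_b, inc$comp_a)
  cls <- purrr::map(inc$neighbor, ~ classify_glycan(parse_composition(.x)))
  tibble::tibble(
    sample_id = inc$sample_id,
    neighbor = inc$neighbor,
    weight = inc$weight,
    neighbor_type = purrr::map_chr(cls, "type_label"),
    neighbor_fucosylated = purrr::map_lgl(cls, "fucosylated"),
    neighbor_sialylated = purrr::map_lgl(cls, "sialylated")
  )
}
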