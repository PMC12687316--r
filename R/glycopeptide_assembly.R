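# Assembly of intact N-glycopeptide records: backbone + site + glycan
# composition, with neutral-mass bookkeeping and the occupancy and
# distribution summaries computed from them.

# Standard amino-acid monoisotopic residue masses (Da).
.AA_RESIDUES <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,  V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
.MASS_CARBAMIDOMETHYL <- 57.02146

#' Monoisotopic mass of a peptide
#'
#' Residue-sum plus one water. Optional fixed carbamidomethylation adds
#' 57.02146 Da per cysteine (the standard alkylation applied during sample
#' preparation).
#'
#' @param sequence Peptide sequence (canonical one-letter amino acids).
#' @param carbamidomethyl Apply fixed Cys carbamidomethylation.
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mass("G")  # 75.03203
#' @export
peptide_mass <- function(sequence, carbamidomethyl = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  chars <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(chars, names(.AA_RESIDUES))
  if (length(unknown) > 0) {
    stop("unknown amino-acid residue: ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  }
  m <- sum(.AA_RESIDUES[chars]) + .MASS_WATER
  if (carbamidomethyl) m <- m + sum(chars == "C") * .MASS_CARBAMIDOMETHYL
  unname(m)
}

#' Neutral monoisotopic mass of an intact glycopeptide
#'
#' Peptide monoisotopic mass plus the glycan residue-sum mass (which includes
#' any O-acetyl increments). The glycan contributes its residue-sum because the
#' glycosidic bond to Asn condenses out the water the free glycan would carry.
#'
#' @param backbone Peptide backbone sequence.
#' @param comp A `glycan_composition` (may be empty for a bare peptide).
#' @param carbamidomethyl Apply fixed Cys carbamidomethylation to the backbone.
#' @return Neutral mass in Da.
#' @export
glycopeptide_neutral_mass <- function(backbone, comp,
                                      carbamidomethyl = FALSE) {
  peptide_mass(backbone, carbamidomethyl = carbamidomethyl) +
    composition_mass(comp, as_free_glycan = FALSE)
}

#' Assemble intact glycopeptide records
#'
#' Joins an intact glycopeptide identification table against the protein set
#' and the glycan composition grammar: parses and canonicalises composition
#' strings, verifies that the reported site is a canonical sequon of the
#' mapped protein covered by the backbone, deduplicates on
#' (sample, backbone, site, composition, acetyl) keeping the best search
#' score, and optionally validates the reported neutral mass against the
#' computed backbone + glycan mass.
#'
#' @param intact Tibble with columns `sample_id`, `peptide` (backbone),
#'   `protein_id`, `site` (protein 1-based Asn position), `composition`
#'   (composition string), `o_acetyl` (count, optional, default 0),
#'   `neutral_mass` (Da, optional), `score` (optional).
#' @param proteins Tibble with `protein_id`, `sequence`.
#' @param validate_mass If `TRUE`, rows whose reported neutral mass deviates
#'   from the computed mass by more than `mass_tol_da` are rejected.
#' @param mass_tol_da Neutral-mass validation tolerance in Da.
#' @param carbamidomethyl Fixed Cys modification assumed when validating mass.
#' @return A list with `records` (deduplicated tibble with canonical
#'   `composition`, `acetyl`, `type_label`, `fucosylated`, `sialylated`,
#'   `neuac`, `computed_mass`) and `rejected` (rows with `reason`).
#' @export
assemble_glycopeptides <- function(intact, proteins, validate_mass = FALSE,
                                   mass_tol_da = 0.05, carbamidomethyl = FALSE) {
  req <- c("sample_id", "peptide", "protein_id", "site", "composition")
  missing_cols <- setdiff(req, names(intact))
  if (length(missing_cols) > 0) {
    stop("intact table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  intact <- tibble::as_tibble(intact)
  if (!"o_acetyl" %in% names(intact)) intact$o_acetyl <- 0L
  intact$o_acetyl[is.na(intact$o_acetyl)] <- 0L
  if (!"score" %in% names(intact)) intact$score <- NA_real_
  if (!"neutral_mass" %in% names(intact)) intact$neutral_mass <- NA_real_
  seq_of <- stats::setNames(proteins$sequence, proteins$protein_id)

  # parse each distinct composition string once
  uniq <- unique(intact$composition)
  parsed <- lapply(uniq, function(s) tryCatch(parse_composition(s),
                                              error = function(e) e))
  names(parsed) <- uniq

  rows <- purrr::pmap_dfr(
    intact[c("sample_id", "peptide", "protein_id", "site", "composition",
             "o_acetyl", "neutral_mass", "score")],
    function(sample_id, peptide, protein_id, site, composition, o_acetyl,
             neutral_mass, score) {
      out <- tibble::tibble(
        sample_id = sample_id, peptide = peptide, protein_id = protein_id,
        site = as.integer(site), composition_in = composition,
        o_acetyl = as.integer(o_acetyl), neutral_mass = neutral_mass,
        score = score, reason = NA_character_, composition = NA_character_,
        type_label = NA_character_, fucosylated = NA, sialylated = NA,
        neuac = NA_integer_, computed_mass = NA_real_,
        acetyl = NA_integer_, motif = NA_character_
      )
      comp <- parsed[[composition]]
      if (inherits(comp, "error")) {
        out$reason <- paste0("unparseable_composition: ", conditionMessage(comp))
        return(out)
      }
      if (o_acetyl > 0) {
        comp <- tryCatch(
          new_glycan_composition(comp$counts, acetyl = comp$acetyl + as.integer(o_acetyl),
                                 core = comp$core, id = comp$id) |>
            validate_glycan_composition(),
          error = function(e) e
        )
        if (inherits(comp, "error")) {
          out$reason <- "acetyl_count_exceeds_neuac"
          return(out)
        }
      }
      prot <- seq_of[[protein_id]]
      if (is.null(prot)) {
        out$reason <- "unknown_protein"
        return(out)
      }
      start <- as.integer(regexpr(peptide, prot, fixed = TRUE))
      if (start < 1L) {
        out$reason <- "peptide_not_in_protein"
        return(out)
      }
      # the backbone must cover the site; the site must be a canonical sequon
      covered <- FALSE
      while (start >= 1L) {
        if (site >= start && site <= start + nchar(peptide) - 1L) {
          covered <- TRUE
          break
        }
        nxt <- regexpr(peptide, substr(prot, start + 1L, nchar(prot)), fixed = TRUE)
        start <- if (nxt < 1L) -1L else start + as.integer(nxt)
      }
      if (!covered) {
        out$reason <- "site_not_covered_by_backbone"
        return(out)
      }
      motif <- .sequon_at(prot, site)
      if (is.na(motif)) {
        out$reason <- "site_not_canonical_sequon"
        return(out)
      }
      cls <- classify_glycan(comp)
      out$composition <- format_composition(comp)
      out$type_label <- cls$type_label
      out$fucosylated <- cls$fucosylated
      out$sialylated <- cls$sialylated
      out$neuac <- neuac_count(comp)
      out$acetyl <- comp$acetyl
      out$motif <- motif
      out$computed_mass <- glycopeptide_neutral_mass(peptide, comp)
      out
    }
  )

  if (validate_mass) {
    bad_mass <- !is.na(rows$neutral_mass) & is.na(rows$reason) &
      abs(rows$neutral_mass - rows$computed_mass) > mass_tol_da
    rows$reason[bad_mass] <- "neutral_mass_mismatch"
  }

  rejected <- rows[!is.na(rows$reason), , drop = FALSE]
  records <- rows[is.na(rows$reason), , drop = FALSE] %>%
    dplyr::group_by(.data$sample_id, .data$peptide, .data$protein_id,
                    .data$site, .data$composition) %>%
    dplyr::arrange(dplyr::desc(.data$score), .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup() %>%
    dplyr::select("sample_id", "peptide", "protein_id", "site", "motif",
                  "composition", "acetyl", "type_label", "fucosylated",
                  "sialylated", "neuac", "neutral_mass", "computed_mass",
                  "score")
  list(records = records,
       rejected = dplyr::select(rejected, -"composition") %>%
         dplyr::rename(composition = "composition_in"))
}

#' Per-sample glycopeptide tallies
#'
#' The counting unit for "N-glycopeptide" is a unique (backbone, composition)
#' pair per sample; backbones, occupied sites and distinct compositions are
#' tallied alongside. Whether O-acetyl variants of the same composition count
#' as distinct compositions is controlled by `acetyl_distinct` (both readings
#' are reported).
#'
#' @param records Assembled records from [assemble_glycopeptides()].
#' @param acetyl_distinct Count acetyl variants as distinct compositions in
#'   `n_compositions` (the alternative is always reported as
#'   `n_compositions_ignoring_acetyl`).
#' @return A tibble with one row per sample: `n_glycopeptides`, `n_backbones`,
#'   `n_sites`, `n_compositions`, `n_compositions_ignoring_acetyl`.
#' @export
glycopeptide_summary <- function(records, acetyl_distinct = TRUE) {
  records %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(
      n_glycopeptides = dplyr::n_distinct(paste(.data$peptide, .data$composition,
                                                .data$acetyl)),
      n_backbones = dplyr::n_distinct(.data$peptide),
      n_sites = dplyr::n_distinct(paste(.data$protein_id, .data$site)),
      n_compositions = if (acetyl_distinct) {
        dplyr::n_distinct(paste(.data$composition, .data$acetyl))
      } else {
        dplyr::n_distinct(.data$composition)
      },
      n_compositions_ignoring_acetyl = dplyr::n_distinct(
        sub(" \\(Acetyl\\)[0-9]+", "", .data$composition)),
      .groups = "drop"
    )
}

#' Expected versus identified N-glycosylation sites
#'
#' Compares the sites expected from the de-N-glycosylated analysis with the
#' sites actually identified in intact glycopeptide records, per sample.
#'
#' @param expected_sites Tibble with `sample_id`, `protein_id`, `position`
#'   (sites from [collapse_redundancy()]).
#' @param records Assembled intact records.
#' @return A tibble per sample: `n_expected`, `n_identified_of_expected`,
#'   `pct_identified`, `n_only_intact` (sites seen only in the intact
#'   analysis).
#' @export
expected_vs_identified <- function(expected_sites, records) {
  if (nrow(expected_sites) == 0) {
    stop("expected site set is empty; the comparison is undefined", call. = FALSE)
  }
  exp_keys <- expected_sites %>%
    dplyr::transmute(.data$sample_id,
                     key = paste(.data$protein_id, .data$position))
  id_keys <- records %>%
    dplyr::distinct(.data$sample_id, .data$protein_id, .data$site) %>%
    dplyr::transmute(.data$sample_id, key = paste(.data$protein_id, .data$site))
  samples <- unique(exp_keys$sample_id)
  purrr::map_dfr(samples, function(s) {
    e <- unique(exp_keys$key[exp_keys$sample_id == s])
    i <- unique(id_keys$key[id_keys$sample_id == s])
    if (length(e) == 0) {
      stop(sprintf("expected site set is empty for sample '%s'", s), call. = FALSE)
    }
    tibble::tibble(
      sample_id = s,
      n_expected = length(e),
      n_identified_of_expected = length(intersect(e, i)),
      pct_identified = 100 * length(intersect(e, i)) / length(e),
      n_only_intact = length(setdiff(i, e))
    )
  })
}

#' Facetted glycopeptide/site counts
#'
#' Contingency counts of glycopeptides (or occupied sites) per toxin class,
#' SVMP structural domain, or sequon motif, per sample. Records whose facet
#' annotation is missing are counted under `"unannotated"`.
#'
#' @param records Assembled intact records.
#' @param annotations Annotation tibble (`protein_id`, `toxin_class`, and for
#'   the domain facet `domain`, `start`, `end`). Not needed for the motif
#'   facet.
#' @param facet One of `"toxin_class"`, `"svmp_domain"`, `"motif"`.
#' @param unit Count unique glycopeptides (`"glycopeptide"`) or unique
#'   occupied sites (`"site"`).
#' @return A tibble `sample_id`, `level`, `n`.
#' @export
class_distribution <- function(records, annotations = NULL,
                               facet = c("toxin_class", "svmp_domain", "motif"),
                               unit = c("glycopeptide", "site")) {
  facet <- match.arg(facet)
  unit <- match.arg(unit)
  df <- records
  if (facet == "toxin_class") {
    if (is.null(annotations)) stop("annotations required for toxin_class facet",
                                   call. = FALSE)
    cls <- dplyr::distinct(annotations, .data$protein_id, .data$toxin_class)
    df <- dplyr::left_join(df, cls, by = "protein_id") %>%
      dplyr::mutate(level = dplyr::coalesce(.data$toxin_class, "unannotated"))
  } else if (facet == "svmp_domain") {
    if (is.null(annotations) || !all(c("domain", "start", "end") %in% names(annotations))) {
      stop("domain annotations (domain, start, end) required for svmp_domain facet",
           call. = FALSE)
    }
    dom <- annotations[!is.na(annotations$domain), , drop = FALSE]
    df$level <- purrr::pmap_chr(df[c("protein_id", "site")], function(protein_id, site) {
      hit <- dom$domain[dom$protein_id == protein_id &
                          dom$start <= site & dom$end >= site]
      if (length(hit) == 0) "unannotated" else hit[1]
    })
  } else {
    df$level <- df$motif
  }
  df %>%
    dplyr::group_by(.data$sample_id, .data$level) %>%
    dplyr::summarise(
      n = if (unit == "glycopeptide") {
        dplyr::n_distinct(paste(.data$peptide, .data$composition, .data$acetyl))
      } else {
        dplyr::n_distinct(paste(.data$protein_id, .data$site))
      },
      .groups = "drop"
    )
}

#' Per-sample O-acetylated glycan fraction
#'
#' Percentage of glycopeptide records whose composition carries at least one
#' O-acetyl group on a sialic acid.
#'
#' @param records Assembled intact records.
#' @return A tibble `sample_id`, `n_records`, `n_acetylated`, `pct_acetylated`.
#' @export
o_acetyl_fraction <- function(records) {
  if (nrow(records) == 0) stop("no records; O-acetyl fraction undefined",
                               call. = FALSE)
  records %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(
      n_records = dplyr::n(),
      n_acetylated = sum(.data$acetyl >= 1L),
      pct_acetylated = 100 * .data$n_acetylated / .data$n_records,
      .groups = "drop"
    )
}
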