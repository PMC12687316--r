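# Monoisotopic residue masses and physical constants.
# Residue masses are for the dehydrated residue as incorporated in a chain;
# a free molecule adds one water.
.MONOSACCHARIDES <- c(
  Hex         = 162.05282,
  HexNAc      = 203.07937,
  Deoxyhexose = 146.05791,
  NeuAc       = 291.09542
)
.MASS_WATER       <- 18.010565
.MASS_PROTON      <- 1.00728
.MASS_ACETYL      <- 42.010565   # C2H2O, the O-acetyl increment on NeuAc
.MASS_DEAMIDATION <- 0.984016    # Asn -> Asp after glycan release

# Canonical N-glycan core appended as "+ (Man)3(GlcNAc)2" in composition strings.
.GLYCAN_CORE <- c(Man = 3L, GlcNAc = 2L)

.SYMBOL_ORDER <- c("Hex", "HexNAc", "Deoxyhexose", "NeuAc")

#' Monosaccharide residue masses and mass constants
#'
#' Monoisotopic residue masses (Da) used throughout the package, together with
#' the water, proton, O-acetyl and deamidation mass constants.
#'
#' @return A list with elements `residues` (named numeric vector: Hex, HexNAc,
#'   Deoxyhexose, NeuAc), `water`, `proton`, `acetyl` and `deamidation`.
#' @examples
#' monosaccharide_masses()$residues[["NeuAc"]]
#' @export
monosaccharide_masses <- function() {
  list(
    residues    = .MONOSACCHARIDES,
    water       = .MASS_WATER,
    proton      = .MASS_PROTON,
    acetyl      = .MASS_ACETYL,
    deamidation = .MASS_DEAMIDATION
  )
}

#' Construct a glycan composition from counts
#'
#' Programmatic constructor; counts are totals including the core segment.
#' An all-zero composition is allowed (e.g. a bare peptide with no glycan).
#'
#' @param Hex,HexNAc,Deoxyhexose,NeuAc Total monosaccharide counts.
#' @param acetyl Number of O-acetyl groups (must not exceed `NeuAc`).
#' @param core_man,core_glcnac Core segment counts, folded into the Hex and
#'   HexNAc totals respectively.
#' @param id Optional composition identifier.
#' @return A `glycan_composition` object.
#' @export
glycan_composition <- function(Hex = 0L, HexNAc = 0L, Deoxyhexose = 0L, NeuAc = 0L,
                               acetyl = 0L, core_man = 0L, core_glcnac = 0L,
                               id = NA_character_) {
  validate_glycan_composition(new_glycan_composition(
    c(Hex = Hex, HexNAc = HexNAc, Deoxyhexose = Deoxyhexose, NeuAc = NeuAc),
    acetyl = acetyl, core = c(Man = core_man, GlcNAc = core_glcnac), id = id
  ))
}

new_glycan_composition <- function(counts, acetyl = 0L, core = c(Man = 0L, GlcNAc = 0L),
                                   id = NA_character_) {
  cnt <- stats::setNames(integer(length(.SYMBOL_ORDER)), .SYMBOL_ORDER)
  cnt[names(counts)] <- as.integer(counts)
  core_full <- c(Man = 0L, GlcNAc = 0L)
  core_full[names(core)] <- as.integer(core)
  structure(
    list(counts = cnt, acetyl = as.integer(acetyl), core = core_full, id = id),
    class = "glycan_composition"
  )
}

validate_glycan_composition <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  if (any(comp$counts < 0L) || comp$acetyl < 0L || any(comp$core < 0L)) {
    stop("glycan composition counts must be non-negative", call. = FALSE)
  }
  if (comp$counts[["Hex"]] < comp$core[["Man"]]) {
    stop("total Hex must cover the core Man count", call. = FALSE)
  }
  if (comp$counts[["HexNAc"]] < comp$core[["GlcNAc"]]) {
    stop("total HexNAc must cover the core GlcNAc count", call. = FALSE)
  }
  if (comp$acetyl > comp$counts[["NeuAc"]]) {
    stop("acetyl count cannot exceed the NeuAc count", call. = FALSE)
  }
  invisible(comp)
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition> ", format_composition(x), "\n", sep = "")
  if (!is.na(x$id)) cat("  id: ", x$id, "\n", sep = "")
  invisible(x)
}

#' @export
format.glycan_composition <- function(x, ...) format_composition(x)

.tokenize_segment <- function(segment, allowed, context) {
  segment <- trimws(segment)
  if (segment == "") return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("\\(([A-Za-z]+)\\)([0-9]+)", segment, perl = TRUE)[[1]]
  residue <- gsub("\\(([A-Za-z]+)\\)([0-9]+)|[[:space:]]", "", segment)
  if (residue != "") {
    stop(sprintf("malformed composition token near '%s' in %s segment",
                 substr(residue, 1, 20), context), call. = FALSE)
  }
  if (m[1] == -1L) {
    stop(sprintf("no composition tokens found in %s segment", context), call. = FALSE)
  }
  toks <- regmatches(segment, gregexpr("\\(([A-Za-z]+)\\)([0-9]+)", segment, perl = TRUE))[[1]]
  syms <- sub("^\\(([A-Za-z]+)\\).*$", "\\1", toks)
  cnts <- as.integer(sub("^\\([A-Za-z]+\\)([0-9]+)$", "\\1", toks))
  bad <- setdiff(syms, allowed)
  if (length(bad) > 0) {
    stop(sprintf("unknown monosaccharide symbol '%s' in %s segment", bad[1], context),
         call. = FALSE)
  }
  if (any(cnts <= 0L)) {
    zt <- toks[cnts <= 0L][1]
    stop(sprintf("count must be a positive integer in token '%s'", zt), call. = FALSE)
  }
  if (anyDuplicated(syms)) {
    stop(sprintf("duplicated symbol '%s' in %s segment", syms[duplicated(syms)][1], context),
         call. = FALSE)
  }
  stats::setNames(cnts, syms)
}

#' Parse an N-glycan composition string
#'
#' Parses the composition notation used by venom N-glycome catalogues, e.g.
#' `"(Hex)2 (HexNAc)2 (Deoxyhexose)1 (NeuAc)4 + (Man)3(GlcNAc)2"`. The segment
#' after `+` is the conserved N-glycan core; its Man count is folded into the
#' Hex total and its GlcNAc count into the HexNAc total. An optional
#' `(Acetyl)n` token in the antenna segment records n O-acetyl groups on
#' sialic acids (package extension so that acetylated variants round-trip
#' through a single string).
#'
#' @param text A single composition string.
#' @param id Optional composition identifier (e.g. `"A1"`, `"B11"`) attached to
#'   the returned object.
#' @return A `glycan_composition` object with elements `counts` (total counts
#'   including the core), `acetyl`, `core` and `id`.
#' @examples
#' comp <- parse_composition("(Hex)2 (HexNAc)2 (Deoxyhexose)1 (NeuAc)4 + (Man)3(GlcNAc)2")
#' comp$counts
#' @seealso [format_composition()], [composition_mass()], [classify_glycan()]
#' @export
parse_composition <- function(text, id = NA_character_) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("composition must be a single character string", call. = FALSE)
  }
  parts <- strsplit(text, "+", fixed = TRUE)[[1]]
  if (length(parts) > 2L) {
    stop("composition may contain at most one '+' core separator", call. = FALSE)
  }
  main <- if (length(parts) >= 1L) parts[1] else ""
  core_seg <- if (length(parts) == 2L) parts[2] else ""
  if (trimws(main) == "" && trimws(core_seg) == "") {
    stop("empty composition string", call. = FALSE)
  }
  main_counts <- if (trimws(main) == "") {
    stats::setNames(integer(0), character(0))
  } else {
    .tokenize_segment(main, c(.SYMBOL_ORDER, "Acetyl"), "antenna")
  }
  core_counts <- if (trimws(core_seg) == "") {
    c(Man = 0L, GlcNAc = 0L)
  } else {
    got <- .tokenize_segment(core_seg, c("Man", "GlcNAc"), "core")
    full <- c(Man = 0L, GlcNAc = 0L)
    full[names(got)] <- got
    full
  }
  acetyl <- if ("Acetyl" %in% names(main_counts)) main_counts[["Acetyl"]] else 0L
  main_counts <- main_counts[setdiff(names(main_counts), "Acetyl")]
  totals <- stats::setNames(integer(length(.SYMBOL_ORDER)), .SYMBOL_ORDER)
  totals[names(main_counts)] <- main_counts
  totals[["Hex"]] <- totals[["Hex"]] + core_counts[["Man"]]
  totals[["HexNAc"]] <- totals[["HexNAc"]] + core_counts[["GlcNAc"]]
  validate_glycan_composition(
    new_glycan_composition(totals, acetyl = acetyl, core = core_counts, id = id)
  )
}

#' Format a glycan composition as its canonical string
#'
#' Inverse of [parse_composition()]: antenna tokens in fixed symbol order
#' separated by single spaces, an `(Acetyl)n` token when O-acetyl groups are
#' present, and the core appended after `" + "` without internal spaces.
#'
#' @param comp A `glycan_composition`.
#' @return A single string; `parse_composition(format_composition(x))`
#'   reproduces `x`.
#' @export
format_composition <- function(comp) {
  validate_glycan_composition(comp)
  antenna <- comp$counts
  antenna[["Hex"]] <- antenna[["Hex"]] - comp$core[["Man"]]
  antenna[["HexNAc"]] <- antenna[["HexNAc"]] - comp$core[["GlcNAc"]]
  toks <- sprintf("(%s)%d", names(antenna)[antenna > 0], antenna[antenna > 0])
  if (comp$acetyl > 0L) toks <- c(toks, sprintf("(Acetyl)%d", comp$acetyl))
  main <- paste(toks, collapse = " ")
  core <- ""
  if (any(comp$core > 0L)) {
    core_toks <- sprintf("(%s)%d", names(comp$core)[comp$core > 0],
                         comp$core[comp$core > 0])
    core <- paste0("+ ", paste(core_toks, collapse = ""))
  }
  out <- trimws(paste(main, core))
  if (out == "") stop("cannot format an empty composition", call. = FALSE)
  out
}

#' Monoisotopic mass of a glycan composition
#'
#' Residue-sum mass: sum of monosaccharide residue masses plus 42.010565 Da per
#' O-acetyl group. This is the mass the glycan adds to a peptide backbone; the
#' free (released) glycan carries one additional water.
#'
#' @param comp A `glycan_composition`.
#' @param as_free_glycan If `TRUE`, add one water (18.010565 Da) to report the
#'   mass of the free glycan molecule.
#' @return Monoisotopic mass in Da.
#' @examples
#' man5 <- parse_composition("(Hex)2 + (Man)3(GlcNAc)2")
#' composition_mass(man5, as_free_glycan = TRUE)  # 1234.4334
#' @export
composition_mass <- function(comp, as_free_glycan = FALSE) {
  validate_glycan_composition(comp)
  m <- sum(comp$counts * .MONOSACCHARIDES[names(comp$counts)]) +
    comp$acetyl * .MASS_ACETYL
  if (as_free_glycan) m <- m + .MASS_WATER
  unname(m)
}

#' Classify an N-glycan composition
#'
#' Two-way type split used for venom N-glycans: high-mannose (only mannose
#' beyond the Man3GlcNAc2 core: total HexNAc == 2, no deoxyhexose, no NeuAc,
#' total Hex >= 5) versus hybrid/complex (everything else; the two are not
#' separated because composition alone cannot distinguish them). Fucosylation
#' and sialylation flags follow directly from the deoxyhexose and NeuAc counts.
#'
#' @param comp A `glycan_composition`.
#' @return A list with `type_label` (`"high-mannose"` or `"hybrid/complex"`),
#'   `fucosylated` and `sialylated` logicals.
#' @export
classify_glycan <- function(comp) {
  validate_glycan_composition(comp)
  cnt <- comp$counts
  fuc <- cnt[["Deoxyhexose"]] >= 1L
  sia <- cnt[["NeuAc"]] >= 1L
  hm <- cnt[["HexNAc"]] == 2L && !fuc && !sia && cnt[["Hex"]] >= 5L
  list(
    type_label  = if (hm) "high-mannose" else "hybrid/complex",
    fucosylated = fuc,
    sialylated  = sia
  )
}

#' Number of sialic acid units in a composition
#'
#' @param comp A `glycan_composition`.
#' @return Integer NeuAc count (0 for nonsialylated glycans).
#' @export
neuac_count <- function(comp) {
  validate_glycan_composition(comp)
  comp$counts[["NeuAc"]]
}

#' Diagnostic oxonium ion m/z values
#'
#' Singly protonated glycan fragment ions used as MS/MS signatures of antenna
#' structure: the NeuAc oxonium ion, the O-acetyl-NeuAc ion (the 316.103 /
#' 334.113 pair when combined with one water loss), and the sialic acid dimer
#' (NeuAc-NeuAc) ion whose dehydration series is m/z 583, 565 and 547.
#'
#' @param kind One of `"neuac"`, `"acetyl_neuac"`, `"neuac_dimer"`.
#' @param n_water_losses Number of water losses, 0, 1 or 2.
#' @return m/z of the singly protonated fragment.
#' @examples
#' diagnostic_ion("neuac_dimer")          # 583.198
#' diagnostic_ion("acetyl_neuac", 1)      # 316.103
#' @export
diagnostic_ion <- function(kind = c("neuac", "acetyl_neuac", "neuac_dimer"),
                           n_water_losses = 0L) {
  kind <- match.arg(kind)
  if (!n_water_losses %in% 0:2) {
    stop("n_water_losses must be 0, 1 or 2", call. = FALSE)
  }
  neuac <- .MONOSACCHARIDES[["NeuAc"]]
  frag <- switch(kind,
    neuac        = neuac,
    acetyl_neuac = neuac + .MASS_ACETYL,
    neuac_dimer  = 2 * neuac
  )
  frag + .MASS_PROTON - n_water_losses * .MASS_WATER
}

#' Table of standard diagnostic ions
#'
#' The diagnostic ion set scanned for in MS/MS spectra: the NeuAc oxonium ion
#' and its water loss, the O-acetyl-NeuAc pair, and the three-member sialic
#' acid dimer dehydration series.
#'
#' @return A tibble with columns `label`, `kind`, `n_water_losses`, `mz`.
#' @export
diagnostic_ion_table <- function() {
  spec <- tibble::tribble(
    ~label,            ~kind,          ~n_water_losses,
    "NeuAc",           "neuac",        0L,
    "NeuAc-H2O",       "neuac",        1L,
    "NeuAcAc",         "acetyl_neuac", 0L,
    "NeuAcAc-H2O",     "acetyl_neuac", 1L,
    "NeuAc2",          "neuac_dimer",  0L,
    "NeuAc2-H2O",      "neuac_dimer",  1L,
    "NeuAc2-2H2O",     "neuac_dimer",  2L
  )
  spec$mz <- purrr::map2_dbl(spec$kind, spec$n_water_losses, diagnostic_ion)
  spec
}

#' Read a glycan composition database
#'
#' Tab-delimited file with columns `id` and `composition` (composition string
#' grammar of [parse_composition()]) and an optional `class` column.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id`, `composition` (canonicalised),
#'   `type_label`, `fucosylated`, `sialylated`, `neuac`, `residue_mass`.
#' @export
read_glycan_db <- function(path) {
  db <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("id", "composition") %in% names(db))) {
    stop("glycan database must have 'id' and 'composition' columns", call. = FALSE)
  }
  comps <- purrr::map2(db$composition, db$id, parse_composition)
  cls <- purrr::map(comps, classify_glycan)
  tibble::tibble(
    id           = db$id,
    composition  = purrr::map_chr(comps, format_composition),
    type_label   = purrr::map_chr(cls, "type_label"),
    fucosylated  = purrr::map_lgl(cls, "fucosylated"),
    sialylated   = purrr::map_lgl(cls, "sialylated"),
    neuac        = purrr::map_int(comps, neuac_count),
    residue_mass = purrr::map_dbl(comps, composition_mass)
  )
}
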