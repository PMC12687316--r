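# MS/MS peak-list handling and diagnostic oxonium ion annotation.

#' Construct a spectrum object
#'
#' @param spectrum_id Identifier string.
#' @param precursor_mz Precursor m/z.
#' @param charge Precursor charge state.
#' @param mz,intensity Numeric peak vectors of equal length; peaks are stored
#'   sorted by m/z.
#' @return A `glyco_spectrum` object.
#' @export
spectrum <- function(spectrum_id, precursor_mz, charge, mz, intensity) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  o <- order(mz)
  structure(
    list(spectrum_id = spectrum_id, precursor_mz = precursor_mz,
         charge = as.integer(charge),
         peaks = tibble::tibble(mz = mz[o], intensity = intensity[o])),
    class = "glyco_spectrum"
  )
}

#' @export
print.glyco_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s> precursor %.4f (%+d), %d peaks\n",
              x$spectrum_id, x$precursor_mz, x$charge, nrow(x$peaks)))
  invisible(x)
}

#' Read spectra from an MGF peak list
#'
#' Minimal Mascot Generic Format reader: BEGIN IONS / END IONS blocks with
#' TITLE, PEPMASS, CHARGE headers and m/z-intensity peak lines.
#'
#' @param path Path to the MGF file.
#' @return A list of `glyco_spectrum` objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("unbalanced BEGIN/END IONS blocks",
                                           call. = FALSE)
  purrr::map2(begins, ends, function(b, e) {
    block <- lines[(b + 1L):(e - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    title <- if ("TITLE" %in% keys) vals[keys == "TITLE"][1] else NA_character_
    pepmass <- if ("PEPMASS" %in% keys) {
      as.numeric(strsplit(vals[keys == "PEPMASS"][1], "\\s+")[[1]][1])
    } else NA_real_
    charge <- if ("CHARGE" %in% keys) {
      as.integer(sub("\\+$", "", vals[keys == "CHARGE"][1]))
    } else NA_integer_
    pk <- block[!hdr & nzchar(trimws(block))]
    if (length(pk) > 0) {
      mat <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"), as.numeric))
      spectrum(title, pepmass, charge, mat[, 1], mat[, 2])
    } else {
      spectrum(title, pepmass, charge, numeric(0), numeric(0))
    }
  })
}

#' Write spectra to an MGF peak list
#'
#' @param spectra A list of `glyco_spectrum` objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", sp$spectrum_id),
      sprintf("PEPMASS=%.6f", sp$precursor_mz),
      sprintf("CHARGE=%d+", sp$charge),
      sprintf("%.6f %.2f", sp$peaks$mz, sp$peaks$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Match theoretical diagnostic ions against a spectrum
#'
#' For each theoretical ion, reports the peak within `tol_ppm` parts-per-million
#' that is nearest in m/z (ties broken by highest intensity); ions without a
#' peak in tolerance are omitted.
#'
#' @param spec A `glyco_spectrum`.
#' @param ions Tibble with columns `label`, `mz` (see [diagnostic_ion_table()]).
#' @param tol_ppm Match tolerance in ppm (default 10).
#' @param min_intensity Intensity floor below which peaks are ignored.
#' @return A tibble `label`, `theoretical_mz`, `observed_mz`, `ppm_error`,
#'   `intensity`.
#' @export
match_diagnostic_ions <- function(spec, ions, tol_ppm = 10, min_intensity = 0) {
  stopifnot(inherits(spec, "glyco_spectrum"), nrow(ions) > 0)
  peaks <- spec$peaks[spec$peaks$intensity >= min_intensity, , drop = FALSE]
  empty <- tibble::tibble(label = character(0), theoretical_mz = numeric(0),
                          observed_mz = numeric(0), ppm_error = numeric(0),
                          intensity = numeric(0))
  if (nrow(peaks) == 0) return(empty)
  hits <- purrr::pmap_dfr(ions[c("label", "mz")], function(label, mz) {
    ppm <- (peaks$mz - mz) / mz * 1e6
    ok <- abs(ppm) <= tol_ppm
    if (!any(ok)) return(NULL)
    cand <- which(ok)
    best <- cand[order(abs(ppm[cand]), -peaks$intensity[cand])][1]
    tibble::tibble(label = label, theoretical_mz = mz,
                   observed_mz = peaks$mz[best], ppm_error = ppm[best],
                   intensity = peaks$intensity[best])
  })
  if (nrow(hits) == 0) empty else hits
}

#' Flag antenna-structure signatures in a spectrum
#'
#' Tests for the sialic acid dimer dehydration series (m/z 583.198, 565.188,
#' 547.177) and the O-acetyl-NeuAc diagnostic pair (334.113 and its water loss
#' 316.103). By default the dimer call requires all three series members and
#' the acetyl call both pair members.
#'
#' @param spec A `glyco_spectrum`.
#' @param tol_ppm Match tolerance in ppm.
#' @param dimer_min_members Members of the 3-ion dimer series required
#'   (default 3, i.e. the full series).
#' @param min_intensity Intensity floor passed to [match_diagnostic_ions()].
#' @return A list with logicals `dimer_series_present`,
#'   `acetyl_neuac_present`, and the underlying `matches` tibble.
#' @export
flag_antenna_signatures <- function(spec, tol_ppm = 10, dimer_min_members = 3L,
                                    min_intensity = 0) {
  ions <- diagnostic_ion_table()
  matches <- match_diagnostic_ions(spec, ions, tol_ppm = tol_ppm,
                                   min_intensity = min_intensity)
  dimer_labels <- c("NeuAc2", "NeuAc2-H2O", "NeuAc2-2H2O")
  acetyl_labels <- c("NeuAcAc", "NeuAcAc-H2O")
  list(
    dimer_series_present = sum(dimer_labels %in% matches$label) >= dimer_min_members,
    acetyl_neuac_present = all(acetyl_labels %in% matches$label),
    matches = matches
  )
}
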