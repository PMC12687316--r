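# Synthetic multi-venom N-glycoproteomics study generator.
#
# Emulates the data structure of a seven-venom bottom-up study with a known
# ground truth: toxin-class-annotated proteins carrying planted sequons,
# de-N-glycosylated identification tables (3 replicates x 3 fractions) with
# deamidation marks, intact glycopeptide tables with group-structured glycan
# repertoires, a glycan composition database, and MS/MS peak lists carrying
# diagnostic oxonium ions.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
           "Q", "R", "S", "T", "V", "W", "Y")

#' Simulation configuration
#'
#' Defaults describe the emulated study: seven venom samples in three
#' phylogeny-like groups of sizes 3, 2 and 2; each group carries its own
#' hybrid/complex glycan repertoire with two high-mannose compositions
#' (Man5/Man6, catalogue ids A1/A2) shared across groups; every occupied site
#' carries exactly `compositions_per_site` glycans; identification noise
#' (replicate dropout, spurious deamidation, missed/semitryptic cleavage) at
#' rates typical of bottom-up venom proteomics.
#'
#' @param seed Integer seed fixing every random draw.
#' @param n_samples Number of samples (venoms).
#' @param group_sizes Integer partition of the samples into groups.
#' @param n_proteins_per_class Named integer vector of proteins per toxin
#'   class; SVMPs get domain annotations (pro, catalytic, disintegrin,
#'   Cys-rich) and three planted sites (one each in pro, catalytic and
#'   Cys-rich; none in the disintegrin domain), other classes two sites.
#' @param occupancy_p Probability that a planted site is identified in the
#'   intact glycopeptide analysis of a sample.
#' @param compositions_per_site Exact number of glycan compositions decorating
#'   every occupied site.
#' @param repertoire_size Compositions per group repertoire.
#' @param within_group_retention Probability that a sample keeps a given
#'   (site, composition) assignment of its group; a dropped assignment is
#'   swapped for another repertoire composition so the per-site count stays
#'   exact.
#' @param between_group_overlap Target fraction of a sample's glycopeptide
#'   features shared with samples of other groups, realised by forcing a
#'   shared high-mannose composition into all groups' assignments at a
#'   matching fraction of sites.
#' @param acetylation_p Probability that a sialylated record carries one
#'   O-acetyl group.
#' @param deamidation_fp_rate Probability that a nonglycosylated peptide with
#'   an Asn outside any sequon acquires a spurious deamidation mark.
#' @param replicate_dropout Probability that an observation is missing from a
#'   given technical replicate.
#' @param missed_cleavage_rate Probability of an additional missed-cleavage
#'   peptide covering a site.
#' @param semitryptic_rate Probability of an additional semitryptic (N-terminal
#'   truncated) peptide covering a site.
#' @param n_replicates,fractions Replicate count and fraction labels of the
#'   de-N-glycosylated tables.
#' @param ppm_noise Magnitude (ppm) of the m/z perturbation applied to planted
#'   spectrum peaks; the sign is random, the magnitude fixed.
#' @param n_spectra Number of MS/MS spectra emitted.
#' @return A `glyco_sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_samples = 7L,
                              group_sizes = c(3L, 2L, 2L),
                              n_proteins_per_class = c(SVMP = 4L, SVSP = 3L,
                                                       LAAO = 1L, CTL = 2L,
                                                       PLA2 = 2L),
                              occupancy_p = 0.55,
                              compositions_per_site = 3L,
                              repertoire_size = 10L,
                              within_group_retention = 0.9,
                              between_group_overlap = 0.2,
                              acetylation_p = 0.15,
                              deamidation_fp_rate = 0.05,
                              replicate_dropout = 0.1,
                              missed_cleavage_rate = 0.5,
                              semitryptic_rate = 0.3,
                              n_replicates = 3L,
                              fractions = c("dF1", "dF2", "dF3"),
                              ppm_noise = 3,
                              n_spectra = 40L) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              group_sizes = as.integer(group_sizes),
              n_proteins_per_class = n_proteins_per_class,
              occupancy_p = occupancy_p,
              compositions_per_site = as.integer(compositions_per_site),
              repertoire_size = as.integer(repertoire_size),
              within_group_retention = within_group_retention,
              between_group_overlap = between_group_overlap,
              acetylation_p = acetylation_p,
              deamidation_fp_rate = deamidation_fp_rate,
              replicate_dropout = replicate_dropout,
              missed_cleavage_rate = missed_cleavage_rate,
              semitryptic_rate = semitryptic_rate,
              n_replicates = as.integer(n_replicates),
              fractions = fractions,
              ppm_noise = ppm_noise, n_spectra = as.integer(n_spectra))
  probs <- c("occupancy_p", "within_group_retention", "between_group_overlap",
             "acetylation_p", "deamidation_fp_rate", "replicate_dropout",
             "missed_cleavage_rate", "semitryptic_rate")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]", call. = FALSE)
  }
  if (sum(cfg$group_sizes) != cfg$n_samples) {
    stop("group sizes must sum to n_samples", call. = FALSE)
  }
  if (sum(cfg$n_proteins_per_class) < 1L) stop("at least one protein required",
                                               call. = FALSE)
  if (cfg$compositions_per_site < 1L ||
      cfg$compositions_per_site > cfg$repertoire_size) {
    stop("compositions_per_site must be between 1 and repertoire_size",
         call. = FALSE)
  }
  structure(cfg, class = "glyco_sim_config")
}

# glycan catalogue: named high-mannose entries plus generated hybrid/complex
# compositions with group-flavoured sialylation.
.named_catalogue <- function() {
  tibble::tibble(
    id = c("A1", "A2", "B11", "B43", "B22", "B32"),
    composition = c(
      "(Hex)2 + (Man)3(GlcNAc)2",
      "(Hex)3 + (Man)3(GlcNAc)2",
      "(Hex)2 (HexNAc)2 (Deoxyhexose)1 (NeuAc)4 + (Man)3(GlcNAc)2",
      "(Hex)2 (HexNAc)2 (Deoxyhexose)1 (NeuAc)2 + (Man)3(GlcNAc)2",
      "(Hex)2 (HexNAc)2 (NeuAc)2 + (Man)3(GlcNAc)2",
      "(Hex)2 (HexNAc)2 (Deoxyhexose)1 (NeuAc)3 + (Man)3(GlcNAc)2"
    )
  )
}

.random_composition <- function(neuac_range) {
  comp <- glycan_composition(
    Hex = 3L + sample(0:2, 1L),
    HexNAc = 2L + sample(1:3, 1L),
    Deoxyhexose = sample(0:1, 1L),
    NeuAc = sample(neuac_range, 1L),
    core_man = 3L, core_glcnac = 2L
  )
  format_composition(comp)
}

.group_repertoires <- function(cfg) {
  n_groups <- length(cfg$group_sizes)
  named <- .named_catalogue()
  shared <- named[named$id %in% c("A1", "A2"), ]
  group_named <- list(c("B11", "B43"), "B22", "B32")
  # sialylation flavour per group: first group high, last low
  neuac_ranges <- list(3:4, 2:3, 1:2)
  catalogue <- named
  reps <- vector("list", n_groups)
  seen <- named$composition
  cid <- 0L
  for (g in seq_len(n_groups)) {
    own_ids <- if (g <= length(group_named)) group_named[[g]] else character(0)
    own <- named$composition[named$id %in% own_ids]
    need <- cfg$repertoire_size - nrow(shared) - length(own)
    extra <- character(0)
    rng <- neuac_ranges[[min(g, length(neuac_ranges))]]
    while (length(extra) < need) {
      cand <- .random_composition(rng)
      if (!cand %in% c(seen, extra)) extra <- c(extra, cand)
    }
    cid_new <- seq(cid + 1L, cid + length(extra))
    cid <- cid + length(extra)
    catalogue <- dplyr::bind_rows(catalogue, tibble::tibble(
      id = sprintf("C%02d", cid_new), composition = extra))
    seen <- c(seen, extra)
    reps[[g]] <- list(shared = shared$composition,
                      specific = c(own, extra))
  }
  list(catalogue = catalogue, repertoires = reps)
}

.random_segment <- function(len, pool = .AA20) {
  # never start with Pro: a leading P would suppress cleavage after the K/R
  # that precedes the segment and break the guaranteed site-covering peptide
  first <- sample(setdiff(pool, "P"), 1L)
  if (len == 1L) return(first)
  paste0(first, paste(sample(pool, len - 1L, replace = TRUE), collapse = ""))
}

# A site block guarantees a clean tryptic peptide of length 12 covering the
# planted sequon: K | 4 aa | N X S/T | 4 aa | K, with no K/R/P inside.
.site_block <- function() {
  pool <- setdiff(.AA20, c("K", "R", "P", "N"))
  x <- sample(setdiff(.AA20, c("P", "K", "R")), 1L)
  st <- sample(c("S", "T"), 1L)
  left <- .random_segment(4L, pool)
  right <- .random_segment(4L, pool)
  list(block = paste0("K", left, "N", x, st, right, "K"),
       site_offset = 6L)  # Asn position within the block (1-based)
}

.build_protein <- function(n_sites, seg_len = 45L) {
  parts <- character(0)
  site_pos <- integer(0)
  offset <- 0L
  for (i in seq_len(n_sites)) {
    seg <- .random_segment(seg_len)
    parts <- c(parts, seg)
    offset <- offset + nchar(seg)
    sb <- .site_block()
    site_pos <- c(site_pos, offset + sb$site_offset)
    parts <- c(parts, sb$block)
    offset <- offset + nchar(sb$block)
  }
  parts <- c(parts, .random_segment(seg_len))
  list(sequence = paste(parts, collapse = ""), site_positions = site_pos)
}

# Tryptic digestion: cleave after K/R unless followed by P.
.tryptic_digest <- function(sequence, min_len = 5L, max_len = 45L) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | chars[pmin(cut_after + 1L, n)] != "P"]
  starts <- c(1L, cut_after[cut_after < n] + 1L)
  ends <- c(cut_after[cut_after < n], n)
  tibble::tibble(
    start = starts, end = ends,
    peptide = substring(sequence, starts, ends)
  ) %>%
    dplyr::filter(nchar(.data$peptide) >= min_len,
                  nchar(.data$peptide) <= max_len)
}

#' Synthetic MS/MS spectrum for a glycan composition
#'
#' Builds a low-mass-range spectrum carrying the diagnostic oxonium ions
#' implied by the composition: HexNAc/Hex oxonium ions always, the NeuAc ion
#' and its water loss when sialylated, the full sialic acid dimer dehydration
#' series when the composition carries at least two NeuAc, and the
#' O-acetyl-NeuAc pair when O-acetylated. Planted m/z values are perturbed by
#' `ppm_noise` parts-per-million with random sign and fixed magnitude.
#'
#' @param comp A `glycan_composition`.
#' @param spectrum_id Identifier for the spectrum.
#' @param precursor_mz,charge Precursor annotation.
#' @param ppm_noise Perturbation magnitude in ppm.
#' @param base_peaks Optional tibble (`mz`, `intensity`) of additional
#'   background peaks.
#' @return A `glyco_spectrum`.
#' @export
spectrum_for_composition <- function(comp, spectrum_id = "syn",
                                     precursor_mz = 1000, charge = 2L,
                                     ppm_noise = 0, base_peaks = NULL) {
  validate_glycan_composition(comp)
  masses <- monosaccharide_masses()
  mz <- c(masses$residues[["HexNAc"]] + masses$proton,
          masses$residues[["Hex"]] + masses$proton)
  if (neuac_count(comp) >= 1L) {
    mz <- c(mz, diagnostic_ion("neuac", 0L), diagnostic_ion("neuac", 1L))
  }
  if (neuac_count(comp) >= 2L) {
    mz <- c(mz, diagnostic_ion("neuac_dimer", 0L), diagnostic_ion("neuac_dimer", 1L),
            diagnostic_ion("neuac_dimer", 2L))
  }
  if (comp$acetyl >= 1L) {
    mz <- c(mz, diagnostic_ion("acetyl_neuac", 0L), diagnostic_ion("acetyl_neuac", 1L))
  }
  if (ppm_noise > 0) {
    mz <- mz * (1 + sample(c(-1, 1), length(mz), replace = TRUE) * ppm_noise * 1e-6)
  }
  intensity <- stats::runif(length(mz), 20, 100)
  if (!is.null(base_peaks)) {
    mz <- c(mz, base_peaks$mz)
    intensity <- c(intensity, base_peaks$intensity)
  }
  spectrum(spectrum_id, precursor_mz, charge, mz, intensity)
}

#' Simulate a multi-venom N-glycoproteomics study
#'
#' Generates the full input bundle consumed by the pipeline, with the planted
#' ground truth alongside. Identical seeds produce identical bundles.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `config`, `proteins`, `annotations`,
#'   `glycan_db`, `deglyco` (replicate-level identification tibble), `intact`
#'   (intact glycopeptide tibble), `spectra` (list of `glyco_spectrum`), and
#'   `truth` (list: `groups`, `sites`, `site_peptides`, `occupied`,
#'   `glycoforms`, `spectrum_signatures`).
#' @export
simulate_glyco_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "glyco_sim_config"))
  set.seed(config$seed)
  cfg <- config

  samples <- sprintf("venom%02d", seq_len(cfg$n_samples))
  groups <- tibble::tibble(
    sample_id = samples,
    group = rep(sprintf("G%d", seq_along(cfg$group_sizes)), cfg$group_sizes)
  )

  # --- glycan catalogue and group repertoires -------------------------------
  gl <- .group_repertoires(cfg)
  catalogue <- gl$catalogue
  parsed_cat <- lapply(catalogue$composition, parse_composition)
  names(parsed_cat) <- catalogue$composition
  cat_class <- vapply(parsed_cat, function(c) classify_glycan(c)$type_label,
                      character(1))
  glycan_db <- tibble::tibble(id = catalogue$id,
                              composition = catalogue$composition,
                              class = unname(cat_class))

  # --- proteins, domains, planted sites -------------------------------------
  prot_rows <- list()
  ann_rows <- list()
  site_rows <- list()
  for (cls in names(cfg$n_proteins_per_class)) {
    for (i in seq_len(cfg$n_proteins_per_class[[cls]])) {
      pid <- sprintf("%s_%02d", cls, i)
      n_sites <- if (cls == "SVMP") 3L else 2L
      bp <- .build_protein(n_sites)
      prot_rows[[pid]] <- tibble::tibble(protein_id = pid, toxin_class = cls,
                                         sequence = bp$sequence)
      if (cls == "SVMP") {
        # domains: pro covers the first site, catalytic the second,
        # Cys-rich the third; disintegrin sits between catalytic and Cys-rich.
        L <- nchar(bp$sequence)
        p <- bp$site_positions
        b1 <- p[1] + 20L
        b2 <- p[2] + 15L
        b3 <- b2 + 12L
        ann_rows[[pid]] <- tibble::tibble(
          protein_id = pid, toxin_class = cls,
          domain = c("pro", "catalytic", "disintegrin", "Cys-rich"),
          start = c(1L, b1 + 1L, b2 + 1L, b3 + 1L),
          end = c(b1, b2, b3, L)
        )
      } else {
        ann_rows[[pid]] <- tibble::tibble(protein_id = pid, toxin_class = cls,
                                          domain = NA_character_,
                                          start = NA_integer_, end = NA_integer_)
      }
      site_rows[[pid]] <- tibble::tibble(
        protein_id = pid,
        position = bp$site_positions,
        motif = vapply(bp$site_positions, function(s)
          .sequon_at(bp$sequence, s), character(1))
      )
    }
  }
  proteins <- dplyr::bind_rows(prot_rows)
  annotations <- dplyr::bind_rows(ann_rows)
  sites <- dplyr::bind_rows(site_rows)
  seq_of <- stats::setNames(proteins$sequence, proteins$protein_id)

  # tryptic peptide covering each planted site
  digests <- lapply(proteins$protein_id, function(pid)
    .tryptic_digest(seq_of[[pid]]))
  names(digests) <- proteins$protein_id
  site_peptides <- purrr::pmap_dfr(sites, function(protein_id, position, motif) {
    dg <- digests[[protein_id]]
    hit <- dg[dg$start <= position & dg$end >= position, , drop = FALSE]
    stopifnot(nrow(hit) == 1L)
    tibble::tibble(protein_id = protein_id, position = position, motif = motif,
                   peptide = hit$peptide, start = hit$start, end = hit$end)
  })

  # --- group-level glycan assignment per site -------------------------------
  n_groups <- length(cfg$group_sizes)
  k <- cfg$compositions_per_site
  site_keys <- paste(sites$protein_id, sites$position)
  shared_rate <- min(1, cfg$between_group_overlap * k)
  site_shared <- stats::setNames(
    ifelse(stats::runif(length(site_keys)) < shared_rate,
           sample(gl$repertoires[[1]]$shared, length(site_keys), replace = TRUE),
           NA_character_),
    site_keys)
  group_assign <- list()
  for (g in seq_len(n_groups)) {
    rep_g <- gl$repertoires[[g]]
    assign_g <- lapply(site_keys, function(skey) {
      forced <- site_shared[[skey]]
      if (!is.na(forced)) {
        c(forced, sample(rep_g$specific, k - 1L))
      } else {
        sample(rep_g$specific, k)
      }
    })
    names(assign_g) <- site_keys
    group_assign[[g]] <- assign_g
  }

  # --- de-N-glycosylated identification tables ------------------------------
  deglyco_rows <- list()
  obs_id <- 0L
  emit_obs <- function(sample_id, peptide, protein_id, start, deam, mc) {
    keep <- stats::runif(cfg$n_replicates) >= cfg$replicate_dropout
    reps <- which(keep)
    if (length(reps) == 0) return(NULL)
    tibble::tibble(
      sample_id = sample_id, replicate = reps,
      fraction = sample(cfg$fractions, length(reps), replace = TRUE),
      peptide = peptide, deamidation_sites = deam,
      protein_id = protein_id, start = start, missed_cleavages = mc
    )
  }
  for (s in samples) {
    # glycosylated-site evidence: base peptide, plus redundancy variants
    for (r in seq_len(nrow(site_peptides))) {
      sp <- site_peptides[r, ]
      local <- sp$position - sp$start + 1L
      obs_id <- obs_id + 1L
      deglyco_rows[[obs_id]] <- emit_obs(s, sp$peptide, sp$protein_id, sp$start,
                                         as.character(local), 0L)
      if (stats::runif(1) < cfg$missed_cleavage_rate) {
        dg <- digests[[sp$protein_id]]
        nxt <- dg[dg$start == sp$end + 1L, , drop = FALSE]
        if (nrow(nxt) == 1L) {
          mc_pep <- paste0(sp$peptide, nxt$peptide)
          obs_id <- obs_id + 1L
          deglyco_rows[[obs_id]] <- emit_obs(s, mc_pep, sp$protein_id, sp$start,
                                             as.character(local), 1L)
        }
      }
      if (stats::runif(1) < cfg$semitryptic_rate && local > 3L) {
        semi <- substring(sp$peptide, 3L)
        obs_id <- obs_id + 1L
        deglyco_rows[[obs_id]] <- emit_obs(s, semi, sp$protein_id, sp$start + 2L,
                                           as.character(local - 2L), 0L)
      }
    }
    # nonglycosylated background peptides, some with spurious deamidation
    for (pid in proteins$protein_id) {
      dg <- digests[[pid]]
      bg <- dg[!(dg$start %in% site_peptides$start[site_peptides$protein_id == pid] &
                   dg$peptide %in% site_peptides$peptide), , drop = FALSE]
      for (r in seq_len(nrow(bg))) {
        pep <- bg$peptide[r]
        deam <- ""
        if (cfg$deamidation_fp_rate > 0 && stats::runif(1) < cfg$deamidation_fp_rate) {
          npos <- which(strsplit(pep, "")[[1]] == "N")
          # only mark an Asn outside any canonical sequon
          npos <- npos[vapply(npos, function(p)
            is.na(.sequon_at(seq_of[[pid]], bg$start[r] + p - 1L)), logical(1))]
          if (length(npos) > 0) deam <- as.character(npos[sample.int(length(npos), 1L)])
        }
        obs_id <- obs_id + 1L
        deglyco_rows[[obs_id]] <- emit_obs(s, pep, pid, bg$start[r], deam, 0L)
      }
    }
  }
  deglyco <- dplyr::bind_rows(deglyco_rows)

  # --- intact glycopeptide tables -------------------------------------------
  intact_rows <- list()
  glycoform_rows <- list()
  occupied_rows <- list()
  for (si in seq_len(cfg$n_samples)) {
    s <- samples[si]
    g <- match(groups$group[si], sprintf("G%d", seq_len(n_groups)))
    rep_g <- gl$repertoires[[g]]
    for (r in seq_len(nrow(site_peptides))) {
      sp <- site_peptides[r, ]
      skey <- paste(sp$protein_id, sp$position)
      detected <- stats::runif(1) < cfg$occupancy_p
      occupied_rows[[length(occupied_rows) + 1L]] <- tibble::tibble(
        sample_id = s, protein_id = sp$protein_id, position = sp$position,
        detected = detected)
      if (!detected) next
      comps <- group_assign[[g]][[skey]]
      # within-group variation: swap assignments while keeping k exact
      if (cfg$within_group_retention < 1) {
        for (ci in seq_along(comps)) {
          if (stats::runif(1) < 1 - cfg$within_group_retention) {
            alt <- setdiff(c(rep_g$shared, rep_g$specific), comps)
            if (length(alt) > 0) comps[ci] <- sample(alt, 1L)
          }
        }
      }
      for (comp_str in comps) {
        comp <- parsed_cat[[comp_str]]
        acetyl <- 0L
        if (neuac_count(comp) >= 1L && stats::runif(1) < cfg$acetylation_p) {
          acetyl <- 1L
        }
        full <- new_glycan_composition(comp$counts, acetyl = acetyl,
                                       core = comp$core, id = comp$id)
        intact_rows[[length(intact_rows) + 1L]] <- tibble::tibble(
          sample_id = s, peptide = sp$peptide, protein_id = sp$protein_id,
          site = sp$position, composition = comp_str, o_acetyl = acetyl,
          neutral_mass = glycopeptide_neutral_mass(sp$peptide, full),
          score = round(stats::runif(1, 5, 50), 3)
        )
        glycoform_rows[[length(glycoform_rows) + 1L]] <- tibble::tibble(
          sample_id = s, protein_id = sp$protein_id, site = sp$position,
          composition = format_composition(full), acetyl = acetyl)
      }
    }
  }
  intact <- dplyr::bind_rows(intact_rows)
  glycoforms <- dplyr::bind_rows(glycoform_rows)
  occupied <- dplyr::bind_rows(occupied_rows)

  # --- MS/MS spectra ---------------------------------------------------------
  spec_src <- glycoforms
  n_spec <- min(cfg$n_spectra, nrow(spec_src))
  spec_idx <- if (n_spec > 0) sample(nrow(spec_src), n_spec) else integer(0)
  spectra <- vector("list", n_spec)
  sig_rows <- vector("list", n_spec)
  for (j in seq_along(spec_idx)) {
    row <- spec_src[spec_idx[j], ]
    comp <- parse_composition(row$composition)
    sid <- sprintf("scan=%04d|%s|%s:%d", j, row$sample_id, row$protein_id,
                   row$site)
    spectra[[j]] <- spectrum_for_composition(
      comp, spectrum_id = sid, ppm_noise = cfg$ppm_noise,
      precursor_mz = round(composition_mass(comp) / 2 + 600, 4)
    )
    sig_rows[[j]] <- tibble::tibble(
      spectrum_id = sid, composition = row$composition,
      dimer_planted = neuac_count(comp) >= 2L,
      acetyl_planted = comp$acetyl >= 1L
    )
  }

  list(
    config = cfg,
    proteins = proteins,
    annotations = annotations,
    glycan_db = glycan_db,
    deglyco = deglyco,
    intact = intact,
    spectra = spectra,
    truth = list(
      groups = groups,
      sites = sites,
      site_peptides = site_peptides,
      occupied = occupied,
      glycoforms = glycoforms,
      spectrum_signatures = dplyr::bind_rows(sig_rows)
    )
  )
}

#' Write a simulated bundle to disk
#'
#' Emits the formats the pipeline consumes: protein FASTA, annotation TSV,
#' de-N-glycosylated identification TSV, intact glycopeptide TSV, glycan
#' database TSV, MGF peak list, and the ground truth as TSV/JSON.
#'
#' @param bundle Bundle from [simulate_glyco_study()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_protein_fasta(bundle$proteins, file.path(dir, "proteins.fasta"))
  readr::write_tsv(bundle$annotations, file.path(dir, "annotations.tsv"))
  readr::write_tsv(bundle$deglyco, file.path(dir, "deglyco_ids.tsv"))
  readr::write_tsv(bundle$intact, file.path(dir, "intact.tsv"))
  readr::write_tsv(bundle$glycan_db, file.path(dir, "glycan_db.tsv"))
  write_mgf(bundle$spectra, file.path(dir, "spectra.mgf"))
  truth_dir <- file.path(dir, "truth")
  if (!dir.exists(truth_dir)) dir.create(truth_dir)
  for (nm in c("groups", "sites", "site_peptides", "occupied", "glycoforms",
               "spectrum_signatures")) {
    readr::write_tsv(bundle$truth[[nm]], file.path(truth_dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(unclass(bundle$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
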