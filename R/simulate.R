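TMT18_LABELS <- c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                  "130N", "130C", "131N", "131C", "132N", "132C", "133N",
                  "133C", "134N", "134C", "135N")

# lipid subclass composition mirroring the identified-species breakdown of
# the study (206 species; 172 glycerophospho- + glycerolipids, 19 sphingo-,
# 14 fatty acyls, 1 prenol)
.LIPID_COMPOSITION <- data.frame(
  subclass = c("TG", "DG", "PC", "PE", "PG", "PI", "PS", "PA", "LPC", "LPE",
               "CL", "Cer", "HexCer", "FA", "FAHFA", "CoQ"),
  class = c("GL", "GL", "GP", "GP", "GP", "GP", "GP", "GP", "GP", "GP",
            "GP", "SL", "SL", "FA", "FA", "PR"),
  n = c(60L, 20L, 25L, 20L, 10L, 12L, 8L, 7L, 5L, 3L, 2L, 12L, 7L, 10L,
        4L, 1L),
  time_slope = c(0.8, 0.5, -0.4, -0.4, -0.4, -0.4, -0.4, -0.4, -0.4, -0.4,
                 -0.4, 0, 0, 0, 0, 0.3),
  stringsAsFactors = FALSE)

#' Configuration of a synthetic multi-omics study
#'
#' Defines the size, effect model and noise of a generated study. The
#' experimental frame is fixed to the 2 (nitrogen high/low) x 3 (24/48/72 h)
#' condition grid with three biological replicates, measured in two TMT-18
#' plexes per assay with shared 24 h bridge channels, pooled total-thiol
#' duplicate channels and two empty channels per plex.
#'
#' @param n_proteins,peptides_per_protein,n_cys_sites,n_phospho_sites,n_lipids
#'   feature counts (all >= 1). When \code{n_lipids} is NULL the generator
#'   uses the full 206-species subclass composition of the study.
#' @param diff_fraction named list: fraction of differential features per
#'   omic (\code{protein}, \code{redox}, \code{phospho}, \code{lipid}).
#' @param effect_size named list of log2 effect magnitudes per omic
#'   (applied to the low-nitrogen conditions, half up / half down).
#' @param pi_range baseline thiol-oxidation occupancy range (fractions).
#' @param stoich_range baseline phosphosite stoichiometry range.
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal measurement noise (0 switches noise off).
#' @param efficiency_sd sdlog of the per-peptide ionization efficiency.
#' @param loading_sd sdlog of per-channel loading factors (0 = all 1).
#' @param loading_factors optional named numeric of exact loading factors,
#'   names \code{"p1:127N"}-style, overriding the drawn values.
#' @param batch_offsets length-2 numeric, log2 batch offsets of the two
#'   physical plexes.
#' @param lipid_time_trends apply the subclass time trends (TG/DG rising,
#'   phospholipids falling) to the lipid ground truth.
#' @param fdr_fail_fraction fraction of decoy PSM rows emitted with
#'   \code{fdr_pass = FALSE}.
#' @param dropout_quantile lipid intensities below this global quantile
#'   become missing, emulating blank cells.
#' @param n_pathways number of synthetic protein pathway sets.
#' @param seed mandatory RNG seed.
#' @return a named list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_proteins = 200L, peptides_per_protein = 3L,
                      n_cys_sites = 300L, n_phospho_sites = 300L,
                      n_lipids = NULL,
                      diff_fraction = list(protein = 0.2, redox = 0.2,
                                           phospho = 0.2, lipid = 0.2),
                      effect_size = list(protein = 1, redox = 1,
                                         phospho = 1, lipid = 1.5),
                      pi_range = c(0.05, 0.3),
                      stoich_range = c(0.1, 0.9),
                      noise_cv = 0.1, efficiency_sd = 0.5,
                      loading_sd = 0.2, loading_factors = NULL,
                      batch_offsets = c(p1 = 0, p2 = 0.5),
                      lipid_time_trends = TRUE,
                      fdr_fail_fraction = 0.05,
                      dropout_quantile = 0.05,
                      n_pathways = 10L, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  counts <- c(n_proteins = n_proteins,
              peptides_per_protein = peptides_per_protein,
              n_cys_sites = n_cys_sites, n_phospho_sites = n_phospho_sites)
  if (any(counts < 1)) stop("all feature counts must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  stopifnot(length(batch_offsets) == 2L)
  names(batch_offsets) <- c("p1", "p2")
  structure(list(n_proteins = as.integer(n_proteins),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 n_cys_sites = as.integer(n_cys_sites),
                 n_phospho_sites = as.integer(n_phospho_sites),
                 n_lipids = n_lipids,
                 diff_fraction = diff_fraction, effect_size = effect_size,
                 pi_range = pi_range, stoich_range = stoich_range,
                 noise_cv = noise_cv, efficiency_sd = efficiency_sd,
                 loading_sd = loading_sd, loading_factors = loading_factors,
                 batch_offsets = batch_offsets,
                 lipid_time_trends = isTRUE(lipid_time_trends),
                 fdr_fail_fraction = fdr_fail_fraction,
                 dropout_quantile = dropout_quantile,
                 n_pathways = as.integer(n_pathways),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# sample ids of the 18 biological samples, ordered
.studySamples <- function() {
  grid <- expand.grid(replicate = 1:3, timepoint_h = TIMEPOINTS_H,
                      nitrogen = c("high", "low"),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("nitrogen", "timepoint_h", "replicate")]
  grid$condition <- paste(grid$nitrogen, grid$timepoint_h, sep = "_")
  grid$sample_id <- paste0(grid$condition, "_r", grid$replicate)
  grid
}

# channel layout of one physical plex: 6 bridge (24 h, both plexes),
# 6 timepoint samples (48 h in p1, 72 h in p2), 2 pool duplicates, 2 empty
.plexChannels <- function(phys, assay) {
  samples <- .studySamples()
  bridge <- samples[samples$timepoint_h == 24L, ]
  own_t <- if (phys == "p1") 48L else 72L
  own <- samples[samples$timepoint_h == own_t, ]
  ch <- data.frame(
    channel_label = TMT18_LABELS[1:16],
    sample_id = c(bridge$sample_id, own$sample_id,
                  "total_thiol_pool", "total_thiol_pool", NA, NA),
    nitrogen = c(bridge$nitrogen, own$nitrogen, "none", "none", NA, NA),
    timepoint_h = c(bridge$timepoint_h, own$timepoint_h, rep(NA_integer_, 4)),
    replicate = c(bridge$replicate, own$replicate, 1L, 2L, NA, NA),
    assay = c(rep(assay, 14L), NA, NA),
    channel_class = c(rep("bridge", 6), rep("sample", 6),
                      rep("total_thiol_pool", 2), rep("empty", 2)),
    batch = c(rep(phys, 14L), NA, NA),
    stringsAsFactors = FALSE)
  ch
}

#' Build the two-plex-per-assay study design
#'
#' @param assays assays to include.
#' @return list of \linkS4class{PlexDesign} named \code{<assay>_p1/p2}.
#' @export
makeStudyDesign <- function(assays = ASSAYS) {
  designs <- list()
  for (a in assays) {
    for (phys in c("p1", "p2")) {
      id <- paste(a, phys, sep = "_")
      designs[[id]] <- PlexDesign(id, .plexChannels(phys, a))
    }
  }
  validateDesigns(designs)
  designs
}

.physPlex <- function(plex_id) sub("^.*_(p[12])$", "\\1", plex_id)

.lnNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# intensity rows for one assay's PSM table given per-sample linear signal
# S (features x 18 samples) and peptide metadata
.assayPSM <- function(assay, designs, S, peptides, efficiency, truth, cfg,
                      pool_signal = rowMeans(S)) {
  samples <- .studySamples()
  rows <- list()
  for (phys in c("p1", "p2")) {
    plex <- paste(assay, phys, sep = "_")
    ch <- designChannels(designs[[plex]])
    ints <- matrix(0, nrow(peptides), nrow(ch),
                   dimnames = list(NULL, ch$channel_label))
    for (j in seq_len(nrow(ch))) {
      cls <- ch$channel_class[j]
      if (cls == "empty") next                      # empty channels stay 0
      base <- if (cls == "total_thiol_pool") pool_signal
              else S[, match(ch$sample_id[j], samples$sample_id)]
      load <- truth$channel_loading[.chanId(phys, ch$channel_label[j])]
      ints[, j] <- base * efficiency * load *
        2^truth$batch_offset[phys] * .lnNoise(nrow(peptides), cfg$noise_cv)
    }
    tab <- cbind(data.frame(plex_id = plex, peptide = peptides$peptide,
                            protein_id = peptides$protein_id,
                            site_keys = peptides$site_keys,
                            fdr_pass = TRUE, stringsAsFactors = FALSE),
                 as.data.frame(ints))
    rows[[phys]] <- tab
  }
  out <- do.call(rbind, rows)
  # decoy rows that fail FDR filtering
  n_decoy <- round(cfg$fdr_fail_fraction * nrow(out))
  if (n_decoy > 0) {
    idx <- sample.int(nrow(out), n_decoy, replace = TRUE)
    dec <- out[idx, , drop = FALSE]
    dec$peptide <- paste0("decoy_", seq_len(n_decoy), "_", dec$peptide)
    dec$fdr_pass <- FALSE
    out <- rbind(out, dec)
  }
  rownames(out) <- NULL
  out
}

# per-condition log2 effects for differential features: half up, half down,
# applied to the low-nitrogen conditions only
.nitrogenEffects <- function(n_features, fraction, magnitude) {
  eff <- numeric(n_features)
  n_diff <- round(fraction * n_features)
  if (n_diff > 0) {
    idx <- sample.int(n_features, n_diff)
    sign <- rep(c(1, -1), length.out = n_diff)
    eff[idx] <- sign * magnitude
  }
  eff
}

#' Generate a complete synthetic multi-omics study
#'
#' Emulates the study's measurement process with known ground truth. The
#' generative model, in order: (1) per-protein baseline log2 abundance ~
#' Normal(20, 2) plus nitrogen condition effects; (2) a fixed log-normal
#' ionization efficiency per peptide; (3) global channel intensity =
#' 2^(protein log2 in the channel's condition) x efficiency x channel
#' loading x batch factor x log-normal noise; (4) redox +NEM channels are
#' proportional to occupancy pi x protein level, while pooled total-thiol
#' channels carry the unweighted mean of the pi = 1 signal over all 18
#' study samples, in duplicate per plex; (5) phospho channels are
#' proportional to stoichiometry x protein level; (6) the six 24 h samples
#' are measured as technical-replicate bridge channels in both plexes, and
#' a per-plex batch factor multiplies all of a plex's intensities;
#' (7) empty channels carry zero intensity; (8) lipid intensities =
#' 2^(lipid log2 level) x log-normal noise with a global low-intensity
#' dropout rule converting blank-like cells to missing.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list of class \code{"SyntheticStudy"} with elements
#'   \code{designs} (six \linkS4class{PlexDesign}), \code{psm} (list of
#'   PSM data.frames for global/redox/phospho), \code{lipids} (lipid
#'   table), \code{lipid_samples} (sample metadata), \code{sets}
#'   (protein pathway GMT list) , \code{lipid_sets} (subclass sets) and
#'   \code{truth} (ground-truth maps).
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  samples <- .studySamples()
  low <- grepl("^low_", CONDITIONS)

  proteins <- sprintf("RT_%04d", seq_len(config$n_proteins))
  base <- stats::rnorm(config$n_proteins, mean = 20, sd = 2)
  prot_eff <- .nitrogenEffects(config$n_proteins,
                               config$diff_fraction$protein,
                               config$effect_size$protein)
  protein_log2 <- matrix(base, config$n_proteins, 6,
                         dimnames = list(proteins, CONDITIONS))
  protein_log2[, low] <- protein_log2[, low] + prot_eff

  # channel loadings shared by physical plex across assays
  chan_ids <- as.vector(outer(c("p1", "p2"), TMT18_LABELS[1:16], .chanId))
  loading <- stats::setNames(
    exp(stats::rnorm(length(chan_ids), 0, config$loading_sd)), chan_ids)
  if (!is.null(config$loading_factors)) {
    unknown <- setdiff(names(config$loading_factors), chan_ids)
    if (length(unknown))
      stop("loading_factors for unknown channel(s): ",
           paste(unknown, collapse = ", "))
    loading[names(config$loading_factors)] <-
      unlist(config$loading_factors)
  }
  batch <- config$batch_offsets

  # redox ground truth: baseline occupancy, shifted in low nitrogen for the
  # differential sites (multiplicative on pi, capped below 0.95)
  n_cys <- config$n_cys_sites
  cys_parent <- proteins[((seq_len(n_cys) - 1L) %% config$n_proteins) + 1L]
  cys_ord <- stats::ave(seq_len(n_cys), cys_parent, FUN = seq_along)
  cys_keys <- paste0(cys_parent, "_C", 10L * cys_ord)
  pi0 <- stats::runif(n_cys, config$pi_range[1], config$pi_range[2])
  pi_shift <- .nitrogenEffects(n_cys, config$diff_fraction$redox,
                               config$effect_size$redox)
  occupancy <- matrix(pi0, n_cys, 6, dimnames = list(cys_keys, CONDITIONS))
  occupancy[, low] <- pmin(0.95, occupancy[, low] * 2^pi_shift)

  # phospho ground truth; ~10% composite (ambiguous) site keys
  n_ph <- config$n_phospho_sites
  ph_parent <- proteins[((seq_len(n_ph) - 1L) %% config$n_proteins) + 1L]
  ph_ord <- stats::ave(seq_len(n_ph), ph_parent, FUN = seq_along)
  composite <- seq_len(n_ph) %% 10L == 0L
  ph_keys <- ifelse(composite,
                    paste0(ph_parent, "_S", 10L * ph_ord + 1L, ";T",
                           10L * ph_ord + 2L),
                    paste0(ph_parent, "_S", 10L * ph_ord + 1L))
  st0 <- stats::runif(n_ph, config$stoich_range[1], config$stoich_range[2])
  st_shift <- .nitrogenEffects(n_ph, config$diff_fraction$phospho,
                               config$effect_size$phospho)
  stoich <- matrix(st0, n_ph, 6, dimnames = list(ph_keys, CONDITIONS))
  stoich[, low] <- pmin(1, stoich[, low] * 2^st_shift)

  # lipid ground truth: subclass composition with optional time trends
  comp <- .LIPID_COMPOSITION
  if (!is.null(config$n_lipids)) {
    n_per <- diff(round(seq(0, config$n_lipids, length.out = nrow(comp) + 1)))
    comp$n <- pmax(n_per, 1L)
  }
  lipid_ann <- data.frame(
    lipid_id = unlist(mapply(function(s, n) sprintf("%s_%02d", s, seq_len(n)),
                             comp$subclass, comp$n, SIMPLIFY = FALSE)),
    class = rep(comp$class, comp$n),
    subclass = rep(comp$subclass, comp$n), stringsAsFactors = FALSE)
  n_lip <- nrow(lipid_ann)
  lip_base <- stats::rnorm(n_lip, 15, 2)
  lip_eff <- .nitrogenEffects(n_lip, config$diff_fraction$lipid,
                              config$effect_size$lipid)
  slope <- comp$time_slope[match(lipid_ann$subclass, comp$subclass)]
  if (!config$lipid_time_trends) slope <- numeric(n_lip)
  tstep <- (match(sub("^.*_", "", CONDITIONS), TIMEPOINTS_H) - 1)
  lipid_log2 <- matrix(lip_base, n_lip, 6,
                       dimnames = list(lipid_ann$lipid_id, CONDITIONS))
  lipid_log2 <- lipid_log2 + outer(slope, tstep)
  lipid_log2[, low] <- lipid_log2[, low] + lip_eff

  truth <- structure(list(
    protein_log2 = protein_log2, site_occupancy = occupancy,
    phospho_stoichiometry = stoich, lipid_log2 = lipid_log2,
    channel_loading = loading, batch_offset = batch,
    noise_cv = config$noise_cv,
    differential = list(protein = prot_eff != 0, redox = pi_shift != 0,
                        phospho = st_shift != 0, lipid = lip_eff != 0),
    effects = list(protein = prot_eff, redox = pi_shift,
                   phospho = st_shift, lipid = lip_eff),
    site_parent = stats::setNames(cys_parent, cys_keys),
    phospho_parent = stats::setNames(ph_parent, ph_keys)),
    class = "GroundTruth")

  designs <- makeStudyDesign()

  # global peptides
  glob_pep <- data.frame(
    peptide = paste0("pep_", rep(proteins, each = config$peptides_per_protein),
                     "_", seq_len(config$peptides_per_protein)),
    protein_id = rep(proteins, each = config$peptides_per_protein),
    site_keys = "", stringsAsFactors = FALSE)
  eff_glob <- stats::setNames(
    exp(stats::rnorm(nrow(glob_pep), 0, config$efficiency_sd)),
    glob_pep$peptide)
  cond_of <- samples$condition
  S_glob <- 2^protein_log2[glob_pep$protein_id, cond_of, drop = FALSE]
  colnames(S_glob) <- samples$sample_id
  psm_global <- .assayPSM("global", designs, S_glob, glob_pep, eff_glob,
                          truth, config)

  # redox: one cysteine peptide per site; +NEM signal = pi x protein level
  cys_pep <- data.frame(peptide = paste0("cpep_", seq_len(n_cys)),
                        protein_id = cys_parent, site_keys = cys_keys,
                        stringsAsFactors = FALSE)
  eff_cys <- stats::setNames(
    exp(stats::rnorm(n_cys, 0, config$efficiency_sd)), cys_pep$peptide)
  S_total <- 2^protein_log2[cys_parent, cond_of, drop = FALSE]
  S_redox <- occupancy[, cond_of, drop = FALSE] * S_total
  colnames(S_redox) <- samples$sample_id
  # pooled total-thiol channels carry the pi = 1 (fully reduced) signal
  psm_redox <- .assayPSM("redox", designs, S_redox, cys_pep, eff_cys,
                         truth, config, pool_signal = rowMeans(S_total))

  # phospho: stoichiometry x protein level
  ph_pep <- data.frame(peptide = paste0("ppep_", seq_len(n_ph)),
                       protein_id = ph_parent, site_keys = ph_keys,
                       stringsAsFactors = FALSE)
  eff_ph <- stats::setNames(
    exp(stats::rnorm(n_ph, 0, config$efficiency_sd)), ph_pep$peptide)
  S_ph <- stoich[, cond_of, drop = FALSE] *
    2^protein_log2[ph_parent, cond_of, drop = FALSE]
  colnames(S_ph) <- samples$sample_id
  psm_phospho <- .assayPSM("phospho", designs, S_ph, ph_pep, eff_ph,
                           truth, config)

  truth$peptide_efficiency <- c(eff_glob, eff_cys, eff_ph)

  # lipids over the 18 samples with dropout below a global quantile
  lip_int <- 2^lipid_log2[, cond_of, drop = FALSE] *
    matrix(.lnNoise(n_lip * 18, config$noise_cv), n_lip, 18)
  colnames(lip_int) <- samples$sample_id
  if (config$dropout_quantile > 0) {
    thr <- stats::quantile(lip_int, config$dropout_quantile, na.rm = TRUE)
    lip_int[lip_int < thr] <- NA_real_
  }
  lipids <- cbind(lipid_ann, as.data.frame(lip_int))
  rownames(lipids) <- NULL

  # synthetic pathway sets over proteins; lipid sets by subclass
  pw <- sprintf("pathway_%02d", ((seq_along(proteins) - 1L) %%
                                   config$n_pathways) + 1L)
  sets <- split(proteins, pw)
  attr(sets, "description") <- stats::setNames(
    paste("synthetic pathway", names(sets)), names(sets))
  lipid_sets <- split(lipid_ann$lipid_id, lipid_ann$subclass)
  attr(lipid_sets, "description") <- stats::setNames(
    paste("lipid subclass", names(lipid_sets)), names(lipid_sets))

  structure(list(designs = designs,
                 psm = list(global = psm_global, redox = psm_redox,
                            phospho = psm_phospho),
                 lipids = lipids, lipid_samples = samples,
                 sets = sets, lipid_sets = lipid_sets,
                 truth = truth, config = config),
            class = "SyntheticStudy")
}

#' @rdname simulateStudy
#' @details \code{simulateNull} forces every condition effect to zero
#'   (differential fractions, occupancy/stoichiometry shifts and lipid time
#'   trends), for type-I-error and FDR calibration.
#' @export
simulateNull <- function(config) {
  config$diff_fraction <- list(protein = 0, redox = 0, phospho = 0,
                               lipid = 0)
  config$lipid_time_trends <- FALSE
  simulateStudy(config)
}

#' Write a synthetic study to disk
#'
#' Writes the design, the three PSM tables, the lipid table with sample
#' metadata, both GMT collections and a long-format \code{ground_truth.tsv}
#' so that recovery tests against the generating truth are self-contained.
#'
#' @param study a \code{"SyntheticStudy"}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(design = file.path(dir, "design.tsv"),
             psm_global = file.path(dir, "psm_global.tsv"),
             psm_redox = file.path(dir, "psm_redox.tsv"),
             psm_phospho = file.path(dir, "psm_phospho.tsv"),
             lipids = file.path(dir, "lipids.csv"),
             lipid_samples = file.path(dir, "lipid_samples.tsv"),
             sets = file.path(dir, "protein_sets.gmt"),
             lipid_sets = file.path(dir, "lipid_sets.gmt"),
             truth = file.path(dir, "ground_truth.tsv"))
  writeDesign(study$designs, paths["design"])
  writePSMTable(study$psm$global, paths["psm_global"])
  writePSMTable(study$psm$redox, paths["psm_redox"])
  writePSMTable(study$psm$phospho, paths["psm_phospho"])
  writeLipidTable(study$lipids, paths["lipids"])
  utils::write.table(study$lipid_samples, paths["lipid_samples"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeGMT(study$sets, paths["sets"])
  writeGMT(study$lipid_sets, paths["lipid_sets"])

  tr <- study$truth
  long <- function(mat, what) {
    data.frame(kind = what, feature = rep(rownames(mat), ncol(mat)),
               key = rep(colnames(mat), each = nrow(mat)),
               value = as.vector(mat), stringsAsFactors = FALSE)
  }
  gt <- rbind(long(tr$protein_log2, "protein_log2"),
              long(tr$site_occupancy, "site_occupancy"),
              long(tr$phospho_stoichiometry, "phospho_stoichiometry"),
              long(tr$lipid_log2, "lipid_log2"),
              data.frame(kind = "channel_loading",
                         feature = names(tr$channel_loading), key = "",
                         value = unname(tr$channel_loading)),
              data.frame(kind = "batch_offset",
                         feature = names(tr$batch_offset), key = "",
                         value = unname(tr$batch_offset)),
              data.frame(kind = "noise_cv", feature = "noise_cv", key = "",
                         value = tr$noise_cv))
  utils::write.table(gt, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
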