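#' PCA score table
#'
#' Descriptive principal-component scores of the channels (features with
#' any missing value are dropped; features are centered), for sample-level
#' overviews of the normalized matrices.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @param n number of components to return.
#' @return data.frame of channel metadata plus PC score columns.
#' @export
pcaScores <- function(m, n = 2L) {
  v <- .values(m)
  complete <- stats::complete.cases(v)
  if (sum(complete) < 3) stop("too few complete features for PCA")
  pr <- stats::prcomp(t(v[complete, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  n <- min(n, ncol(pr$x))
  cbind(channelInfo(m), as.data.frame(pr$x[, seq_len(n), drop = FALSE]))
}

#' Channel-by-channel correlation matrix
#'
#' Pairwise-complete Pearson correlations between channels, a descriptive
#' quality-control summary.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @return correlation matrix over channels.
#' @export
sampleCorrelation <- function(m) {
  stats::cor(.values(m), use = "pairwise.complete.obs", method = "pearson")
}

.manifestEntry <- function(stage, n_in, n_out, note = "") {
  data.frame(stage = stage, n_in = n_in, n_out = n_out,
             dropped = n_in - n_out, note = note, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete chain on one configuration: synthetic-study
#' generation (or reading of supplied files), global/redox/phospho
#' quantification in the fixed normalization order, occupancy, lipid
#' normalization, time-matched two-group statistics, the factorial
#' nitrogen-by-time model on redox sites, set enrichment, and the
#' redox-lipid correlation integration. Every stage appends one manifest
#' entry (row counts in/out); all tabular outputs are written under
#' \code{outdir} when given, and the manifest records the seed and
#' configuration so a re-run reproduces identical outputs.
#'
#' @param config a \code{\link{simConfig}} (synthetic mode) or a named list
#'   of file paths with elements \code{design}, \code{psm_global},
#'   \code{psm_redox}, \code{psm_phospho}, \code{lipids}, \code{sets}
#'   (file mode).
#' @param outdir optional output directory for TSV/JSON artifacts.
#' @param filter a \code{\link{filterConfig}}.
#' @return invisibly, a list with the result tables and the
#'   \code{manifest}.
#' @export
runAll <- function(config, outdir = NULL, filter = filterConfig()) {
  manifest <- list()
  if (inherits(config, "SimConfig")) {
    study <- simulateStudy(config)
    manifest$simulate <- .manifestEntry("simulate", 0L,
                                        nrow(study$psm$global))
  } else {
    designs <- readDesign(config$design)
    study <- list(
      designs = designs,
      psm = list(global = readPSMTable(config$psm_global, designs),
                 redox = readPSMTable(config$psm_redox, designs),
                 phospho = readPSMTable(config$psm_phospho, designs)),
      lipids = readLipidTable(config$lipids),
      lipid_samples = NULL,
      sets = readGMT(config$sets),
      lipid_sets = NULL, truth = NULL)
  }
  psm <- lapply(study$psm, function(x) x[x$fdr_pass, , drop = FALSE])
  byAssay <- function(a) study$designs[grepl(paste0("^", a, "_"),
                                             vapply(study$designs, plexId,
                                                    ""))]

  # global: rollup -> log2 -> batch-correct -> median-center
  proteins <- normalizeGlobal(psm$global, byAssay("global"))
  manifest$global <- .manifestEntry("global_quant", nrow(psm$global),
                                    nrow(proteins))
  peptides_log2 <- log2Transform(rollupPeptide(psm$global,
                                               byAssay("global")))
  # PTM chains share the channel-loading offsets from global peptide data
  redox <- normalizePTM(psm$redox, byAssay("redox"), "redox",
                        peptides_log2, proteins)
  manifest$redox <- .manifestEntry("redox_quant", nrow(psm$redox),
                                   nrow(redox$sites))
  occupancy <- computeOccupancy(redox$sites_linear_scaled)
  manifest$occupancy <- .manifestEntry("occupancy",
                                       nrow(redox$sites_linear_scaled) * 6L,
                                       nrow(occupancy))
  phospho <- normalizePTM(psm$phospho, byAssay("phospho"), "phospho",
                          peptides_log2, proteins)
  manifest$phospho <- .manifestEntry("phospho_quant", nrow(psm$phospho),
                                     nrow(phospho$sites))
  lipids <- normalizeLipids(study$lipids, study$lipid_samples)
  manifest$lipids <- .manifestEntry("lipid_quant", nrow(study$lipids),
                                    nrow(lipids$linear))

  # time-matched two-group differential statistics per omic
  contrasts <- lapply(TIMEPOINTS_H, function(h)
    c(paste0("low_", h), paste0("high_", h)))
  diffOne <- function(m) {
    mm <- filterMinReps(m, k = filter$min_bio_reps)
    do.call(rbind, lapply(contrasts, function(ct)
      moderatedTwoGroup(mm, ct[1], ct[2])))
  }
  diffs <- list(global = diffOne(proteins),
                redox = diffOne(redox$sites),
                phospho = diffOne(phospho$sites),
                lipid = diffOne(lipids$log2))
  manifest$diff <- .manifestEntry("diff_stats",
                                  nrow(proteins) + nrow(redox$sites) +
                                    nrow(phospho$sites) +
                                    nrow(lipids$log2),
                                  sum(vapply(diffs, nrow, 1L)))
  # factorial model on redox sites; the Nitrogen coefficient drives the
  # integration selection
  fact <- fitFactorial(filterMinReps(redox$sites, k = filter$min_bio_reps))
  nitrogen_coef <- fact[fact$contrast == "Nitrogen", , drop = FALSE]

  # enrichment: protein-level ORA of time-matched global results
  sel_global <- keggInputFilter(diffs$global, filter)
  universe_global <- unique(diffs$global$feature_id)
  ora <- if (length(sel_global) && !is.null(study$sets))
    oraHypergeometric(sel_global, study$sets, universe_global,
                      filter$min_set_size) else NULL
  # rank-based lipid set enrichment on the 72 h contrast
  lipid72 <- diffs$lipid[diffs$lipid$contrast == "low_72 vs high_72", ]
  lsea <- if (!is.null(study$lipid_sets) && nrow(lipid72) >= 4) {
    scores <- stats::setNames(lipid72$log2FC, lipid72$feature_id)
    tryCatch(rankSetTest(scores, study$lipid_sets, filter$min_set_size),
             error = function(e) NULL)
  } else NULL

  # integration: oxidized-site means vs lipid subclass sums
  site_means <- conditionMeans(redox$sites)
  lipid_means <- conditionMeans(lipids$subclass)
  corr <- correlateSitesLipids(site_means, lipid_means)
  selected <- selectCorrelatedSites(corr, nitrogen_coef, filter)
  manifest$integrate <- .manifestEntry("integrate", nrow(site_means),
                                       length(selected))
  sel_ora <- if (length(selected) && !is.null(study$sets)) {
    sel_prot <- unique(.siteProtein(selected))
    univ_prot <- unique(.siteProtein(rownames(site_means)))
    oraHypergeometric(sel_prot, study$sets, univ_prot,
                      filter$min_set_size)
  } else NULL

  manifest_df <- do.call(rbind, manifest)
  rownames(manifest_df) <- NULL
  result <- list(proteins = proteins, redox = redox, phospho = phospho,
                 occupancy = occupancy, lipids = lipids, diffs = diffs,
                 factorial = fact, correlations = corr,
                 selected_sites = selected, ora = ora, lsea = lsea,
                 selection_ora = sel_ora, manifest = manifest_df,
                 truth = study$truth, config = config)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wtsv <- function(x, f) utils::write.table(
      x, file.path(outdir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wmat <- function(m, f) utils::write.table(
      data.frame(feature_id = rownames(.values(m)), .values(m),
                 check.names = FALSE),
      file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wmat(proteins, "global_normalized.tsv")
    wmat(redox$sites, "redox_sites_adjusted.tsv")
    wmat(redox$sites_unadjusted, "redox_sites.tsv")
    wmat(phospho$sites, "phospho_sites_adjusted.tsv")
    wmat(lipids$log2, "lipids_normalized.tsv")
    wtsv(occupancy, "occupancy.tsv")
    for (nm in names(diffs)) wtsv(diffs[[nm]], paste0("diff_", nm, ".tsv"))
    wtsv(fact, "diff_factorial_redox.tsv")
    wtsv(corr, "site_lipid_correlations.tsv")
    if (length(selected))
      writeLines(selected, file.path(outdir, "selected_sites.txt"))
    if (!is.null(ora)) wtsv(ora, "ora_global.tsv")
    if (!is.null(lsea)) wtsv(lsea, "lsea_lipids.tsv")
    if (!is.null(sel_ora)) wtsv(sel_ora, "ora_selected_sites.tsv")
    wtsv(manifest_df, "manifest.tsv")
    run_info <- list(seed = if (inherits(config, "SimConfig"))
      config$seed else NA,
      config = unclass(config)[!vapply(config, is.function, TRUE)],
      n_stages = nrow(manifest_df))
    jsonlite::write_json(run_info, file.path(outdir, "run_info.json"),
                         auto_unbox = TRUE, null = "null", digits = NA,
                         force = TRUE)
  }
  invisible(result)
}
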