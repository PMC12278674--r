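# Shared PSM -> feature x channel rollup. Intensities are summed within the
# grouping key per channel; missing values are skipped, and a cell is
# missing only when every contributing PSM is missing there.
.psmRollup <- function(psm, designs, group, step) {
  dtab <- .designTable(designs, quantitativeOnly = TRUE)
  keep_plex <- dtab$plex_id %in% unique(psm$plex_id)
  dtab <- dtab[keep_plex, , drop = FALSE]
  if (!nrow(dtab)) stop("no design channels match the PSM table's plexes")
  features <- sort(unique(group))
  out <- matrix(NA_real_, length(features), nrow(dtab),
                dimnames = list(features, dtab$channel_id))
  for (p in unique(dtab$plex_id)) {
    rows <- psm$plex_id == p
    if (!any(rows)) next
    labels <- dtab$channel_label[dtab$plex_id == p]
    missing_cols <- setdiff(labels, names(psm))
    if (length(missing_cols))
      stop("PSM table lacks intensity column(s) for plex '", p, "': ",
           paste(missing_cols, collapse = ", "))
    vals <- as.matrix(psm[rows, labels, drop = FALSE])
    rs <- .rowsumSkipNA(vals, group[rows])
    out[rownames(rs), .chanId(p, labels)] <- rs
  }
  .makeOmicsMatrix(out, dtab, scale = "linear", steps = step)
}

#' Roll up PSM reporter intensities to proteins
#'
#' Global protein abundance is the sum of raw TMT reporter ion intensities
#' over a protein's FDR-passing peptides, per channel. Missing peptide
#' intensities are skipped (never treated as zero); a protein is missing in
#' a channel only when all of its peptides are missing there.
#'
#' @param psm PSM data.frame (already FDR-filtered; see
#'   \code{\link{readPSMTable}}).
#' @param designs list of \linkS4class{PlexDesign}; empty channels are
#'   excluded.
#' @return a linear-scale \linkS4class{OmicsMatrix}, proteins x channels.
#' @export
rollupProtein <- function(psm, designs) {
  if (any(!psm$fdr_pass))
    stop("PSM table contains FDR-failing rows; filter first")
  .psmRollup(psm, designs, psm$protein_id, "rollup_protein")
}

#' @rdname rollupProtein
#' @details \code{rollupPeptide} sums PSMs of the same peptide sequence; the
#'   resulting peptide-level global matrix (log2, not batch-corrected) is
#'   the reference for TMT channel-loading estimation in
#'   \code{\link{channelLoadingOffsets}}.
#' @export
rollupPeptide <- function(psm, designs) {
  if (any(!psm$fdr_pass))
    stop("PSM table contains FDR-failing rows; filter first")
  .psmRollup(psm, designs, psm$peptide, "rollup_peptide")
}

#' Log2-transform a linear abundance matrix
#'
#' Elementwise log2. Zero intensities become missing (their count is
#' reported); negative values are an error.
#'
#' @param m a linear-scale \linkS4class{OmicsMatrix}.
#' @return the matrix on log2 scale.
#' @export
log2Transform <- function(m) {
  .assertScale(m, "linear")
  v <- .values(m)
  if (any(v < 0, na.rm = TRUE)) stop("negative intensities cannot be logged")
  zeros <- sum(v == 0, na.rm = TRUE)
  if (zeros > 0) {
    message("log2Transform: ", zeros, " zero intensities set to missing")
    v[!is.na(v) & v == 0] <- NA_real_
  }
  .values(m) <- log2(v)
  m@scale <- "log2"
  .recordStep(m, "log2_transform")
}

#' Bridge-channel batch correction
#'
#' Aligns plexes on the shared bridge channels (the 24 h technical
#' replicates measured in every plex). For each feature, the plex offset is
#' the mean of its bridge-channel values in that plex minus the mean over
#' all plexes' bridge channels, and is subtracted from every channel of the
#' plex. Features with no observed bridge value in a plex fall back to the
#' plex-median offset across features. With \code{method = "median"} the
#' per-feature offsets are instead medians over all of a plex's channels
#' minus the feature's grand median (a fallback for designs without
#' bridges).
#'
#' Because a single offset is subtracted from all of a feature's channels
#' within a plex, within-plex differences between channels are untouched.
#'
#' @param m a log2-scale \linkS4class{OmicsMatrix} spanning >= 2 plexes.
#' @param method \code{"bridge"} (default) or \code{"median"}.
#' @return the corrected matrix.
#' @export
bridgeBatchCorrect <- function(m, method = c("bridge", "median")) {
  method <- match.arg(method)
  .assertScale(m, "log2")
  info <- channelInfo(m)
  plexes <- unique(info$plex_id)
  if (length(plexes) < 2)
    stop("batch correction needs >= 2 plexes")
  v <- .values(m)
  if (method == "bridge") {
    bridge <- info$channel_class == "bridge"
    if (!any(bridge))
      stop("no bridge channels in any plex; re-run with method = 'median' ",
           "for per-plex median alignment")
    grand <- rowMeans(v[, bridge, drop = FALSE], na.rm = TRUE)
    for (p in plexes) {
      pb <- bridge & info$plex_id == p
      if (!any(pb))
        stop("plex '", p, "' has no bridge channels; re-run with ",
             "method = 'median'")
      off <- rowMeans(v[, pb, drop = FALSE], na.rm = TRUE) - grand
      off[is.nan(off)] <- NA_real_
      fallback <- stats::median(off, na.rm = TRUE)
      off[is.na(off)] <- fallback
      v[, info$plex_id == p] <- v[, info$plex_id == p, drop = FALSE] - off
    }
  } else {
    grand <- apply(v, 1L, stats::median, na.rm = TRUE)
    for (p in plexes) {
      pc <- info$plex_id == p
      off <- apply(v[, pc, drop = FALSE], 1L, stats::median, na.rm = TRUE) -
        grand
      off[is.na(off)] <- stats::median(off, na.rm = TRUE)
      v[, pc] <- v[, pc, drop = FALSE] - off
    }
  }
  .values(m) <- v
  .recordStep(m, "bridge_batch_correct")
}

#' Median-center channels
#'
#' Subtracts each channel's median over its observed features, so that
#' every channel median is zero afterwards.
#'
#' @param m a log2-scale \linkS4class{OmicsMatrix}.
#' @return the centered matrix.
#' @export
medianCenterChannels <- function(m) {
  .assertScale(m, "log2")
  v <- .values(m)
  n_obs <- colSums(!is.na(v))
  if (any(n_obs < 1))
    stop("channel(s) with no observed features: ",
         paste(colnames(v)[n_obs < 1], collapse = ", "))
  v <- sweep(v, 2L, .colMedians(v), "-")
  .values(m) <- v
  .recordStep(m, "median_center_channels")
}

#' Full global-proteomics normalization chain
#'
#' Convenience wrapper running rollup, log2 transform, bridge batch
#' correction and channel median centering in the fixed pipeline order.
#'
#' @inheritParams rollupProtein
#' @param batchMethod passed to \code{\link{bridgeBatchCorrect}}.
#' @return a normalized log2 \linkS4class{OmicsMatrix}.
#' @export
normalizeGlobal <- function(psm, designs, batchMethod = "bridge") {
  m <- rollupProtein(psm, designs)
  m <- log2Transform(m)
  m <- bridgeBatchCorrect(m, method = batchMethod)
  medianCenterChannels(m)
}
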