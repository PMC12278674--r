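#' Aggregate PSM intensities to PTM sites
#'
#' Site-level PTM abundance is the sum of reporter ion intensities over the
#' FDR-passing peptides that carry a given site key. Composite (ambiguous)
#' keys such as \code{"RT_0001_S512;T513"} aggregate only peptides carrying
#' the identical composite and are kept distinct from their single-residue
#' counterparts. Peptides without a site key do not belong in a PTM table;
#' they are skipped with a warning.
#'
#' @param psm redox or phospho PSM data.frame (FDR-filtered).
#' @param designs list of \linkS4class{PlexDesign}.
#' @param kind \code{"redox"} or \code{"phospho"}.
#' @return a linear-scale \linkS4class{SiteMatrix}.
#' @export
aggregateSites <- function(psm, designs, kind = c("redox", "phospho")) {
  kind <- match.arg(kind)
  if (any(!psm$fdr_pass))
    stop("PSM table contains FDR-failing rows; filter first")
  no_key <- is.na(psm$site_keys) | psm$site_keys == ""
  if (any(no_key)) {
    warning(sum(no_key), " peptide row(s) without site keys skipped")
    psm <- psm[!no_key, , drop = FALSE]
  }
  if (!nrow(psm)) stop("no site-bearing peptides to aggregate")
  invisible(parseSiteKeys(unique(psm$site_keys)))   # validate grammar
  m <- .psmRollup(psm, designs, psm$site_keys, "aggregate_sites")
  new("SiteMatrix", m, scale = m@scale, appliedSteps = m@appliedSteps,
      ptmKind = kind, adjustedForProtein = FALSE)
}

#' TMT channel-loading offsets from global peptide data
#'
#' Estimates per-channel loading on the log2 scale from the global
#' peptide-level matrix (before batch correction). Each peptide's log2
#' profile is first referenced to its own median across channels, removing
#' the peptide-to-peptide abundance and ionization-efficiency spread; the
#' loading offset of a channel is then the median of these deviations over
#' peptides, centered so that the median offset is zero. The double median
#' makes the estimate robust to missingness and to differential features
#' (any minority of shifted peptides leaves the channel median untouched),
#' and a channel loaded uniformly 2x above the rest recovers an offset of
#' exactly +1.
#'
#' @param globalPeptides log2-scale peptide-level \linkS4class{OmicsMatrix}
#'   from \code{\link{rollupPeptide}}; must not be batch-corrected.
#' @return named numeric vector of offsets, one per channel id.
#' @export
channelLoadingOffsets <- function(globalPeptides) {
  .assertScale(globalPeptides, "log2")
  if ("bridge_batch_correct" %in% appliedSteps(globalPeptides))
    stop("channel loadings must be estimated from non-batch-corrected data")
  v <- .values(globalPeptides)
  ref <- apply(v, 1L, stats::median, na.rm = TRUE)
  off <- .colMedians(v - ref)
  if (any(is.na(off)))
    stop("channel(s) without observed peptides: ",
         paste(colnames(v)[is.na(off)], collapse = ", "))
  off - stats::median(off)
}

#' Apply channel-loading scaling to site abundances
#'
#' Removes per-channel loading differences estimated by
#' \code{\link{channelLoadingOffsets}}: on log2 scale the offset is
#' subtracted, on linear scale the intensity is divided by \code{2^offset}.
#' The PTM channels are matched to the global-data channels of the same
#' physical plex and reporter label, since the same labelled material was
#' split for global analysis and PTM enrichment.
#'
#' @param sites a \linkS4class{SiteMatrix} (linear or log2).
#' @param offsets named offsets from \code{\link{channelLoadingOffsets}}.
#' @return the scaled matrix.
#' @export
applyLoadingScaling <- function(sites, offsets) {
  info <- channelInfo(sites)
  key <- .chanId(.physPlex(info$plex_id), info$channel_label)
  off_key <- .chanId(.physPlex(sub(":.*$", "", names(offsets))),
                     sub("^[^:]*:", "", names(offsets)))
  idx <- match(key, off_key)
  if (any(is.na(idx)))
    stop("no loading offset for channel(s): ",
         paste(colnames(sites)[is.na(idx)], collapse = ", "))
  off <- unname(offsets)[idx]
  v <- .values(sites)
  if (sites@scale == "log2") {
    v <- sweep(v, 2L, off, "-")
  } else {
    v <- sweep(v, 2L, 2^off, "/")
  }
  .values(sites) <- v
  .recordStep(sites, "apply_loading_scaling")
}

#' Subtract per-condition protein abundance from site abundances
#'
#' Removes protein-level differential signal from normalized PTM site
#' abundances: for every site channel belonging to condition k, the mean
#' normalized abundance of the site's parent protein over condition-k
#' channels is subtracted. Sites whose parent protein was not quantified
#' are left unadjusted and flagged in \code{rowData(sites)$protein_adjusted}.
#'
#' @param sites fully normalized log2 \linkS4class{SiteMatrix} (loading
#'   scaled, median centered, batch corrected).
#' @param proteins fully normalized log2 protein \linkS4class{OmicsMatrix}.
#' @return the adjusted \linkS4class{SiteMatrix} with
#'   \code{isProteinAdjusted(x) == TRUE}.
#' @export
subtractProteinAbundance <- function(sites, proteins) {
  .assertScale(sites, "log2")
  .assertScale(proteins, "log2")
  parent <- .siteProtein(rownames(sites))
  pinfo <- channelInfo(proteins)
  pv <- .values(proteins)
  cond_means <- do.call(cbind, lapply(CONDITIONS, function(k) {
    cols <- which(pinfo$condition == k &
                    pinfo$channel_class %in% c("sample", "bridge"))
    if (!length(cols)) return(rep(NA_real_, nrow(pv)))
    rowMeans(pv[, cols, drop = FALSE], na.rm = TRUE)
  }))
  cond_means[is.nan(cond_means)] <- NA_real_
  dimnames(cond_means) <- list(rownames(pv), CONDITIONS)

  sinfo <- channelInfo(sites)
  v <- .values(sites)
  has_parent <- parent %in% rownames(pv)
  for (j in seq_len(ncol(v))) {
    k <- sinfo$condition[j]
    if (is.na(k)) next                      # pool channels keep raw values
    adj <- rep(NA_real_, nrow(v))
    adj[has_parent] <- cond_means[parent[has_parent], k]
    v[, j] <- v[, j] - ifelse(is.na(adj), 0, adj)
  }
  .values(sites) <- v
  rd <- SummarizedExperiment::rowData(sites)
  rd$protein_adjusted <- has_parent
  SummarizedExperiment::rowData(sites) <- rd
  if (any(!has_parent))
    message("subtractProteinAbundance: ", sum(!has_parent),
            " orphan site(s) left unadjusted")
  sites <- .recordStep(sites, "subtract_protein_abundance")
  sites@adjustedForProtein <- TRUE
  sites
}

#' Percent thiol-oxidation occupancy
#'
#' For every cysteine site and condition, occupancy is 100 x (mean linear
#' intensity of the condition's thiol-oxidation channels) / (mean linear
#' intensity of the pooled total-thiol duplicate channels). It is computed
#' on loading-scaled linear intensities, before log2 transformation and
#' before protein-level adjustment. Ratios are formed within each plex
#' (numerator channels and pool duplicates of the same plex, so residual
#' plex factors cancel) and then averaged across the plexes in which the
#' condition was measured. Per-site multiplicative constants such as
#' peptide ionization efficiency cancel between numerator and denominator.
#'
#' Rows whose denominator is missing or zero are omitted (with a reported
#' count); occupancies above 100 percent can arise under noise and are
#' retained but flagged.
#'
#' @param sites loading-scaled linear \linkS4class{SiteMatrix} of kind
#'   \code{"redox"}.
#' @return data.frame with \code{site_key}, \code{condition},
#'   \code{mean_percent_oxidation}, \code{n_channels} and \code{flagged}
#'   (TRUE when above 100).
#' @export
computeOccupancy <- function(sites) {
  stopifnot(is(sites, "SiteMatrix"))
  if (ptmKind(sites) != "redox")
    stop("occupancy is defined for redox site matrices")
  .assertScale(sites, "linear")
  info <- channelInfo(sites)
  if (!any(info$channel_class == "total_thiol_pool"))
    stop("no total_thiol_pool channels present")
  v <- .values(sites)
  plexes <- unique(info$plex_id)
  out <- list()
  dropped <- 0L
  for (k in CONDITIONS) {
    num <- matrix(NA_real_, nrow(v), length(plexes))
    for (pi in seq_along(plexes)) {
      p <- plexes[pi]
      ox <- which(info$plex_id == p & info$condition == k &
                    info$channel_class %in% c("sample", "bridge"))
      if (!length(ox)) next
      pool <- which(info$plex_id == p &
                      info$channel_class == "total_thiol_pool")
      ox_mean <- rowMeans(v[, ox, drop = FALSE], na.rm = TRUE)
      pool_mean <- rowMeans(v[, pool, drop = FALSE], na.rm = TRUE)
      bad <- is.na(pool_mean) | pool_mean == 0
      ratio <- ifelse(bad, NA_real_, 100 * ox_mean / pool_mean)
      ratio[is.nan(ox_mean)] <- NA_real_
      num[, pi] <- ratio
    }
    occ <- rowMeans(num, na.rm = TRUE)
    n_pl <- rowSums(!is.na(num))
    keep <- n_pl > 0
    dropped <- dropped + sum(!keep)
    out[[k]] <- data.frame(site_key = rownames(v)[keep],
                           condition = rep(k, sum(keep)),
                           mean_percent_oxidation = occ[keep],
                           n_channels = n_pl[keep],
                           flagged = occ[keep] > 100,
                           stringsAsFactors = FALSE)
  }
  if (dropped > 0)
    message("computeOccupancy: ", dropped,
            " site-condition cell(s) omitted (missing/zero denominator)")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full PTM-site normalization chain
#'
#' Runs the fixed site-level order: aggregate, log2, channel-loading
#' scaling, channel median centering, bridge batch correction and (for
#' adjusted output) per-condition protein subtraction. For redox data the
#' loading-scaled linear matrix is also returned, since occupancy is
#' computed at that stage.
#'
#' @inheritParams aggregateSites
#' @param globalPeptides log2 peptide-level global matrix for loading
#'   estimation (see \code{\link{channelLoadingOffsets}}).
#' @param proteins normalized protein matrix, or NULL to skip adjustment.
#' @return list with \code{sites} (normalized, protein-adjusted when
#'   \code{proteins} given), \code{sites_unadjusted} and
#'   \code{sites_linear_scaled} (input to \code{\link{computeOccupancy}}).
#' @export
normalizePTM <- function(psm, designs, kind, globalPeptides,
                         proteins = NULL) {
  raw <- aggregateSites(psm, designs, kind)
  offsets <- channelLoadingOffsets(globalPeptides)
  linear_scaled <- applyLoadingScaling(raw, offsets)
  m <- log2Transform(raw)
  m <- applyLoadingScaling(m, offsets)
  m <- medianCenterChannels(m)
  m <- bridgeBatchCorrect(m)
  unadj <- m
  if (!is.null(proteins)) m <- subtractProteinAbundance(m, proteins)
  list(sites = m, sites_unadjusted = unadj,
       sites_linear_scaled = linear_scaled)
}
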