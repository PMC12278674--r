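#' Build a lipid abundance matrix
#'
#' Converts a lipid table (see \code{\link{readLipidTable}}) into a
#' \linkS4class{LipidMatrix}, recording which cells were missing in the
#' input; the mask is immutable and is used to restore missingness after
#' probabilistic quotient normalization.
#'
#' @param lipids lipid data.frame with \code{lipid_id}, \code{class},
#'   \code{subclass} and sample columns.
#' @param samples optional sample metadata data.frame with
#'   \code{sample_id}, \code{nitrogen}, \code{timepoint_h},
#'   \code{replicate}; when omitted, metadata is parsed from sample ids of
#'   the form \code{"<nitrogen>_<time>_r<rep>"} where possible.
#' @return a linear-scale \linkS4class{LipidMatrix}.
#' @export
lipidMatrix <- function(lipids, samples = NULL) {
  ann_cols <- c("lipid_id", "class", "subclass")
  samp_cols <- setdiff(names(lipids), ann_cols)
  v <- as.matrix(lipids[, samp_cols, drop = FALSE])
  rownames(v) <- lipids$lipid_id
  if (is.null(samples)) {
    pat <- "^(high|low)_(24|48|72)_r([0-9]+)$"
    ok <- grepl(pat, samp_cols)
    samples <- data.frame(
      sample_id = samp_cols,
      nitrogen = ifelse(ok, sub(pat, "\\1", samp_cols), NA),
      timepoint_h = ifelse(ok, as.integer(sub(pat, "\\2", samp_cols)), NA),
      replicate = ifelse(ok, as.integer(sub(pat, "\\3", samp_cols)), NA),
      stringsAsFactors = FALSE)
  }
  samples <- samples[match(samp_cols, samples$sample_id), , drop = FALSE]
  channels <- data.frame(
    plex_id = "lipidomics", channel_label = samp_cols,
    sample_id = samp_cols, nitrogen = samples$nitrogen,
    timepoint_h = as.integer(samples$timepoint_h),
    replicate = as.integer(samples$replicate),
    assay = NA_character_, channel_class = "sample",
    batch = "lipidomics", stringsAsFactors = FALSE)
  channels$condition <- .conditionLabel(channels$nitrogen,
                                        channels$timepoint_h)
  channels$channel_id <- channels$sample_id
  .makeOmicsMatrix(v, channels, scale = "linear", steps = character(),
                   rowData = lipids[, ann_cols],
                   class = "LipidMatrix", missingMask = is.na(v))
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution on the linear scale: missing cells are set
#' to 1 for the computation (the convention applied before
#' log-transformation), the reference spectrum is the per-lipid median over
#' samples, each sample's dilution factor is the median over lipids of its
#' value divided by the reference, and every value is divided by its
#' sample's factor. Originally-missing cells are restored to missing
#' afterwards, so the missingness mask is bit-identical before and after.
#'
#' After normalization the median quotient of every sample against the
#' reference is 1.
#'
#' @param m a linear-scale \linkS4class{LipidMatrix}.
#' @return the normalized matrix; dilution factors are kept in
#'   \code{metadata(m)$pqn_dilution}.
#' @export
pqnNormalize <- function(m) {
  stopifnot(is(m, "LipidMatrix"))
  .assertScale(m, "linear")
  v <- .values(m)
  mask <- missingMask(m)
  all_missing <- colSums(!mask) == 0
  if (any(all_missing))
    stop("sample(s) with all lipids missing: ",
         paste(colnames(v)[all_missing], collapse = ", "))
  v[mask] <- 1
  ref <- apply(v, 1L, stats::median)
  if (any(ref <= 0)) stop("non-positive reference spectrum entries")
  d <- apply(sweep(v, 1L, ref, "/"), 2L, stats::median)
  v <- sweep(v, 2L, d, "/")
  v[mask] <- NA_real_
  .values(m) <- v
  S4Vectors::metadata(m)$pqn_dilution <- d
  .recordStep(m, "pqn_normalize")
}

#' Sum lipid intensities by subclass
#'
#' Summed peak heights per subclass and sample; missing cells contribute
#' zero to the sums, and subclasses with no member lipids are omitted.
#'
#' @param m a linear-scale \linkS4class{LipidMatrix}.
#' @return an \linkS4class{OmicsMatrix}, subclass x sample.
#' @export
sumSubclass <- function(m) {
  stopifnot(is(m, "LipidMatrix"))
  .assertScale(m, "linear")
  v <- .values(m)
  v[is.na(v)] <- 0
  sub <- SummarizedExperiment::rowData(m)$subclass
  sums <- rowsum(v, sub, reorder = TRUE)
  info <- channelInfo(m)
  info$channel_id <- rownames(info)
  .makeOmicsMatrix(sums, info, scale = "linear",
                   steps = c(appliedSteps(m), "sum_subclass"))
}

#' Row z-scaling
#'
#' Scales each feature row to mean zero and unit standard deviation
#' (denominator n - 1), the transform used for subclass heatmaps. Constant
#' rows are an error (named in the message). Missing values are ignored in
#' the row statistics and stay missing.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @return the row-scaled matrix.
#' @export
zscoreRows <- function(m) {
  v <- .values(m)
  mu <- rowMeans(v, na.rm = TRUE)
  sd <- apply(v, 1L, stats::sd, na.rm = TRUE)
  bad <- is.na(sd) | sd == 0
  if (any(bad))
    stop("constant or unobserved row(s): ",
         paste(utils::head(rownames(v)[bad], 5), collapse = ", "))
  .values(m) <- (v - mu) / sd
  .recordStep(m, "zscore_rows")
}

#' Full lipidomics preprocessing chain
#'
#' PQN on linear intensities, then log2 with the missing-as-NA convention:
#' the matrix is returned both ways since subclass sums use linear values.
#'
#' @param lipids lipid table (see \code{\link{readLipidTable}}).
#' @param samples optional sample metadata (see \code{\link{lipidMatrix}}).
#' @return list with \code{linear} (PQN-normalized linear matrix),
#'   \code{log2} (log2 of the same) and \code{subclass} (linear subclass
#'   sums of the normalized data).
#' @export
normalizeLipids <- function(lipids, samples = NULL) {
  m <- lipidMatrix(lipids, samples)
  m <- pqnNormalize(m)
  sub <- sumSubclass(m)
  list(linear = m, log2 = log2Transform(m), subclass = sub)
}
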