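# Internal helpers shared across modules.

# canonical column id for a (plex, channel) pair
.chanId <- function(plex_id, channel_label) paste(plex_id, channel_label,
                                                  sep = ":")

# condition label "high_24" etc.; NA for channels without condition metadata
.conditionLabel <- function(nitrogen, timepoint_h) {
  out <- ifelse(is.na(nitrogen) | is.na(timepoint_h) | nitrogen == "none",
                NA_character_, paste(nitrogen, timepoint_h, sep = "_"))
  out
}

CONDITIONS <- c("high_24", "high_48", "high_72", "low_24", "low_48", "low_72")

# flatten a list of PlexDesign into one channel table with plex_id and
# condition columns; empty channels dropped when quantitativeOnly
.designTable <- function(designs, quantitativeOnly = TRUE) {
  stopifnot(length(designs) >= 1L)
  tabs <- lapply(designs, function(d) {
    ch <- designChannels(d)
    ch$plex_id <- plexId(d)
    ch
  })
  tab <- do.call(rbind, tabs)
  tab$condition <- .conditionLabel(tab$nitrogen, tab$timepoint_h)
  tab$channel_id <- .chanId(tab$plex_id, tab$channel_label)
  if (quantitativeOnly) tab <- tab[tab$channel_class != "empty", , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# build an OmicsMatrix (or subclass) from a values matrix and a channel table
.makeOmicsMatrix <- function(values, channels, scale, steps = character(),
                             rowData = NULL, class = "OmicsMatrix", ...) {
  stopifnot(ncol(values) == nrow(channels))
  colnames(values) <- channels$channel_id
  cd <- S4Vectors::DataFrame(channels[, c("plex_id", "channel_label",
                                          "sample_id", "nitrogen",
                                          "timepoint_h", "replicate",
                                          "assay", "channel_class", "batch",
                                          "condition")],
                             row.names = channels$channel_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values), colData = cd)
  if (!is.null(rowData))
    SummarizedExperiment::rowData(se) <- S4Vectors::DataFrame(rowData)
  new(class, se, scale = scale, appliedSteps = steps, ...)
}

.values <- function(m) SummarizedExperiment::assay(m, "abundance")

`.values<-` <- function(m, value) {
  SummarizedExperiment::assay(m, "abundance") <- value
  m
}

# append a processing step, refusing re-application
.recordStep <- function(m, step) {
  if (step %in% m@appliedSteps)
    stop("step '", step, "' has already been applied (steps so far: ",
         paste(m@appliedSteps, collapse = " -> "), ")", call. = FALSE)
  m@appliedSteps <- c(m@appliedSteps, step)
  m
}

.assertScale <- function(m, scale) {
  if (m@scale != scale)
    stop("expected a ", scale, "-scale matrix but got ", m@scale,
         call. = FALSE)
  invisible(m)
}

# collapse technical replicates: average channels sharing a sample_id.
# Returns list(values = feature x sample matrix, samples = metadata df with
# one row per sample carrying condition).
.collapseBySample <- function(m, classes = c("sample", "bridge")) {
  info <- channelInfo(m)
  keep <- info$channel_class %in% classes & !is.na(info$condition)
  v <- .values(m)[, keep, drop = FALSE]
  info <- info[keep, , drop = FALSE]
  sid <- info$sample_id
  usid <- unique(sid)
  out <- matrix(NA_real_, nrow(v), length(usid),
                dimnames = list(rownames(v), usid))
  for (j in seq_along(usid)) {
    cols <- which(sid == usid[j])
    out[, j] <- rowMeans(v[, cols, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  samples <- info[match(usid, sid),
                  c("sample_id", "nitrogen", "timepoint_h", "replicate",
                    "condition")]
  rownames(samples) <- NULL
  list(values = out, samples = samples)
}

# grouped rowsum that treats NA as absent: a cell is NA only when every
# contributing value is NA
.rowsumSkipNA <- function(values, group) {
  obs <- !is.na(values)
  v0 <- values
  v0[!obs] <- 0
  sums <- rowsum(v0, group, reorder = TRUE)
  counts <- rowsum(obs + 0, group, reorder = TRUE)
  sums[counts == 0] <- NA_real_
  sums
}

.colMedians <- function(values, na.rm = TRUE)
  apply(values, 2L, stats::median, na.rm = na.rm)
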