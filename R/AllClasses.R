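#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

DESIGN_COLUMNS <- c("channel_label", "sample_id", "nitrogen", "timepoint_h",
                    "replicate", "assay", "channel_class", "batch")
CHANNEL_CLASSES <- c("sample", "total_thiol_pool", "bridge", "empty")
NITROGEN_LEVELS <- c("high", "low", "none")
ASSAYS <- c("global", "redox", "phospho")
TIMEPOINTS_H <- c(24L, 48L, 72L)

#' Design of one TMT plex
#'
#' A \code{PlexDesign} maps the reporter channels of one isobaric plex to
#' samples and their metadata: nitrogen condition (high/low), timepoint in
#' hours, biological replicate, assay (global, redox, phospho), channel class
#' and batch. Channel classes distinguish biological samples, bridge channels
#' (24 h technical replicates shared between plexes for batch correction),
#' pooled total-thiol reference channels (the -NEM duplicates used as the
#' occupancy denominator) and skipped "empty" channels that carry no sample.
#'
#' @slot plexId single character identifier of the plex.
#' @slot channels data.frame with one row per used channel and columns
#'   \code{channel_label}, \code{sample_id}, \code{nitrogen},
#'   \code{timepoint_h}, \code{replicate}, \code{assay},
#'   \code{channel_class}, \code{batch}.
#'
#' @section Validity:
#' Channel labels must be unique within the plex; empty channels must carry
#' no sample id; nitrogen/assay/channel-class values must come from their
#' declared vocabularies. Cross-plex rules (bridge sharing, the presence of a
#' total-thiol pool in redox plexes) are checked by
#' \code{\link{validateDesigns}} over a list of plexes.
#'
#' @seealso \code{\link{readDesign}}, \code{\link{validateDesigns}}
#' @export
setClass("PlexDesign",
         representation(plexId = "character", channels = "data.frame"))

.validPlexDesign <- function(object) {
  errs <- character()
  ch <- object@channels
  if (length(object@plexId) != 1L || is.na(object@plexId) ||
      !nzchar(object@plexId))
    errs <- c(errs, "plexId must be a single non-empty string")
  missing_cols <- setdiff(DESIGN_COLUMNS, names(ch))
  if (length(missing_cols))
    return(paste0("missing design columns: ",
                  paste(missing_cols, collapse = ", ")))
  dup <- ch$channel_label[duplicated(ch$channel_label)]
  if (length(dup))
    errs <- c(errs, paste0("plex '", object@plexId,
                           "': duplicate channel label(s): ",
                           paste(unique(dup), collapse = ", ")))
  bad_class <- setdiff(unique(ch$channel_class), CHANNEL_CLASSES)
  if (length(bad_class))
    errs <- c(errs, paste0("plex '", object@plexId,
                           "': unknown channel_class: ",
                           paste(bad_class, collapse = ", ")))
  empty_with_sample <- ch$channel_class == "empty" &
    !is.na(ch$sample_id) & nzchar(ch$sample_id)
  if (any(empty_with_sample))
    errs <- c(errs, paste0("plex '", object@plexId, "': empty channel(s) ",
                           paste(ch$channel_label[empty_with_sample],
                                 collapse = ", "),
                           " carry a sample_id"))
  nonempty <- ch$channel_class != "empty"
  if (any(nonempty & (is.na(ch$sample_id) | !nzchar(ch$sample_id))))
    errs <- c(errs, paste0("plex '", object@plexId,
                           "': non-empty channel(s) lack a sample_id"))
  bad_n <- !is.na(ch$nitrogen) & !(ch$nitrogen %in% NITROGEN_LEVELS)
  if (any(bad_n))
    errs <- c(errs, paste0("plex '", object@plexId, "': invalid nitrogen: ",
                           paste(unique(ch$nitrogen[bad_n]), collapse = ", ")))
  bad_a <- !is.na(ch$assay) & !(ch$assay %in% ASSAYS)
  if (any(bad_a))
    errs <- c(errs, paste0("plex '", object@plexId, "': invalid assay: ",
                           paste(unique(ch$assay[bad_a]), collapse = ", ")))
  bad_t <- !is.na(ch$timepoint_h) & !(ch$timepoint_h %in% TIMEPOINTS_H)
  if (any(bad_t))
    errs <- c(errs, paste0("plex '", object@plexId,
                           "': timepoint_h outside {24,48,72}"))
  if (length(errs)) errs else TRUE
}
setValidity("PlexDesign", .validPlexDesign)

#' @describeIn PlexDesign construct a plex design from a channel table.
#' @param plexId plex identifier.
#' @param channels channel metadata data.frame (see slots).
#' @export
PlexDesign <- function(plexId, channels) {
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  for (col in setdiff(DESIGN_COLUMNS, names(channels))) {
    channels[[col]] <- if (col %in% c("timepoint_h", "replicate")) NA_integer_
                       else NA_character_
  }
  channels <- channels[, DESIGN_COLUMNS]
  channels$timepoint_h <- as.integer(channels$timepoint_h)
  channels$replicate <- as.integer(channels$replicate)
  rownames(channels) <- NULL
  new("PlexDesign", plexId = as.character(plexId), channels = channels)
}

setMethod("show", "PlexDesign", function(object) {
  ch <- object@channels
  cat("PlexDesign '", object@plexId, "': ", nrow(ch), " channels (",
      sum(ch$channel_class != "empty"), " quantitative)\n", sep = "")
  tab <- table(ch$channel_class)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' Feature-by-channel abundance container
#'
#' \code{OmicsMatrix} extends \linkS4class{SummarizedExperiment} with a scale
#' flag (\code{"linear"} or \code{"log2"}) and an append-only record of the
#' normalization steps applied, so each transform can assert its
#' preconditions (e.g. log2 transform requires linear input; no step runs
#' twice). Column metadata carries the per-channel design fields
#' (\code{plex_id}, \code{channel_label}, \code{sample_id}, \code{nitrogen},
#' \code{timepoint_h}, \code{replicate}, \code{assay}, \code{channel_class},
#' \code{batch}, \code{condition}).
#'
#' @slot scale \code{"linear"} or \code{"log2"}.
#' @slot appliedSteps character vector of applied processing step names.
#' @export
setClass("OmicsMatrix",
         contains = "SummarizedExperiment",
         representation(scale = "character", appliedSteps = "character"))

setValidity("OmicsMatrix", function(object) {
  errs <- character()
  if (length(object@scale) != 1L || !(object@scale %in% c("linear", "log2")))
    errs <- c(errs, "scale must be 'linear' or 'log2'")
  need <- c("plex_id", "channel_label", "channel_class", "condition")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    errs <- c(errs, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if (length(errs)) errs else TRUE
})

#' PTM site abundance container
#'
#' An \linkS4class{OmicsMatrix} whose features are PTM site keys
#' (\code{"<protein>_<AA><pos>[;<AA><pos>...]"}). \code{ptmKind} records the
#' enrichment (redox or phospho); \code{adjustedForProtein} becomes TRUE only
#' after \code{\link{subtractProteinAbundance}}.
#'
#' @slot ptmKind \code{"redox"} or \code{"phospho"}.
#' @slot adjustedForProtein logical scalar.
#' @export
setClass("SiteMatrix",
         contains = "OmicsMatrix",
         representation(ptmKind = "character",
                        adjustedForProtein = "logical"))

setValidity("SiteMatrix", function(object) {
  errs <- character()
  if (!(object@ptmKind %in% c("redox", "phospho")))
    errs <- c(errs, "ptmKind must be 'redox' or 'phospho'")
  if (length(object@adjustedForProtein) != 1L ||
      is.na(object@adjustedForProtein))
    errs <- c(errs, "adjustedForProtein must be TRUE or FALSE")
  if (object@adjustedForProtein &&
      !("subtract_protein_abundance" %in% object@appliedSteps))
    errs <- c(errs,
              "adjustedForProtein without a subtract_protein_abundance step")
  if (length(errs)) errs else TRUE
})

#' Lipid abundance container
#'
#' An \linkS4class{OmicsMatrix} over lipid species, retaining class/subclass
#' annotation in \code{rowData} and an immutable mask of the cells that were
#' missing (blank or zero peak height) in the input, so probabilistic
#' quotient normalization can impute-for-computation and then restore
#' missingness exactly.
#'
#' @slot missingMask logical matrix, same dimensions as the assay.
#' @export
setClass("LipidMatrix",
         contains = "OmicsMatrix",
         representation(missingMask = "matrix"))

setValidity("LipidMatrix", function(object) {
  if (!identical(dim(object@missingMask), dim(object)))
    return("missingMask dimensions differ from assay dimensions")
  if (!is.logical(object@missingMask))
    return("missingMask must be logical")
  need <- c("class", "subclass")
  miss <- setdiff(need, colnames(SummarizedExperiment::rowData(object)))
  if (length(miss))
    return(paste0("rowData lacks: ", paste(miss, collapse = ", ")))
  TRUE
})

setMethod("show", "OmicsMatrix", function(object) {
  cat(class(object), ": ", nrow(object), " features x ", ncol(object),
      " channels [", object@scale, "]\n", sep = "")
  if (length(object@appliedSteps))
    cat("  steps: ", paste(object@appliedSteps, collapse = " -> "), "\n",
        sep = "")
  cls <- table(SummarizedExperiment::colData(object)$channel_class)
  cat("  channels:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SiteMatrix", function(object) {
  callNextMethod()
  cat("  ptm: ", object@ptmKind, "; protein-adjusted: ",
      object@adjustedForProtein, "\n", sep = "")
})

# keep the missingness mask aligned under subsetting
setMethod("[", c("LipidMatrix", "ANY", "ANY"),
          function(x, i, j, ..., drop = FALSE) {
  mask <- x@missingMask
  if (!missing(i)) mask <- mask[i, , drop = FALSE]
  if (!missing(j)) mask <- mask[, j, drop = FALSE]
  out <- callNextMethod()
  out@missingMask <- mask
  out
})
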