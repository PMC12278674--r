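#' Per-condition mean abundances
#'
#' Averages replicate channels per condition (technical replicates are
#' collapsed by sample first, so bridge channels measured in both plexes
#' count once); missing replicates are skipped. The six columns are the
#' 2 x 3 nitrogen-by-time grid in fixed order.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @param conditions condition columns to report (default the full grid).
#' @return a numeric matrix, features x conditions.
#' @export
conditionMeans <- function(m, conditions = CONDITIONS) {
  cl <- .collapseBySample(m)
  out <- sapply(conditions, function(k) {
    cols <- which(cl$samples$condition == k)
    if (!length(cols))
      stop("no observed replicates for condition '", k, "'")
    rowMeans(cl$values[, cols, drop = FALSE], na.rm = TRUE)
  })
  out[is.nan(out)] <- NA_real_
  rownames(out) <- rownames(cl$values)
  out
}

#' Correlate cysteine-site abundances with lipid subclass trajectories
#'
#' Pearson correlation, over the per-condition means, of every (site,
#' lipid subclass) pair: the systems-level link between thiol-oxidation
#' state and lipid class dynamics. Both inputs must cover the identical
#' conditions in the same order, with at least three conditions. Rows with
#' zero variance in either vector have undefined correlation and are
#' omitted (with a reported count).
#'
#' @param siteMeans site x condition matrix (see
#'   \code{\link{conditionMeans}}).
#' @param lipidMeans subclass x condition matrix on the same conditions.
#' @return data.frame with \code{site_key}, \code{target},
#'   \code{pearson_r}, \code{n_conditions}.
#' @export
correlateSitesLipids <- function(siteMeans, lipidMeans) {
  if (!identical(colnames(siteMeans), colnames(lipidMeans)))
    stop("condition columns must match exactly (same order)")
  if (ncol(siteMeans) < 3)
    stop("need >= 3 conditions for a reported correlation")
  ok_site <- apply(siteMeans, 1L, function(x)
    all(is.finite(x)) && stats::sd(x) > 0)
  ok_lip <- apply(lipidMeans, 1L, function(x)
    all(is.finite(x)) && stats::sd(x) > 0)
  n_drop <- sum(!ok_site) + sum(!ok_lip)
  if (n_drop > 0)
    message("correlateSitesLipids: ", sum(!ok_site), " site row(s) and ",
            sum(!ok_lip), " lipid row(s) omitted (missing or constant)")
  sm <- siteMeans[ok_site, , drop = FALSE]
  lm_ <- lipidMeans[ok_lip, , drop = FALSE]
  r <- stats::cor(t(sm), t(lm_), method = "pearson")
  data.frame(site_key = rep(rownames(sm), times = ncol(r)),
             target = rep(colnames(r), each = nrow(r)),
             pearson_r = as.vector(r),
             n_conditions = ncol(sm), stringsAsFactors = FALSE)
}

#' Select sites correlated with storage-lipid accumulation
#'
#' Applies the integration rule: cysteine sites whose per-condition
#' abundance profile has Pearson r above the cutoff (default 0.80) against
#' the TG and DG subclass trajectories -- by default the conjunction of
#' both, \code{mode = "any"} for the union -- and whose absolute log2 fold
#' change for the nitrogen coefficient is at least the PTM cutoff
#' (default 0.8). The returned ids feed hypergeometric ORA against the
#' full quantified-site universe.
#'
#' @param corr correlation data.frame from
#'   \code{\link{correlateSitesLipids}}.
#' @param diff differential results for the nitrogen coefficient
#'   (\code{\link{fitFactorial}}).
#' @param cfg a \code{\link{filterConfig}}.
#' @param targets lipid subclasses to correlate against.
#' @param mode require r above cutoff for all targets or for any.
#' @return character vector of selected site keys.
#' @export
selectCorrelatedSites <- function(corr, diff, cfg = filterConfig(),
                                  targets = c("TG", "DG"),
                                  mode = c("all", "any")) {
  mode <- match.arg(mode)
  sub <- corr[corr$target %in% targets, , drop = FALSE]
  pass <- tapply(sub$pearson_r > cfg$pearson_min, sub$site_key,
                 if (mode == "all") all else any)
  n_targets <- tapply(sub$target, sub$site_key,
                      function(x) length(unique(x)))
  ok <- names(pass)[pass & (mode == "any" | n_targets == length(targets))]
  lfc <- diff$log2FC[match(ok, diff$feature_id)]
  sort(ok[!is.na(lfc) & abs(lfc) >= cfg$lfc_min_ptm])
}
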