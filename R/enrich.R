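#' Hypergeometric over-representation analysis
#'
#' Exact upper-tail hypergeometric test of a selected id list against each
#' set of a collection, within a declared universe: with N universe ids, K
#' set members in the universe, n selected ids and k selected set members,
#' p = P(X >= k) for X ~ Hypergeometric(N, K, n). Sets smaller than
#' \code{minSetSize} after intersection with the universe are skipped.
#' BH-adjusted p and Storey q-values are computed across the tested sets.
#'
#' @param selected character vector of selected ids (subset of universe).
#' @param sets named list of member-id vectors (see \code{\link{readGMT}}),
#'   or a single character vector for one set.
#' @param universe character vector of all quantifiable ids.
#' @param minSetSize minimum in-universe set size (default 2).
#' @return data.frame with \code{set_name}, \code{overlap_k},
#'   \code{set_size_K}, \code{selected_n}, \code{universe_N}, \code{p},
#'   \code{adj_p}, \code{q}.
#' @export
oraHypergeometric <- function(selected, sets, universe, minSetSize = 2L) {
  if (!length(universe)) stop("empty universe")
  if (!length(selected)) stop("empty selection")
  universe <- unique(universe)
  selected <- unique(selected)
  if (length(setdiff(selected, universe)))
    stop("selected ids outside the universe: ",
         paste(utils::head(setdiff(selected, universe), 5), collapse = ", "))
  if (!is.list(sets)) sets <- list(set = sets)
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    K <- length(members)
    if (K < minSetSize) return(NULL)
    k <- length(intersect(selected, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_k = k, set_size_K = K,
               selected_n = n, universe_N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no set reaches the minimum size in the universe")
  res$adj_p <- bhAdjust(res$p)
  res$q <- storeyQ(res$p)
  rownames(res) <- NULL
  res
}

#' Rank-based set enrichment test
#'
#' Two-sided Wilcoxon rank-sum comparison of set members' log2 fold
#' changes against non-members, the rank-based statistic used for lipid
#' set enrichment over a fold-change ranking. The p-value is exact (by
#' enumeration of the rank-sum distribution) when the total number of
#' scored features is at most 12 and there are no ties; otherwise the
#' normal approximation with continuity correction is used. Direction is
#' the sign of the difference in median ranks (up = members ranked
#' higher). If members and non-members are completely tied, p = 1.
#'
#' @param scores named numeric vector, feature -> log2FC.
#' @param sets named list of member-id vectors, or one character vector.
#' @param minSetSize minimum number of members with scores.
#' @return data.frame with \code{set_name}, \code{overlap_k},
#'   \code{set_size_K}, \code{selected_n} (members scored),
#'   \code{universe_N} (features scored), \code{p}, \code{adj_p},
#'   \code{q}, \code{direction}.
#' @export
rankSetTest <- function(scores, sets, minSetSize = 2L) {
  if (is.null(names(scores))) stop("scores must be named by feature id")
  scores <- scores[!is.na(scores)]
  if (!is.list(sets)) sets <- list(set = sets)
  total <- length(scores)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), names(scores))
    if (length(members) < minSetSize) return(NULL)
    if (length(members) == total) return(NULL)   # no complement to rank
    x <- scores[members]
    y <- scores[setdiff(names(scores), members)]
    if (length(unique(c(x, y))) == 1L) {
      p <- 1
      dir <- "two-sided"
    } else {
      exact <- total <= 12 && !anyDuplicated(c(x, y))
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = exact, correct = TRUE))
      p <- wt$p.value
      r <- rank(c(x, y))
      dmed <- stats::median(r[seq_along(x)]) -
        stats::median(r[-seq_along(x)])
      dir <- if (dmed > 0) "up" else if (dmed < 0) "down" else "two-sided"
    }
    data.frame(set_name = nm, overlap_k = length(members),
               set_size_K = length(unique(sets[[nm]])),
               selected_n = length(members), universe_N = total,
               p = p, direction = dir, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no set reaches the minimum size among the scores")
  res$adj_p <- bhAdjust(res$p)
  res$q <- storeyQ(res$p)
  rownames(res) <- NULL
  res[, c("set_name", "overlap_k", "set_size_K", "selected_n",
          "universe_N", "p", "adj_p", "q", "direction")]
}

#' Report enrichments passing the joint cutoffs
#'
#' Applies the reporting rule for enrichment tables: q-value <= 0.2 and
#' BH-adjusted p <= 0.05, jointly.
#'
#' @param res enrichment data.frame with \code{adj_p} and \code{q}.
#' @param cfg a \code{\link{filterConfig}}.
#' @return the filtered data.frame.
#' @export
reportEnrichment <- function(res, cfg = filterConfig()) {
  res[res$adj_p <= cfg$adj_p_max & res$q <= cfg$q_max_enrich, ,
      drop = FALSE]
}

#' Threshold differential results for enrichment input
#'
#' \code{keggInputFilter} selects features with BH-adjusted p <= 0.05 and
#' |log2FC| >= 1 (the over-representation input rule);
#' \code{mseaInputFilter} uses the stricter |log2FC| >= 4 rule for
#' metabolite-set ORA. Both cutoffs are inclusive.
#'
#' @param diff a differential result data.frame (\code{feature_id},
#'   \code{log2FC}, \code{adj_p}).
#' @param cfg a \code{\link{filterConfig}}.
#' @return character vector of selected feature ids.
#' @export
keggInputFilter <- function(diff, cfg = filterConfig()) {
  unique(diff$feature_id[diff$adj_p <= cfg$adj_p_max &
                           abs(diff$log2FC) >= cfg$lfc_min_kegg_input])
}

#' @rdname keggInputFilter
#' @export
mseaInputFilter <- function(diff, cfg = filterConfig()) {
  unique(diff$feature_id[diff$adj_p <= cfg$adj_p_max &
                           abs(diff$log2FC) >= cfg$lfc_min_msea])
}
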