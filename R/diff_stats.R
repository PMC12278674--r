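#' Filter features on biological-replicate support
#'
#' Keeps features observed (non-missing) in at least \code{k} biological
#' replicates of at least one of the tested conditions. Technical
#' replicates (bridge channels measured in both plexes) count once: support
#' is the number of distinct sample ids with an observed value.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @param conditions conditions defining the tested contrast; default all.
#' @param k minimum biological replicates (default 2, the study's rule).
#' @return the filtered matrix.
#' @export
filterMinReps <- function(m, conditions = CONDITIONS, k = 2L) {
  stopifnot(k >= 1L)
  cl <- .collapseBySample(m)
  keep_cond <- cl$samples$condition %in% conditions
  support <- matrix(0L, nrow(m), length(conditions))
  for (i in seq_along(conditions)) {
    cols <- which(cl$samples$condition == conditions[i])
    support[, i] <- rowSums(!is.na(cl$values[, cols, drop = FALSE]))
  }
  keep <- apply(support, 1L, max) >= k
  m[keep, ]
}

#' Empirical-Bayes variance moderation prior
#'
#' Fits a scaled inverse-chi-square prior to the observed per-feature
#' residual variances by method of moments on log s^2: the mean and
#' variance of log s^2 are corrected by digamma/trigamma terms of the
#' residual degrees of freedom, and the prior degrees of freedom d0 solve
#' trigamma(d0/2) = excess variance via a monotone Newton iteration
#' (to |delta| < 1e-8). When the spread of log s^2 does not exceed its
#' theoretical sampling variance, d0 is +Inf and all variances shrink to
#' the common value s0^2.
#'
#' @param s2 numeric vector of residual variances (>= 10 finite values).
#' @param df residual degrees of freedom (scalar or per-feature).
#' @return list of class \code{"ModerationPrior"} with \code{d0} and
#'   \code{s0_sq}.
#' @export
estimatePrior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df >= 1
  if (sum(ok) < 10)
    stop("need >= 10 features with positive variance and df >= 1")
  if (all(s2[is.finite(s2)] == 0)) stop("all residual variances are zero")
  s2 <- s2[ok]; df <- df[ok]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) * (length(e) - 1) / length(e) -
    mean(trigamma(df / 2))
  if (is.na(evar) || evar <= 0) {
    # no excess spread beyond sampling noise: infinite prior df, and the
    # common variance is estimated by the plain mean
    prior <- list(d0 = Inf, s0_sq = mean(s2))
  } else {
    d0 <- 2 * .trigammaInverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    prior <- list(d0 = d0, s0_sq = s0_sq)
  }
  structure(prior, class = "ModerationPrior")
}

# Newton inversion of trigamma on (0, Inf); trigamma is strictly decreasing
.trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-8) break
  }
  y
}

.moderate <- function(s2, df, prior) {
  if (is.null(prior)) return(list(s2 = s2, df = df))
  if (is.infinite(prior$d0))
    return(list(s2 = rep(prior$s0_sq, length(s2)), df = rep(Inf, length(s2))))
  list(s2 = (prior$d0 * prior$s0_sq + df * s2) / (prior$d0 + df),
       df = df + prior$d0)
}

.tPValue <- function(t, df) {
  p <- ifelse(is.infinite(df), 2 * stats::pnorm(-abs(t)),
              2 * stats::pt(-abs(t), df))
  # infinite t from exact fits underflows to 0; keep p in (0, 1]
  p <- pmax(p, .Machine$double.xmin)
  p[is.na(t)] <- NA_real_
  p
}

#' Moderated two-group differential test
#'
#' Per-feature two-sample comparison on log2 data with optional
#' empirical-Bayes variance moderation: log2FC = mean(A) - mean(B), the
#' pooled variance is shrunk towards the prior, and the t statistic is
#' referred to a t distribution with d0 + df degrees of freedom. With
#' \code{prior = NULL} this is the ordinary Student test. Technical
#' replicates are collapsed by sample before testing, and features with
#' fewer than two samples per group are skipped (counted in the
#' \code{skipped} attribute).
#'
#' @param m log2-scale \linkS4class{OmicsMatrix}.
#' @param groupA,groupB condition labels (e.g. \code{"low_72"} vs
#'   \code{"high_72"}: log2FC is A minus B).
#' @param prior a \code{"ModerationPrior"}, \code{"auto"} to estimate one
#'   from all testable features, or NULL for no moderation.
#' @param adjust apply Benjamini-Hochberg adjustment across features.
#' @return data.frame with \code{feature_id}, \code{contrast},
#'   \code{log2FC}, \code{t_stat}, \code{df}, \code{p}, \code{adj_p},
#'   \code{n_A}, \code{n_B}.
#' @export
moderatedTwoGroup <- function(m, groupA, groupB, prior = "auto",
                              adjust = TRUE) {
  .assertScale(m, "log2")
  cl <- .collapseBySample(m)
  a_cols <- which(cl$samples$condition == groupA)
  b_cols <- which(cl$samples$condition == groupB)
  if (!length(a_cols) || !length(b_cols))
    stop("unknown group label(s): ", groupA, " / ", groupB)
  va <- cl$values[, a_cols, drop = FALSE]
  vb <- cl$values[, b_cols, drop = FALSE]
  nA <- rowSums(!is.na(va)); nB <- rowSums(!is.na(vb))
  testable <- nA >= 2 & nB >= 2
  mA <- rowMeans(va, na.rm = TRUE); mB <- rowMeans(vb, na.rm = TRUE)
  sA <- apply(va, 1L, stats::var, na.rm = TRUE)
  sB <- apply(vb, 1L, stats::var, na.rm = TRUE)
  df <- nA + nB - 2
  s2 <- ((nA - 1) * sA + (nB - 1) * sB) / df
  if (identical(prior, "auto"))
    prior <- estimatePrior(s2[testable], df[testable])
  mod <- .moderate(s2, df, prior)
  se <- sqrt(mod$s2 * (1 / nA + 1 / nB))
  lfc <- mA - mB
  t <- lfc / se
  t[se == 0 & lfc == 0] <- 0
  p <- .tPValue(t, mod$df)
  p[se == 0 & lfc == 0] <- 1
  res <- data.frame(feature_id = rownames(cl$values),
                    contrast = paste(groupA, "vs", groupB),
                    log2FC = lfc, t_stat = t, df = mod$df, p = p,
                    adj_p = NA_real_, n_A = nA, n_B = nB,
                    stringsAsFactors = FALSE)
  res <- res[testable, , drop = FALSE]
  if (adjust && nrow(res)) res$adj_p <- bhAdjust(res$p)
  attr(res, "skipped") <- sum(!testable)
  attr(res, "prior") <- prior
  rownames(res) <- NULL
  res
}

#' Factorial nitrogen-by-time linear model
#'
#' Per-feature ordinary least squares for the design
#' \code{~ Nitrogen + Time + Nitrogen:Time}, with nitrogen coded 0 = high,
#' 1 = low and time either numeric in hours centered at 24 (default) or
#' categorical. Coefficient standard errors are moderated with a shared
#' empirical-Bayes prior on the residual variance. Exact-fit features
#' (zero residual variance, no prior) report t = 0, p = 1 for zero
#' coefficients.
#'
#' @inheritParams moderatedTwoGroup
#' @param timeCoding \code{"numeric"} or \code{"categorical"}.
#' @return data.frame of per-coefficient results (one block per
#'   non-intercept coefficient), columns as in
#'   \code{\link{moderatedTwoGroup}} with \code{contrast} naming the
#'   coefficient (\code{"Nitrogen"}, \code{"Time"}, \code{"Nitrogen:Time"}).
#' @export
fitFactorial <- function(m, prior = "auto",
                         timeCoding = c("numeric", "categorical"),
                         adjust = TRUE) {
  timeCoding <- match.arg(timeCoding)
  .assertScale(m, "log2")
  cl <- .collapseBySample(m)
  s <- cl$samples
  keep <- !is.na(s$condition)
  s <- s[keep, , drop = FALSE]
  v <- cl$values[, keep, drop = FALSE]
  N <- as.numeric(s$nitrogen == "low")
  if (timeCoding == "numeric") {
    Tc <- s$timepoint_h - 24
    X <- cbind(`(Intercept)` = 1, Nitrogen = N, Time = Tc,
               `Nitrogen:Time` = N * Tc)
  } else {
    Tf <- factor(s$timepoint_h)
    X <- stats::model.matrix(~ N * Tf)
    colnames(X) <- sub("^N$", "Nitrogen", colnames(X))
  }
  if (length(unique(s$condition)) < 4)
    stop("factorial fit needs >= 4 distinct design cells")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design; aliased column(s): ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "))
  coefs <- colnames(X)[-1]
  nfeat <- nrow(v)
  beta <- se_unit <- matrix(NA_real_, nfeat, length(coefs),
                            dimnames = list(rownames(v), coefs))
  s2 <- dfres <- rep(NA_real_, nfeat)
  for (i in seq_len(nfeat)) {
    obs <- !is.na(v[i, ])
    if (sum(obs) < ncol(X) + 1) next
    Xi <- X[obs, , drop = FALSE]
    if (qr(Xi)$rank < ncol(X)) next
    fit <- stats::lm.fit(Xi, v[i, obs])
    dfres[i] <- sum(obs) - ncol(X)
    s2[i] <- sum(fit$residuals^2) / dfres[i]
    XtXinv <- chol2inv(chol(crossprod(Xi)))
    beta[i, ] <- fit$coefficients[coefs]
    se_unit[i, ] <- sqrt(diag(XtXinv)[-1])
  }
  testable <- !is.na(s2)
  if (identical(prior, "auto"))
    prior <- estimatePrior(s2[testable], dfres[testable])
  mod <- .moderate(s2, dfres, prior)
  out <- list()
  # exact fits (zero residual variance up to round-off) get the degenerate
  # convention: zero coefficients are t = 0, p = 1; non-zero ones t = +-Inf
  zero_fit <- !is.na(s2) & s2 <= 1e-20
  for (cc in coefs) {
    se <- se_unit[, cc] * sqrt(mod$s2)
    t <- beta[, cc] / se
    null_beta <- abs(beta[, cc]) < 1e-8
    t[zero_fit & null_beta] <- 0
    t[zero_fit & !null_beta] <- sign(beta[zero_fit & !null_beta, cc]) * Inf
    p <- .tPValue(t, mod$df)
    p[zero_fit & null_beta] <- 1
    res <- data.frame(feature_id = rownames(v), contrast = cc,
                      log2FC = beta[, cc], t_stat = t, df = mod$df, p = p,
                      adj_p = NA_real_,
                      n_A = rowSums(!is.na(v)), n_B = NA_integer_,
                      stringsAsFactors = FALSE)
    res <- res[testable, , drop = FALSE]
    if (adjust && nrow(res)) res$adj_p <- bhAdjust(res$p)
    out[[cc]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "prior") <- prior
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: p-values must lie in (0, 1];
#' the adjusted values are monotone in the sorted order and returned in the
#' input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Storey q-values with fixed lambda
#'
#' pi0 is estimated as min(1, #\{p > lambda\} / ((1 - lambda) m)) at
#' lambda = 0.5 and multiplies the BH step-up values.
#'
#' @param p p-values in (0, 1].
#' @param lambda tuning constant (default 0.5).
#' @return q-values.
#' @export
storeyQ <- function(p, lambda = 0.5) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * length(p)))
  pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}
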