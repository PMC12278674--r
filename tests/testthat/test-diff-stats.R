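twoGroupMatrix <- function(a, b, extra = NULL) {
  vals <- rbind(c(a, b), extra)
  makeTestMatrix(vals, conditions = rep(c("low_72", "high_72"),
                                        c(length(a), length(b))))
}

test_that("replicate filtering keeps features with >= k supported samples", {
  vals <- rbind(c(1, NA, NA, 2, 3, 4),    # 1 rep in low, 3 in high -> keep
                c(1, 2, NA, NA, NA, NA),  # 2 in low only -> keep
                c(1, NA, NA, 2, NA, NA))  # 1 and 1 -> drop
  m <- makeTestMatrix(vals, conditions = rep(c("low_72", "high_72"),
                                             each = 3))
  kept <- filterMinReps(m, conditions = c("low_72", "high_72"), k = 2)
  expect_equal(rownames(kept), c("f1", "f2"))
  expect_equal(nrow(filterMinReps(m, k = 1)), 3)
  # technical replicates (same sample in two plexes) count once
  tech <- makeTestMatrix(matrix(c(1, 1, 5), 1),
                         conditions = "low_24",
                         plex = c("p1", "p2", "p1"),
                         classes = c("bridge", "bridge", "sample"),
                         sample_ids = c("low_24_r1", "low_24_r1",
                                        "low_24_r2"))
  expect_equal(nrow(filterMinReps(tech, conditions = "low_24", k = 2)), 1)
  expect_equal(nrow(filterMinReps(tech, conditions = "low_24", k = 3)), 0)
})

test_that("the unmoderated two-group test matches the textbook t-test", {
  m <- twoGroupMatrix(c(0, 1, 2), c(3, 4, 5))
  res <- moderatedTwoGroup(m, "low_72", "high_72", prior = NULL)
  oracle <- t.test(c(0, 1, 2), c(3, 4, 5), var.equal = TRUE)
  expect_equal(res$log2FC, -3)
  expect_equal(res$t_stat, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-10)
  expect_equal(res$n_A, 3)
  expect_equal(res$n_B, 3)
})

test_that("identical groups give zero fold change and p = 1", {
  m <- twoGroupMatrix(c(2, 3, 4), c(2, 3, 4))
  res <- moderatedTwoGroup(m, "low_72", "high_72", prior = NULL)
  expect_equal(res$log2FC, 0)
  expect_equal(res$p, 1)
})

test_that("moderation limits behave: d0 = 0 is ordinary, d0 = Inf plugs s0", {
  set.seed(21)
  extra <- matrix(rnorm(60 * 6), 60)
  m <- twoGroupMatrix(c(0, 1.2, 2.1), c(2.9, 4, 5.2), extra)
  ord <- moderatedTwoGroup(m, "low_72", "high_72", prior = NULL)
  d0zero <- moderatedTwoGroup(m, "low_72", "high_72",
                              prior = structure(list(d0 = 0, s0_sq = 99),
                                                class = "ModerationPrior"))
  expect_equal(d0zero$t_stat, ord$t_stat, tolerance = 1e-10)
  expect_equal(d0zero$p, ord$p, tolerance = 1e-10)

  s0 <- 0.7
  inf <- moderatedTwoGroup(m, "low_72", "high_72",
                           prior = structure(list(d0 = Inf, s0_sq = s0),
                                             class = "ModerationPrior"))
  expect_equal(inf$t_stat, inf$log2FC / sqrt(s0 * (2 / 3)),
               tolerance = 1e-12)
})

test_that("skipped features (fewer than two replicates) are counted", {
  vals <- rbind(c(1, 2, 3, 4, 5, 6), c(1, NA, NA, 4, 5, 6))
  m <- makeTestMatrix(vals, conditions = rep(c("low_72", "high_72"),
                                             each = 3))
  res <- moderatedTwoGroup(m, "low_72", "high_72", prior = NULL)
  expect_equal(nrow(res), 1)
  expect_equal(attr(res, "skipped"), 1)
})

test_that("the moderation prior is recovered from simulated variances", {
  # all variances equal -> d0 = Inf with s0 the common value
  flat <- estimatePrior(rep(0.3, 50), df = 4)
  expect_true(is.infinite(flat$d0))
  expect_equal(flat$s0_sq, 0.3, tolerance = 1e-9)

  set.seed(31)
  d0 <- 4; s0 <- 0.05; dfres <- 4; n <- 5000
  sigma2 <- d0 * s0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, dfres) / dfres
  fit <- estimatePrior(s2, dfres)
  expect_lt(abs(fit$d0 - d0) / d0, 0.2)
  expect_lt(abs(fit$s0_sq - s0) / s0, 0.2)
  # agrees with the independent empirical-Bayes reference implementation
  ref <- limma::fitFDist(s2, df1 = dfres)
  expect_equal(fit$d0, ref$df2, tolerance = 0.05)
  expect_equal(fit$s0_sq, ref$scale, tolerance = 0.05)
})

test_that("the factorial model recovers exact linear truth", {
  # y = b0 + bN N + bT Tc + bNT N Tc, no noise
  s <- expand.grid(rep = 1:3, t = c(24, 48, 72), n = c("high", "low"),
                   stringsAsFactors = FALSE)
  conds <- paste(s$n, s$t, sep = "_")
  N <- as.numeric(s$n == "low"); Tc <- s$t - 24
  b <- c(b0 = 5, bN = 1.5, bT = 0.02, bNT = -0.01)
  y1 <- b["b0"] + b["bN"] * N + b["bT"] * Tc + b["bNT"] * N * Tc
  y2 <- 3 + 0 * N + 0.05 * Tc + 0 * N * Tc     # zero interaction truth
  m <- makeTestMatrix(rbind(f1 = y1, f2 = y2), conditions = conds)
  res <- fitFactorial(m, prior = NULL)
  r1 <- res[res$feature_id == "f1", ]
  expect_equal(r1$log2FC[r1$contrast == "Nitrogen"], 1.5, tolerance = 1e-9)
  expect_equal(r1$log2FC[r1$contrast == "Time"], 0.02, tolerance = 1e-9)
  expect_equal(r1$log2FC[r1$contrast == "Nitrogen:Time"], -0.01,
               tolerance = 1e-9)
  r2 <- res[res$feature_id == "f2", ]
  # exact fit with a zero coefficient: t = 0, p = 1 by convention
  expect_equal(r2$t_stat[r2$contrast == "Nitrogen:Time"], 0)
  expect_equal(r2$p[r2$contrast == "Nitrogen:Time"], 1)
})

test_that("aliased factorial designs are rejected with the column named", {
  conds <- c("high_24", "high_48", "high_72", "low_24")
  m <- makeTestMatrix(matrix(rnorm(2 * 12), 2),
                      conditions = rep(conds, each = 3))
  expect_error(fitFactorial(m, prior = NULL), "Nitrogen:Time")
})

test_that("the nitrogen coefficient is unbiased at realistic noise", {
  set.seed(41)
  s <- expand.grid(rep = 1:3, t = c(24, 48, 72), n = c("high", "low"),
                   stringsAsFactors = FALSE)
  conds <- paste(s$n, s$t, sep = "_")
  N <- as.numeric(s$n == "low")
  vals <- t(sapply(1:1000, function(i) 1 * N + rnorm(18, 0, 0.25)))
  m <- makeTestMatrix(vals, conditions = conds)
  res <- fitFactorial(m)
  bn <- res$log2FC[res$contrast == "Nitrogen"]
  expect_lt(abs(mean(bn) - 1), 0.1)
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.07, 5)), rep(0.07, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # independent step-up: adj_i = min_{j >= i} p_j * n / j in sorted order
  n <- length(p)
  hand <- rev(cummin(rev(sort(p) * n / seq_len(n))))[rank(p)]
  expect_equal(bhAdjust(p), pmin(1, hand))
  # monotone non-decreasing in sorted p order
  set.seed(5)
  q <- runif(100)
  expect_true(all(diff(bhAdjust(sort(q))) >= -1e-15))
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("Storey q-values scale BH by the pi0 estimate", {
  set.seed(6)
  p <- runif(1000)
  q <- storeyQ(p)
  pi0 <- min(1, sum(p > 0.5) / (0.5 * length(p)))
  expect_equal(q, pmin(1, pi0 * p.adjust(p, "BH")))
  expect_true(all(q <= p.adjust(p, "BH") + 1e-15))
})
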