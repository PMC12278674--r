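# independent oracle: hypergeometric upper tail by explicit combinatorial
# summation (and, for small N, full enumeration of selections)
oraOracle <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

test_that("ORA reproduces the exact hypergeometric tail", {
  # N=20, K=5, n=5, k=3 -> 1126/15504
  universe <- paste0("g", 1:20)
  set <- universe[1:5]
  selected <- c(universe[1:3], universe[6:7])
  res <- oraHypergeometric(selected, list(s = set), universe)
  expect_equal(res$p, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$overlap_k, 3)
  expect_equal(res$set_size_K, 5)

  # k = 0 -> p = 1; selected = set = universe -> p = 1
  res0 <- oraHypergeometric(universe[6:10], list(s = universe[1:5]),
                            universe)
  expect_equal(res0$p, 1)
  resall <- oraHypergeometric(universe, list(s = universe), universe)
  expect_equal(resall$p, 1)
})

test_that("ORA equals brute-force enumeration across small universes", {
  for (N in c(6, 9, 12, 15)) {
    universe <- paste0("g", seq_len(N))
    for (K in unique(c(2, floor(N / 2), N - 1))) {
      set <- universe[seq_len(K)]
      for (n in unique(c(1, floor(N / 3), N - 2))) {
        if (n < 1) next
        for (k in 0:min(K, n)) {
          if (n - k > N - K) next
          selected <- c(set[seq_len(k)],
                        setdiff(universe, set)[seq_len(n - k)])
          got <- oraHypergeometric(selected, list(s = set), universe,
                                   minSetSize = 1)$p
          expect_equal(got, oraOracle(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
  # full enumeration over all C(8,4) selections for one case
  universe <- letters[1:8]
  set <- universe[1:3]
  sel_all <- combn(8, 4)
  for (k in 0:3) {
    tail_prob <- mean(apply(sel_all, 2, function(ix)
      sum(ix <= 3) >= k))
    sel <- c(set[seq_len(k)], setdiff(universe, set)[seq_len(4 - k)])
    expect_equal(oraHypergeometric(sel, list(s = set), universe,
                                   minSetSize = 1)$p,
                 tail_prob, tolerance = 1e-12)
  }
})

# oracle: exact two-sided rank-sum p by enumeration of all member subsets
rankOracle <- function(scores, members) {
  n <- length(scores)
  m <- length(members)
  r <- rank(scores)
  w_obs <- sum(r[members]) - m * (m + 1) / 2
  all_w <- apply(combn(n, m), 2, function(ix)
    sum(r[ix]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(all_w <= w_obs), mean(all_w >= w_obs)))
}

test_that("the rank-set test matches exact permutation enumeration", {
  # 6 features, set = top 3: two-sided exact p = 2 * 1/C(6,3) = 0.10
  scores <- c(a = 1, b = 2, c = 3, d = 10, e = 11, f = 12)
  res <- rankSetTest(scores, list(top = c("d", "e", "f")))
  expect_equal(res$p, 0.10, tolerance = 1e-12)
  expect_equal(res$direction, "up")
  expect_equal(rankOracle(scores, 4:6), 0.10, tolerance = 1e-12)

  set.seed(77)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    sc <- setNames(rnorm(n), paste0("f", seq_len(n)))
    m <- sample(2:(n - 2), 1)
    members <- sample(n, m)
    got <- rankSetTest(sc, list(s = names(sc)[members]))$p
    expect_equal(got, rankOracle(sc, members), tolerance = 1e-12)
  }
})

test_that("rank-set test handles ties and the approximation boundary", {
  tied <- setNames(rep(1, 8), paste0("f", 1:8))
  expect_equal(rankSetTest(tied, list(s = paste0("f", 1:3)))$p, 1)
  # down-ranked set
  sc <- setNames(c(1, 2, 3, 9, 10, 11), paste0("f", 1:6))
  expect_equal(rankSetTest(sc, list(s = paste0("f", 1:3)))$direction,
               "down")
  # exact and normal-approximation branches agree near the boundary for a
  # mid-range statistic (interleaved member ranks)
  sc12 <- setNames(as.numeric(1:12), paste0("f", 1:12))
  members <- paste0("f", c(2, 5, 8, 11))
  p_exact <- rankSetTest(sc12, list(s = members))$p
  x <- sc12[members]; y <- sc12[setdiff(names(sc12), members)]
  p_approx <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(p_exact - p_approx), 0.01)
})

test_that("rank-set p-values are calibrated under exchangeable scores", {
  set.seed(99)
  p <- replicate(400, {
    sc <- setNames(rnorm(20), paste0("f", 1:20))
    rankSetTest(sc, list(s = paste0("f", sample(20, 10))))$p
  })
  expect_gt(mean(p <= 0.05), 0.02)
  expect_lt(mean(p <= 0.05), 0.09)
  expect_gt(mean(p), 0.4)
})

test_that("condition means average replicates and skip missing", {
  vals <- rbind(c(1, 2, 3, 10, NA, 20), c(5, 5, 5, 7, 7, 7))
  m <- makeTestMatrix(vals, conditions = rep(c("high_24", "low_24"),
                                             each = 3))
  cm <- conditionMeans(m, c("high_24", "low_24"))
  expect_equal(unname(cm[1, ]), c(2, 15))
  expect_equal(unname(cm[2, ]), c(5, 7))
  expect_error(conditionMeans(m, "low_72"), "no observed replicates")
})

test_that("site-lipid correlations obey affine invariance and sign", {
  tg <- c(1, 3, 2, 6, 4, 9)
  site_up <- 2 * tg + 1
  site_dn <- -tg
  sm <- rbind(S1 = site_up, S2 = site_dn)
  lm_ <- rbind(TG = tg, DG = tg^2)
  colnames(sm) <- colnames(lm_) <- paste0("c", 1:6)
  got <- correlateSitesLipids(sm, lm_)
  expect_equal(got$pearson_r[got$site_key == "S1" & got$target == "TG"], 1)
  expect_equal(got$pearson_r[got$site_key == "S2" & got$target == "TG"], -1)
  expect_true(all(got$n_conditions == 6))

  # zero-variance rows are omitted with a message
  sm2 <- rbind(sm, S3 = rep(1, 6))
  expect_message(got2 <- correlateSitesLipids(sm2, lm_), "omitted")
  expect_false("S3" %in% got2$site_key)
  # mismatched condition ordering is an error
  expect_error(correlateSitesLipids(sm, lm_[, 6:1]), "same order")
})

test_that("random orthogonal profiles have near-zero mean correlation", {
  set.seed(55)
  sm <- matrix(rnorm(2000 * 6), 2000)
  lm_ <- matrix(rnorm(5 * 6), 5)
  rownames(sm) <- paste0("s", 1:2000); rownames(lm_) <- paste0("L", 1:5)
  colnames(sm) <- colnames(lm_) <- paste0("c", 1:6)
  got <- correlateSitesLipids(sm, lm_)
  expect_lt(abs(mean(got$pearson_r)), 0.05)
})

test_that("the correlation selection rule is a thresholded conjunction", {
  corr <- data.frame(
    site_key = rep(c("s1", "s2", "s3", "s4"), each = 2),
    target = rep(c("TG", "DG"), 4),
    pearson_r = c(0.9, 0.85, 0.9, 0.5, 0.95, 0.9, 0.81, 0.82),
    n_conditions = 6)
  diff <- data.frame(feature_id = c("s1", "s2", "s3", "s4"),
                     log2FC = c(1.0, 2.0, 0.5, -0.8))
  cfg <- filterConfig()
  expect_equal(selectCorrelatedSites(corr, diff, cfg), c("s1", "s4"))
  # s2 fails the conjunction but passes "any"
  expect_equal(selectCorrelatedSites(corr, diff, cfg, mode = "any"),
               c("s1", "s2", "s4"))
  # boundary: |lfc| = 0.8 is inclusive, r = 0.80 is not (> threshold)
  corr2 <- data.frame(site_key = rep("s9", 2), target = c("TG", "DG"),
                      pearson_r = c(0.80, 0.95), n_conditions = 6)
  diff2 <- data.frame(feature_id = "s9", log2FC = 0.8)
  expect_length(selectCorrelatedSites(corr2, diff2, cfg), 0)
})

test_that("enrichment input filters apply inclusive cutoffs", {
  diff <- data.frame(feature_id = paste0("f", 1:4),
                     log2FC = c(1.2, 0.9, 1.0, -4.0),
                     adj_p = c(0.04, 0.04, 0.05, 0.01))
  cfg <- filterConfig()
  expect_setequal(keggInputFilter(diff, cfg), c("f1", "f3", "f4"))
  expect_equal(mseaInputFilter(diff, cfg), "f4")
})

test_that("enrichment reporting applies the q and adjusted-p rule jointly", {
  res <- data.frame(set_name = c("a", "b", "c"),
                    adj_p = c(0.01, 0.01, 0.30),
                    q = c(0.1, 0.5, 0.1))
  expect_equal(reportEnrichment(res)$set_name, "a")
})

test_that("a null lipidome yields no enriched sets after adjustment", {
  clean <- 0L
  for (s in 1:8) {
    st <- suppressMessages(simulateNull(
      simConfig(n_proteins = 5L, n_cys_sites = 5L, n_phospho_sites = 5L,
                n_lipids = 60L, seed = 500L + s)))
    lip <- suppressMessages(normalizeLipids(st$lipids, st$lipid_samples))
    d <- moderatedTwoGroup(lip$log2, "low_72", "high_72")
    scores <- setNames(d$log2FC, d$feature_id)
    res <- tryCatch(rankSetTest(scores, st$lipid_sets),
                    error = function(e) NULL)
    if (is.null(res) || !any(res$adj_p <= 0.05)) clean <- clean + 1L
  }
  expect_gte(clean, 7L)
})
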