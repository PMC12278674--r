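test_that("site aggregation sums peptides per key and keeps composites apart", {
  d <- makeMiniDesign(2, assay = "redox")
  psm <- makeMiniPSM(d, c("a", "b", "c", "d"), "RT_1",
                     c("RT_1_C48", "RT_1_C48", "RT_1_S512;T513",
                       "RT_1_S512"),
                     c(40, 1, 60, 2, 5, 6, 7, 8))
  m <- suppressMessages(aggregateSites(psm, list(d), "redox"))
  v <- SummarizedExperiment::assay(m)
  expect_equal(unname(v["RT_1_C48", ]), c(100, 3))
  expect_equal(unname(v["RT_1_S512;T513", ]), c(5, 6))  # composite distinct
  expect_equal(unname(v["RT_1_S512", ]), c(7, 8))
  expect_equal(ptmKind(m), "redox")
  expect_false(isProteinAdjusted(m))

  # keyless peptides are skipped with a warning
  psm$site_keys[1] <- ""
  expect_warning(aggregateSites(psm, list(d), "redox"), "without site keys")
})

test_that("channel-loading offsets recover uniform loading shifts", {
  set.seed(9)
  # identical channels -> all offsets zero
  same <- makeTestMatrix(matrix(rep(rnorm(50), 4), 50, 4),
                         conditions = "high_24")
  expect_equal(unname(channelLoadingOffsets(same)), rep(0, 4))
  # one channel uniformly 2x (+1 in log2) above otherwise flat peptide
  # profiles -> its offset is exactly +1
  shifted <- matrix(rep(rnorm(100, 20, 2), 4), 100, 4)
  shifted[, 3] <- shifted[, 3] + 1
  ms <- makeTestMatrix(shifted, conditions = c("high_24", "high_48",
                                               "low_24", "low_48"))
  off <- channelLoadingOffsets(ms)
  expect_equal(unname(off[3] - off[1]), 1, tolerance = 1e-12)
  expect_equal(unname(off[1] - off[2]), 0, tolerance = 1e-12)
  # batch-corrected input is refused
  mbc <- ms
  mbc@appliedSteps <- c(mbc@appliedSteps, "bridge_batch_correct")
  expect_error(channelLoadingOffsets(mbc), "non-batch-corrected")
})

test_that("loading scaling subtracts on log2 and divides on linear", {
  vals <- matrix(c(4, 8), 1)
  m <- asSiteMatrix(makeTestMatrix(vals, conditions = c("high_24",
                                                        "high_48"),
                                   scale = "linear"))
  off <- c(0, 1)
  names(off) <- colnames(m)
  lin <- applyLoadingScaling(m, off)
  expect_equal(unname(SummarizedExperiment::assay(lin)[1, ]), c(4, 4))
  mlog <- asSiteMatrix(makeTestMatrix(log2(vals),
                                      conditions = c("high_24", "high_48")))
  lg <- applyLoadingScaling(mlog, off)
  expect_equal(unname(SummarizedExperiment::assay(lg)[1, ]), c(2, 2))
  # zero offsets: identity
  zero <- off * 0
  expect_equal(SummarizedExperiment::assay(
    applyLoadingScaling(mlog, zero)),
    SummarizedExperiment::assay(mlog))
  # channels without an offset are an error
  expect_error(applyLoadingScaling(mlog, off[1]), "no loading offset")
})

test_that("protein subtraction nulls sites that track their protein", {
  # protein P1 with condition means 1 (24h) and 3 (48h)
  pvals <- matrix(c(1, 1, 3, 3), 1, dimnames = list("P1", NULL))
  prot <- makeTestMatrix(pvals, conditions = c("high_24", "high_24",
                                               "high_48", "high_48"))
  svals <- matrix(c(1, 1, 3, 3, 5, 5, 5, 5), 2, byrow = TRUE,
                  dimnames = list(c("P1_C10", "ORPHAN_C9"), NULL))
  sites <- asSiteMatrix(makeTestMatrix(svals,
                                       conditions = c("high_24", "high_24",
                                                      "high_48", "high_48")))
  adj <- suppressMessages(subtractProteinAbundance(sites, prot))
  v <- SummarizedExperiment::assay(adj)
  expect_equal(unname(v["P1_C10", ]), rep(0, 4))
  expect_equal(unname(v["ORPHAN_C9", ]), rep(5, 4))  # orphan unchanged
  rd <- SummarizedExperiment::rowData(adj)
  expect_true(rd["P1_C10", "protein_adjusted"])
  expect_false(rd["ORPHAN_C9", "protein_adjusted"])
  expect_true(isProteinAdjusted(adj))
})

test_that("occupancy is the per-condition ox/pool ratio in percent", {
  d <- makeMiniDesign(2, condition = "high_24", pools = 2, assay = "redox")
  psm <- makeMiniPSM(d, "cp", "RT_1", "RT_1_C48", c(10, 14, 100, 100))
  sites <- suppressMessages(aggregateSites(psm, list(d), "redox"))
  occ <- computeOccupancy(sites)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$mean_percent_oxidation, 12)
  expect_false(occ$flagged)

  # ox mean equal to pool mean: 100 percent; above 100 is flagged
  psm2 <- makeMiniPSM(d, c("cp", "cq"), "RT_1",
                      c("RT_1_C48", "RT_1_C58"),
                      c(100, 100, 100, 100, 300, 300, 100, 100))
  occ2 <- computeOccupancy(
    suppressMessages(aggregateSites(psm2, list(d), "redox")))
  expect_equal(occ2$mean_percent_oxidation, c(100, 300))
  expect_equal(occ2$flagged, c(FALSE, TRUE))
})

test_that("occupancy cancels per-site multiplicative constants", {
  d <- makeMiniDesign(3, condition = "low_48", pools = 2, assay = "redox")
  psm <- makeMiniPSM(d, "cp", "RT_1", "RT_1_C48", c(11, 13, 12, 80, 82))
  base <- computeOccupancy(
    suppressMessages(aggregateSites(psm, list(d), "redox")))
  scaled_psm <- psm
  scaled_psm[, paste0("ch", 1:5)] <- psm[, paste0("ch", 1:5)] * 37.5
  scaled <- computeOccupancy(
    suppressMessages(aggregateSites(scaled_psm, list(d), "redox")))
  expect_equal(scaled$mean_percent_oxidation,
               base$mean_percent_oxidation, tolerance = 1e-12)
})

test_that("occupancy requires redox linear input and pool channels", {
  d <- makeMiniDesign(2, assay = "redox")
  psm <- makeMiniPSM(d, "cp", "RT_1", "RT_1_C48", c(1, 2))
  sites <- suppressMessages(aggregateSites(psm, list(d), "redox"))
  expect_error(computeOccupancy(sites), "total_thiol_pool")
  ph <- sites
  ph@ptmKind <- "phospho"
  expect_error(computeOccupancy(ph), "redox")
})

test_that("zero pool denominators drop the affected rows with a count", {
  d <- makeMiniDesign(1, condition = "high_24", pools = 2, assay = "redox")
  psm <- makeMiniPSM(d, c("a", "b"), "RT_1", c("RT_1_C10", "RT_1_C20"),
                     c(5, 0, 0, 7, 50, 50))
  sites <- suppressMessages(aggregateSites(psm, list(d), "redox"))
  expect_message(occ <- computeOccupancy(sites), "omitted")
  expect_equal(occ$site_key, "RT_1_C20")
  expect_equal(occ$mean_percent_oxidation, 14)
})

test_that("full PTM chain runs in the documented order", {
  cfg <- simConfig(n_proteins = 15L, peptides_per_protein = 2L,
                   n_cys_sites = 10L, n_phospho_sites = 8L, seed = 5L)
  st <- quietStudy(cfg)
  chain <- runRedoxChain(st)
  expect_identical(appliedSteps(chain$redox$sites),
                   c("aggregate_sites", "log2_transform",
                     "apply_loading_scaling", "median_center_channels",
                     "bridge_batch_correct",
                     "subtract_protein_abundance"))
  expect_true(isProteinAdjusted(chain$redox$sites))
  expect_false(isProteinAdjusted(chain$redox$sites_unadjusted))
  expect_identical(appliedSteps(chain$redox$sites_linear_scaled),
                   c("aggregate_sites", "apply_loading_scaling"))
  expect_equal(abundanceScale(chain$redox$sites_linear_scaled), "linear")
})
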