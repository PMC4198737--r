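test_that("Dtest contrasts tail means of sub-pool means, antisymmetrically", {
  be <- beFromSubpoolMeans(c(0.52, 0.50), c(0.48, 0.50))
  spm <- subpoolMeans(be)
  expect_equal(unname(spm[1, ]), c(0.52, 0.50, 0.48, 0.50))
  expect_equal(unname(dTest(spm)), 0.02)

  # flat SNP
  flat <- subpoolMeans(beFromSubpoolMeans(c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(unname(dTest(flat)), 0)

  # relabelling the tails negates Dtest exactly
  expect_equal(unname(dTest(subpoolMeans(swapTails(be)))), -0.02)

  # sub-pool means weight sub-pools equally and ignore missing replicates
  vals <- matrix(0.5, 1, 24)
  lab <- enumerateMeasurements(2, 2, 3)
  vals[1, which(lab$tail == "high" & lab$subpool == 1)] <-
    c(0.6, 0.6, 0.6, NA, 0.6, 0.6)
  spmNA <- subpoolMeans(beFixture(vals))
  expect_equal(unname(spmNA[1, "high:1"]), 0.6)
})

test_that("Dnull contrasts sub-pools within tails and ignores column order", {
  be <- beFromSubpoolMeans(c(0.52, 0.50), c(0.48, 0.50))
  dn <- dNull(subpoolMeans(be))
  expect_equal(sort(colnames(dn)), c("high:1-2", "low:1-2"))
  expect_equal(unname(dn[1, "high:1-2"]), 0.02)
  expect_equal(unname(dn[1, "low:1-2"]), -0.02)

  ident <- dNull(subpoolMeans(beFromSubpoolMeans(c(0.4, 0.4), c(0.3, 0.3))))
  expect_true(all(ident == 0))

  # permuting duplicate/replicate columns within a sub-pool changes nothing
  withr::local_seed(8)
  vals <- matrix(runif(24, 0.3, 0.7), 1, 24)
  be1 <- beFixture(vals)
  lab <- enumerateMeasurements(2, 2, 3)
  perm <- unlist(lapply(split(seq_len(24), paste(lab$tail, lab$subpool)),
                        sample))
  be2 <- BafExperiment(vals[, perm, drop = FALSE], lab[perm, ],
                       snpInfo(be1))
  expect_equal(dNull(subpoolMeans(be2)), dNull(subpoolMeans(be1)))
})

test_that("SD(Dnull) estimators: RMS core, design calibration, smoothing", {
  be <- beFromSubpoolMeans(c(0.52, 0.50), c(0.48, 0.50))
  dn <- dNull(subpoolMeans(be))
  # raw RMS of (+0.02, -0.02) is sqrt((4e-4 + 4e-4) / 2) = 0.02
  expect_equal(unname(sdDnull(dn, "per_snp_rms", calibrate = FALSE)[1]), 0.02)
  # calibrated to the null SD of Dtest: / sqrt(nSubpools)
  expect_equal(unname(sdDnull(dn, "per_snp_rms")[1]), 0.02 / sqrt(2))

  # a single contrast gives |d|
  one <- matrix(-0.03, 1, 1, dimnames = list("s", "high:1-2"))
  expect_equal(unname(sdDnull(one, "per_snp_rms", calibrate = FALSE)[1]), 0.03)

  # when every SNP shares one Dnull distribution, the binned estimate
  # agrees with the pooled per-SNP RMS to < 5%
  withr::local_seed(15)
  M <- 10000
  dnBig <- matrix(rnorm(2 * M, 0, 0.02), M, 2,
                  dimnames = list(sprintf("s%05d", 1:M), NULL))
  pooled <- sqrt(mean(dnBig^2))
  binned <- sdDnull(dnBig, "binned_smoothed", binSize = 1000,
                    meanBaf = runif(M), calibrate = FALSE)
  expect_lt(max(abs(binned - pooled) / pooled), 0.05)

  # all-zero contrasts are floored to a positive SD and flagged
  dnZero <- rbind(dnBig, s99999 = c(0, 0))
  est <- sdDnull(dnZero, "per_snp_rms")
  expect_true(all(est > 0))
  expect_identical(attr(est, "floored"), "s99999")
})

test_that("the z test matches the closed-form chi-square(1) tail", {
  zt <- zTest(0, 0.01)
  expect_equal(zt$z, 0)
  expect_equal(zt$p_value, 1)

  zt <- zTest(0.12, 0.03)
  expect_equal(zt$z, 4)
  expect_equal(zt$chi2, 16)
  expect_equal(zt$p_value, 2 * pnorm(4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(zt$p_value, 6.334248e-05, tolerance = 1e-6)

  # sign symmetry is exact
  expect_identical(zTest(-0.12, 0.03)$p_value, zTest(0.12, 0.03)$p_value)

  # closed-form oracle 2 * (1 - Phi(sqrt(chi2))) across the working range
  chi2 <- seq(0.01, 60, length.out = 400)
  p <- zTest(sqrt(chi2), 1)$p_value
  oracle <- 2 * pnorm(sqrt(chi2), lower.tail = FALSE)
  expect_lt(max(abs(p - oracle) / oracle), 1e-12)

  expect_error(zTest(0.1, 0), "positive")
})

test_that("Bonferroni threshold and significance calls are exact", {
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.01, 100), 1e-4)
  expect_equal(bonferroniThreshold(0.05, 655665), 0.05 / 655665)
  expect_error(bonferroniThreshold(0.05, 0), ">= 1")
  expect_error(bonferroniThreshold(1.5, 10), "alpha")

  res <- data.frame(p_value = c(1, 0.05, 0.049999, 1e-8, NA))
  out <- callSignificant(res, 0.05)
  expect_equal(out$significant, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(callSignificant(data.frame(p_value = rep(1, 5)),
                                   0.05)$significant), 0)
  # brute-force count on a random vector
  withr::local_seed(9)
  p <- runif(500)
  thr <- 0.031
  expect_equal(sum(callSignificant(data.frame(p_value = p), thr)$significant),
               sum(p <= thr))
})

test_that("sdpTest returns a complete, thresholded per-SNP table", {
  sim <- simulateNullScan(400, seed = 61, nSires = 100,
                          maxPerTail = c(high = 20, low = 20))
  res <- sdpTest(sim$baf, sdpConfig())
  expect_named(res, c("snp_id", "rs_id", "chromosome", "position", "d_test",
                      "sd_dnull", "z", "chi2", "p_value", "significant"))
  expect_equal(attr(res, "n_tests"), nrow(res))
  expect_equal(attr(res, "threshold"), 0.05 / nrow(res))
  expect_true(all(res$chi2 >= 0))
  expect_equal(res$chi2, res$z^2)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # mostly null: no mass significance at genome-wide control
  expect_lt(sum(res$significant), 3)
})
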