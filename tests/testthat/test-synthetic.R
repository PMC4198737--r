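smallMap <- function(n, chrom = "1")
  data.frame(snp_id = sprintf("m%04d", seq_len(n)), chromosome = chrom,
             position = seq_len(n) * 1000)

test_that("identical seeds reproduce cohorts and measurements exactly", {
  map <- smallMap(50)
  a <- simulateCohort(20, map, seed = 3)
  b <- simulateCohort(20, map, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a$genotypes,
                         simulateCohort(20, map, seed = 4)$genotypes))
  design <- buildPoolDesign(a$sires, 0.3, nReplicates = 2)
  m1 <- simulatePoolMeasurements(design, a$genotypes, map, seed = 9)
  m2 <- simulatePoolMeasurements(design, a$genotypes, map, seed = 9)
  expect_identical(bafValues(m1$baf), bafValues(m2$baf))
})

test_that("a null cohort has the requested trait moments", {
  c0 <- simulateCohort(4000, smallMap(5), qtls = NULL, noiseSd = 1, seed = 5)
  expect_lt(abs(mean(c0$sires$dp_ebv)), 0.05)
  expect_lt(abs(sd(c0$sires$dp_ebv) - 1), 0.05)
  expect_true(all(c0$sires$reliability >= 0.45 & c0$sires$reliability <= 0.65))
  expect_true(all(c0$genotypes %in% 0:2))
})

test_that("planted-QTL genotype/trait correlation matches the closed form", {
  map <- smallMap(20)
  qtl <- data.frame(snp_index = 7L, effect = 0.5)
  ch <- simulateCohort(5000, map, qtl, noiseSd = 1, seed = 11)
  g <- ch$genotypes[7, ]
  p <- ch$truth$pop_freqs[7]
  # ebv = a (g - 2p) + e  =>  r = a sd(g) / sqrt(a^2 var(g) + 1)
  vg <- 2 * p * (1 - p)
  rExp <- 0.5 * sqrt(vg) / sqrt(0.25 * vg + 1)
  expect_lt(abs(cor(g, ch$sires$dp_ebv) - rExp), 0.05)

  # effect zero leaves genotype and trait uncorrelated
  ch0 <- simulateCohort(2000, map, data.frame(snp_index = 7L, effect = 0),
                        seed = 12)
  expect_lt(abs(cor(ch0$genotypes[7, ], ch0$sires$dp_ebv)), 0.08)

  expect_error(simulateCohort(3, map), ">= 4")
  expect_error(simulateCohort(10, map,
    data.frame(snp_index = c(2L, 2L), effect = c(1, 1))), "duplicate")
})

test_that("noise-free measurements equal the true sub-pool frequencies", {
  map <- smallMap(30)
  ch <- simulateCohort(40, map, seed = 21)
  design <- buildPoolDesign(ch$sires, 0.25)
  sim <- simulatePoolMeasurements(design, ch$genotypes, map,
                                  error = errorModel(0, 0), seed = 1)
  a <- bafValues(sim$baf)
  info <- measurementInfo(sim$baf)
  key <- paste(info$tail, info$subpool, sep = ":")
  for (k in unique(key))
    for (col in which(key == k))
      expect_equal(unname(a[, col]), unname(sim$truth$true_pool_freqs[, k]))

  # all sires homozygous B => every measurement is exactly 1
  gAll2 <- matrix(2L, nrow(map), 40,
                  dimnames = list(map$snp_id, colnames(ch$genotypes)))
  simB <- simulatePoolMeasurements(design, gAll2, map,
                                   error = errorModel(0, 0), seed = 1)
  expect_true(all(bafValues(simB$baf) == 1))
})

test_that("replicate means are unbiased for the true pool frequency", {
  map <- smallMap(10000)
  ch <- simulateCohort(80, map, seed = 31)
  design <- buildPoolDesign(ch$sires, 0.2)
  sim <- simulatePoolMeasurements(design, ch$genotypes, map, seed = 32)
  a <- bafValues(sim$baf)
  info <- measurementInfo(sim$baf)
  key <- paste(info$tail, info$subpool, sep = ":")
  for (k in unique(key)) {
    f <- sim$truth$true_pool_freqs[, k]
    mid <- f >= 0.1 & f <= 0.9   # clipping negligible away from the bounds
    bias <- mean(rowMeans(a[mid, key == k]) - f[mid])
    expect_lt(abs(bias), 0.002)
  }
})

test_that("the toy fixture is deterministic, in-domain, and its planted QTL rank high", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  fx1 <- makeToyFixture(d1, seed = 1)
  fx2 <- makeToyFixture(d2, seed = 1)
  for (nm in names(fx1$paths))
    expect_identical(readLines(fx1$paths[nm]), readLines(fx2$paths[nm]),
                     label = nm)
  a <- bafValues(fx1$baf)
  expect_true(all(a >= 0 & a <= 1, na.rm = TRUE))
  expect_equal(dim(a), c(500L, 24L))

  # pilot scan: both planted QTL (effect 1.0) in the top 5% of chi2,
  # the stronger one genome-wide significant; at 16-sire tails the
  # expected causal z is ~2-4, so top-1% for both is not guaranteed
  be <- attachSnpMap(fx1$baf, fx1$snpMap)
  res <- sdpTest(runQc(be, sdpConfig())$baf, sdpConfig())
  qtlIds <- fx1$snpMap$snp_id[fx1$truth$qtls$snp_index]
  ranks <- match(qtlIds, res$snp_id[order(-res$chi2)])
  expect_true(all(ranks <= ceiling(0.05 * nrow(res))))
  expect_lte(min(ranks), ceiling(0.01 * nrow(res)))
  best <- res[res$snp_id == qtlIds[which.min(ranks)], ]
  expect_true(best$significant)
})
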