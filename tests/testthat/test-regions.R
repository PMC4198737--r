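test_that("region lengths reproduce all 13 published start/end pairs", {
  t3 <- table3Regions()
  for (i in seq_len(nrow(t3))) {
    snps <- data.frame(chromosome = t3$chromosome[i],
                       position = c(t3$start[i], t3$end[i]),
                       snp_id = c("a", "b"))
    span <- t3$end[i] - t3$start[i]
    reg <- buildRegions(snps, maxGap = span, minSnps = 2)
    expect_equal(length(reg), 1L)
    expect_equal(reg$region_length, t3$length[i],
                 label = sprintf("row %d (BTA %s)", i, t3$chromosome[i]))
  }
})

test_that("a 1-Mb gap rule splits chromosome 15 into its three published runs", {
  pos15 <- c(28399876, 28999494,            # 28.4-29.0 Mb run boundaries
             31285729, 32027462,            # 31.3-32.0 Mb run boundaries
             bta15MainRunPositions())       # 50.4-51.6 Mb run
  snps <- data.frame(chromosome = "15", position = pos15,
                     snp_id = sprintf("s%02d", seq_along(pos15)))
  reg <- buildRegions(snps, maxGap = 1e6, minSnps = 2)
  expect_equal(length(reg), 3L)
  expect_equal(GenomicRanges::start(reg), c(28399876, 31285729, 50438721))
  expect_equal(GenomicRanges::end(reg), c(28999494, 32027462, 51638163))
  expect_equal(reg$region_length, c(599618, 741733, 1199442))
})

test_that("regions need minSnps members and tolerate unsorted input", {
  two <- data.frame(chromosome = "1", position = c(100, 200),
                    snp_id = c("a", "b"))
  expect_length(buildRegions(two, maxGap = 1e6, minSnps = 3), 0L)
  expect_length(buildRegions(two[0, ], maxGap = 1e6, minSnps = 3), 0L)

  shuffled <- data.frame(chromosome = "1", position = c(300, 100, 200),
                         snp_id = c("c", "a", "b"),
                         rs_id = c("rs3", "rs1", "rs2"))
  reg <- buildRegions(shuffled, maxGap = 1e6, minSnps = 3)
  expect_equal(as.character(reg$members[[1]]), c("rs1", "rs2", "rs3"))
})

test_that("region merging matches the O(n^2) transitive-merge oracle", {
  for (i in 1:100) {
    withr::local_seed(2000 + i)
    n <- sample(5:50, 1)
    snps <- data.frame(
      chromosome = sample(c("1", "2"), n, replace = TRUE),
      position = sample.int(5e6, n),
      snp_id = sprintf("s%03d", seq_len(n)))
    minSnps <- sample(1:3, 1)
    got <- regionsAsFrame(buildRegions(snps, maxGap = 1e6,
                                       minSnps = minSnps))
    want <- bruteForceRegions(snps, maxGap = 1e6, minSnps = minSnps)
    expect_equal(got$chromosome, want$chromosome)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_snps, want$n_snps)
    expect_equal(got$members, want$members)
    # structural invariants: sorted, disjoint, members within bounds
    if (nrow(got) > 1) {
      sameChrom <- got$chromosome[-1] == got$chromosome[-nrow(got)]
      expect_true(all(got$start[-1][sameChrom] >
                        got$end[-nrow(got)][sameChrom]))
    }
    expect_true(all(got$n_snps >= minSnps))
    expect_equal(got$length, got$end - got$start)
  }
})

test_that("gene annotation classifies intragenic, nearby and intergenic", {
  genes <- GenomicRanges::GRanges(
    c("7", "7", "8"), IRanges::IRanges(c(1000, 5000, 100), c(2000, 6000, 200)),
    symbol = c("G1", "G2", "G3"))
  snps <- data.frame(
    snp_id = c("in1", "near1", "edge", "far", "othchr"),
    chromosome = c("7", "7", "7", "7", "9"),
    position = c(1500, 3000, 6000 + 1e6, 6000 + 1e6 + 1, 150))
  ann <- annotateSnps(snps, genes, window = 1e6)
  expect_equal(ann$status,
               c("intragenic", "nearby", "nearby", "intergenic", "intergenic"))
  expect_equal(ann$genes[1], "G1")
  expect_equal(ann$distance[1], 0)
  # nearest boundary of G1 is 2000 (d = 1000) vs G2 at 5000 (d = 2000)
  expect_equal(ann$genes[2], "G1")
  expect_equal(ann$distance[2], 1000)
  # exactly `window` past the last gene boundary is still nearby (inclusive)
  expect_equal(ann$genes[3], "G2")
  expect_equal(ann$distance[3], 1e6)
  expect_true(is.na(ann$distance[4]))
  expect_equal(ann$genes[4], "")

  # invariant to gene list order
  annRev <- annotateSnps(snps, rev(genes), window = 1e6)
  expect_equal(annRev, ann)

  # a SNP inside two overlapping genes lists both, alphabetically
  genes2 <- GenomicRanges::GRanges("7",
    IRanges::IRanges(c(1000, 1400), c(2000, 1600)),
    symbol = c("ZZ", "AA"))
  ann2 <- annotateSnps(snps[1, ], genes2, window = 1e6)
  expect_equal(ann2$genes, "AA;ZZ")
})
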