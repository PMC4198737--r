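# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# BafExperiment from a value matrix under a given design crossing
beFixture <- function(values, nSubpools = 2, nDuplicates = 2,
                      nReplicates = 3, snpIds = NULL) {
  lab <- enumerateMeasurements(nSubpools, nDuplicates, nReplicates)
  values <- matrix(values, ncol = nrow(lab))
  if (is.null(snpIds)) snpIds <- sprintf("snp%03d", seq_len(nrow(values)))
  rownames(values) <- snpIds
  BafExperiment(values, lab)
}

# BafExperiment whose sub-pool means are exactly the given values:
# highMeans / lowMeans are SNP x subpool matrices (or vectors for 1 SNP)
beFromSubpoolMeans <- function(highMeans, lowMeans, nDuplicates = 2,
                               nReplicates = 3, snpIds = NULL) {
  highMeans <- rbind(highMeans)
  lowMeans <- rbind(lowMeans)
  lab <- enumerateMeasurements(ncol(highMeans), nDuplicates, nReplicates)
  vals <- matrix(NA_real_, nrow(highMeans), nrow(lab))
  for (j in seq_len(nrow(lab))) {
    src <- if (lab$tail[j] == "high") highMeans else lowMeans
    vals[, j] <- src[, lab$subpool[j]]
  }
  if (is.null(snpIds)) snpIds <- sprintf("snp%03d", seq_len(nrow(vals)))
  rownames(vals) <- snpIds
  BafExperiment(vals, lab)
}

# relabel high <-> low, leaving everything else untouched
swapTails <- function(be) {
  info <- measurementInfo(be)
  info$tail <- ifelse(info$tail == "high", "low", "high")
  BafExperiment(bafValues(be), info, snpInfo(be))
}

# random BafExperiment with independent noise, for filter/property tests
randomBe <- function(nSnp, seed, sd = 0.02, mid = 0.5) {
  withr::local_seed(seed)
  beFixture(clip01(matrix(rnorm(nSnp * 24, mid, sd), nSnp, 24)),
            snpIds = sprintf("snp%03d", seq_len(nSnp)))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# published candidate-region table: chromosome, start, end, length, n_snps
table3Regions <- function() {
  data.frame(
    chromosome = c("1", "1", "2", "3", "4", "9", "13", "15", "15", "15",
                   "17", "21", "22"),
    start = c(21625461, 27814460, 117668432, 6388643, 117852857, 72784616,
              78273095, 28399876, 31285729, 50438721, 67344705, 60154246,
              33753508),
    end = c(21632949, 28017039, 118739748, 6396280, 118898784, 72804256,
            78416778, 28999494, 32027462, 51638163, 67375670, 60175026,
            34051778),
    length = c(7488, 202579, 1071316, 7637, 1045927, 19640, 143683, 599618,
               741733, 1199442, 30965, 20780, 298270),
    n_snps = c(3, 7, 9, 3, 4, 4, 4, 3, 5, 14, 3, 4, 3))
}

# the known positions inside the 14-SNP candidate run on chromosome 15:
# the two boundary SNPs plus the intragenic SNPs published with positions
bta15MainRunPositions <- function() {
  c(50438721, 50730325, 50733648, 50753778, 50765770, 50769861, 50774198,
    50780537, 50784307, 50792403, 50795681, 50799229, 51638163)
}

# O(n^2) transitive-merge oracle for region building
bruteForceRegions <- function(snps, maxGap, minSnps) {
  out <- list()
  for (ch in unique(snps$chromosome)) {
    sub <- snps[snps$chromosome == ch, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    n <- nrow(sub)
    # transitive closure of the "within maxGap" relation
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (abs(sub$position[i] - sub$position[j]) <= maxGap &&
            comp[i] != comp[j]) {
          comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      m <- sub[comp == cc, , drop = FALSE]
      if (nrow(m) < minSnps) next
      out[[length(out) + 1L]] <- data.frame(
        chromosome = ch, start = min(m$position), end = max(m$position),
        n_snps = nrow(m),
        members = paste(m$snp_id[order(m$position)], collapse = ";"))
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), n_snps = integer(0),
                      members = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# simulate a complete null scan: cohort, tails capped 40/39 as in a
# 275-candidate bio-bank, pooled measurements, QC'd test results
simulateNullScan <- function(nSnp, seed, nSires = 275,
                             maxPerTail = c(high = 40, low = 39)) {
  map <- data.frame(snp_id = sprintf("s%05d", seq_len(nSnp)),
                    chromosome = "1", position = seq_len(nSnp) * 1000)
  cohort <- simulateCohort(nSires, map, qtls = NULL, noiseSd = 1, seed = seed)
  design <- buildPoolDesign(cohort$sires, tailFraction = 0.2,
                            maxPerTail = maxPerTail)
  sim <- simulatePoolMeasurements(design, cohort$genotypes, map,
                                  seed = seed + 1L)
  sim
}

# independent full-sort oracle for the variability exclusion
oracleVariabilityDrop <- function(be, fraction) {
  sc <- variabilityScores(be)
  k <- floor(fraction * length(sc))
  df <- data.frame(id = names(sc), score = sc)
  df <- df[order(-df$score, df$id), ]
  df$id[seq_len(k)]
}
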