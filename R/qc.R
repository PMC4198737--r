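# Pre-test SNP filters and Dnull distributional diagnostics.

#' Per-SNP replicate-variability score
#'
#' Technical variability of each SNP, measured from the only pure technical
#' contrast in the design: array replicates within one chip pool (a
#' tail/sub-pool/duplicate combination). Per tail the replicate deviations
#' about their pool means are pooled into one SD across that tail's pools;
#' the score is the mean of the per-tail SDs.
#'
#' @param x a [BafExperiment-class] with >= 2 replicates in some pool.
#' @return named numeric vector, one score per SNP (NA if a SNP has no
#'   usable replicate contrast).
#' @export
variabilityScores <- function(x) {
  a <- bafValues(x)
  info <- measurementInfo(x)
  pool <- interaction(info$tail, info$subpool, info$duplicate, drop = TRUE)
  if (max(table(pool)) < 2L)
    stop("variability filter inapplicable: no pool has >= 2 array replicates")
  tails <- unique(info$tail)
  perTail <- sapply(tails, function(tl) {
    ss <- numeric(nrow(a)); df <- numeric(nrow(a))
    for (pl in unique(pool[info$tail == tl])) {
      cols <- which(pool == pl & info$tail == tl)
      if (length(cols) < 2L) next
      sub <- a[, cols, drop = FALSE]
      n <- rowSums(!is.na(sub))
      mu <- rowMeans(sub, na.rm = TRUE)
      ss <- ss + rowSums((sub - mu)^2, na.rm = TRUE)
      df <- df + pmax(n - 1, 0)
    }
    out <- sqrt(ss / df)
    out[df == 0] <- NA_real_
    out
  })
  perTail <- matrix(perTail, nrow = nrow(a))
  scores <- rowMeans(perTail)
  names(scores) <- rownames(a)
  scores
}

#' Exclude the most variable SNPs
#'
#' Drops exactly `floor(fraction * M)` SNPs with the highest
#' [variabilityScores()], ties broken deterministically by
#' (score descending, snp_id ascending).
#'
#' @param x a [BafExperiment-class].
#' @param fraction fraction of SNPs to exclude (default 0.01).
#' @return list with `kept` and `dropped` character vectors of SNP ids and
#'   the numeric `scores`.
#' @export
variabilityFilter <- function(x, fraction = 0.01) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  scores <- variabilityScores(x)
  k <- floor(fraction * length(scores))
  ids <- names(scores)
  if (k == 0L)
    return(list(kept = ids, dropped = character(0), scores = scores))
  ord <- order(-scores, ids, na.last = TRUE)
  dropped <- ids[ord][seq_len(k)]
  list(kept = setdiff(ids, dropped), dropped = dropped, scores = scores)
}

#' Remove monomorphic SNPs
#'
#' A SNP is monomorphic when every non-missing measurement is `<= epsilon`
#' or every one is `>= 1 - epsilon`; with pooled data there are no
#' per-animal genotypes, so monomorphism is declared on the measured BAF.
#'
#' @param x a [BafExperiment-class].
#' @param epsilon BAF tolerance (default 0.02).
#' @return list with `kept` and `dropped` character vectors of SNP ids.
#' @export
monomorphicFilter <- function(x, epsilon = 0.02) {
  a <- bafValues(x)
  hasVal <- rowSums(!is.na(a)) > 0
  mx <- suppressWarnings(apply(a, 1L, max, na.rm = TRUE))
  mn <- suppressWarnings(apply(a, 1L, min, na.rm = TRUE))
  mono <- hasVal & (mx <= epsilon | mn >= 1 - epsilon)
  list(kept = rownames(a)[!mono], dropped = rownames(a)[mono])
}

#' Remove SNPs with an incomplete pooling design
#'
#' The null contrast needs two sub-pool means per tail, so a SNP is dropped
#' when any tail has fewer than two sub-pools with at least one non-missing
#' measurement.
#'
#' @param x a [BafExperiment-class].
#' @return list with `kept` and `dropped` character vectors of SNP ids.
#' @export
missingDesignFilter <- function(x) {
  spm <- subpoolMeans(x)
  info <- attr(spm, "groups")
  ok <- rep(TRUE, nrow(spm))
  for (tl in unique(info$tail)) {
    cols <- which(info$tail == tl)
    ok <- ok & rowSums(!is.na(spm[, cols, drop = FALSE])) >= 2L
  }
  list(kept = rownames(spm)[ok], dropped = rownames(spm)[!ok])
}

#' Normality diagnostics on the Dnull distribution
#'
#' Anderson-Darling, Shapiro-Wilk and Kolmogorov-Smirnov tests of the
#' pooled within-tail differences against a normal with sample-estimated
#' mean and SD. Shapiro-Wilk is computed on a seeded subsample of at most
#' 5000 values when the input is larger; the KS test uses estimated
#' parameters (Lilliefors-style, so its p-value is approximate).
#'
#' @param values numeric vector of Dnull values (>= 8, non-constant).
#' @param seed seed for the Shapiro-Wilk subsample.
#' @return data.frame with columns `test`, `statistic`, `p_value`.
#' @export
dnullNormality <- function(values, seed = 1) {
  values <- values[is.finite(values)]
  if (length(values) < 8L)
    stop("need at least 8 finite Dnull values for normality tests")
  if (sd(values) == 0)
    stop("Dnull values are constant; normality tests are undefined")
  ad <- nortest::ad.test(values)
  swVals <- if (length(values) > 5000L)
    withSeed(seed, sample(values, 5000L)) else values
  sw <- shapiro.test(swVals)
  ks <- suppressWarnings(ks.test(values, "pnorm", mean(values), sd(values)))
  data.frame(
    test = c("anderson_darling", "shapiro_wilk", "kolmogorov_smirnov"),
    statistic = as.numeric(c(ad$statistic, sw$statistic, ks$statistic)),
    p_value = as.numeric(c(ad$p.value, sw$p.value, ks$p.value)))
}

#' Run all pre-test filters
#'
#' Applies, in order, the replicate-variability exclusion, the monomorphic
#' filter and the incomplete-design filter, then computes the Dnull
#' normality diagnostics on the retained SNPs.
#'
#' @param x a [BafExperiment-class].
#' @param config an [SdpConfig-class].
#' @return list with `baf` (the filtered [BafExperiment-class]) and
#'   `report` (a [QcReport-class]).
#' @export
runQc <- function(x, config = sdpConfig()) {
  nInput <- nrow(x)
  vf <- variabilityFilter(x, config@qcVariabilityFraction)
  x1 <- x[vf$kept, ]
  mf <- monomorphicFilter(x1, config@monomorphicEpsilon)
  x2 <- x1[mf$kept, ]
  df <- missingDesignFilter(x2)
  x3 <- x2[df$kept, ]
  norm <- if (nrow(x3)) {
    dn <- dNull(subpoolMeans(x3))
    vals <- as.numeric(dn)
    if (sum(is.finite(vals)) >= 8L && sd(vals[is.finite(vals)]) > 0)
      dnullNormality(vals, seed = config@seed)
    else data.frame(test = character(0), statistic = numeric(0),
                    p_value = numeric(0))
  } else data.frame(test = character(0), statistic = numeric(0),
                    p_value = numeric(0))
  report <- new("QcReport", nInput = nInput,
                droppedVariability = vf$dropped,
                droppedMonomorphic = mf$dropped,
                droppedMissingDesign = df$dropped,
                nRetained = nrow(x3), normality = norm)
  list(baf = x3, report = report)
}
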