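# The multiple-marker selective-pooling test:
#   Z = Dtest / SD(Dnull),  Z^2 ~ chi-square(1) under no association,
# where Dtest contrasts the tail BAF means and Dnull the sub-pool means
# within a tail. Sub-pool means (not raw measurement means) are the unit of
# both contrasts, so unequal sub-pool sizes and replicate counts carry
# equal weight.

#' Sub-pool mean BAF matrix
#'
#' Averages all duplicate x replicate measurements of each (tail, sub-pool)
#' into one column; missing values are dropped from the mean, and a
#' sub-pool with no usable measurement yields `NA`.
#'
#' @param x a [BafExperiment-class].
#' @return numeric matrix, SNPs x sub-pools, columns named `tail:subpool`;
#'   the grouping is carried in `attr(, "groups")`.
#' @export
subpoolMeans <- function(x) {
  a <- bafValues(x)
  info <- measurementInfo(x)
  key <- paste(info$tail, info$subpool, sep = ":")
  # canonical (tail, subpool) column order, independent of input column order
  u <- !duplicated(key)
  keys <- key[u][order(info$tail[u], info$subpool[u])]
  out <- matrix(NA_real_, nrow(a), length(keys),
                dimnames = list(rownames(a), keys))
  for (k in keys) {
    cols <- which(key == k)
    m <- rowMeans(a[, cols, drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[, k] <- m
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  attr(out, "groups") <- data.frame(
    tail = vapply(parts, `[`, "", 1L),
    subpool = as.integer(vapply(parts, `[`, "", 2L)))
  out
}

#' Between-tail contrast Dtest
#'
#' Difference of the B-allele frequency means among tails: mean of the
#' high-tail sub-pool means minus mean of the low-tail sub-pool means.
#'
#' @param spm sub-pool mean matrix from [subpoolMeans()].
#' @return named numeric vector of per-SNP Dtest values (`NA` when a tail
#'   has no non-missing sub-pool mean).
#' @export
dTest <- function(spm) {
  info <- attr(spm, "groups")
  hi <- rowMeans(spm[, info$tail == "high", drop = FALSE], na.rm = TRUE)
  lo <- rowMeans(spm[, info$tail == "low", drop = FALSE], na.rm = TRUE)
  out <- hi - lo
  out[is.nan(out)] <- NA_real_
  out
}

#' Within-tail null contrasts Dnull
#'
#' Differences of the B-allele frequency means within tails: for each tail,
#' sub-pool mean differences over all unordered sub-pool pairs (one value
#' per tail in the standard two-sub-pool design).
#'
#' @param spm sub-pool mean matrix from [subpoolMeans()].
#' @return numeric matrix, SNPs x contrasts, columns named
#'   `tail:subpoolA-subpoolB`.
#' @export
dNull <- function(spm) {
  info <- attr(spm, "groups")
  cols <- list(); nms <- character(0)
  for (tl in unique(info$tail)) {
    idx <- which(info$tail == tl)
    if (length(idx) < 2L)
      stop(sprintf("tail '%s' has < 2 sub-pools; Dnull undefined", tl))
    prs <- utils::combn(idx, 2L)
    for (j in seq_len(ncol(prs))) {
      cols[[length(cols) + 1L]] <- spm[, prs[1L, j]] - spm[, prs[2L, j]]
      nms <- c(nms, sprintf("%s:%d-%d", tl, info$subpool[prs[1L, j]],
                            info$subpool[prs[2L, j]]))
    }
  }
  out <- do.call(cbind, cols)
  dimnames(out) <- list(rownames(spm), nms)
  out
}

#' Estimate the null SD of Dtest from the Dnull contrasts
#'
#' Both estimators start from the per-SNP root-mean-square of the Dnull
#' values (mean zero under the design, so no centring). With
#' `method = "per_snp_rms"` each SNP keeps its own RMS; with
#' `method = "binned_smoothed"` (default) SNPs are ranked by mean BAF,
#' partitioned into bins of `binSize`, and every SNP in a bin receives the
#' bin-pooled RMS — the per-SNP estimator has only as many degrees of
#' freedom as Dnull contrasts (two in the standard design), far too few for
#' a chi-square reference, while the allele-frequency-matched bin pools
#' thousands. The effective bin size is reduced to
#' `max(50, floor(M / 10))` when fewer than `binSize * 10` SNPs are tested,
#' so the estimator still tracks the allele-frequency dependence of
#' `Var(Dnull)` on small marker panels.
#'
#' With `calibrate = TRUE` (default) the RMS is scaled by
#' `sqrt(1 / nSubpools)`: Dtest averages `nSubpools` sub-pool means per
#' tail, so its null variance is `1/nSubpools` of a single sub-pool pair
#' contrast's, and the scaled estimate is the null SD of Dtest itself —
#' this is what makes `Z^2` chi-square(1) under the null.
#' `calibrate = FALSE` returns the raw Dnull RMS.
#'
#' Zero or missing estimates are floored at the 0.1 percentile of the
#' positive estimates so every retained SNP gets a finite test.
#'
#' @param dnull matrix from [dNull()].
#' @param method `"binned_smoothed"` or `"per_snp_rms"`.
#' @param binSize SNPs per bin for the smoothed estimator.
#' @param meanBaf per-SNP mean BAF used to rank SNPs into bins (required
#'   for `"binned_smoothed"`).
#' @param nSubpools sub-pools per tail in the design.
#' @param calibrate scale to the null SD of Dtest (see Details).
#' @return named numeric vector of per-SNP SD estimates, all `> 0`; ids of
#'   floored SNPs in `attr(, "floored")`.
#' @export
sdDnull <- function(dnull, method = c("binned_smoothed", "per_snp_rms"),
                    binSize = 1000, meanBaf = NULL, nSubpools = 2,
                    calibrate = TRUE) {
  method <- match.arg(method)
  rms <- sqrt(rowMeans(dnull^2, na.rm = TRUE))
  if (method == "per_snp_rms") {
    est <- rms
  } else {
    if (is.null(meanBaf))
      stop("meanBaf is required for the binned_smoothed estimator")
    stopifnot(length(meanBaf) == nrow(dnull))
    M <- nrow(dnull)
    # keep enough bins to track the allele-frequency dependence of
    # Var(Dnull) when M is small, without dropping below ~50 SNPs per bin
    effBinSize <- min(binSize, max(50, floor(M / 10)))
    ord <- order(meanBaf)
    bin <- ceiling(seq_len(M) / effBinSize)
    sq <- rowMeans(dnull^2, na.rm = TRUE)[ord]
    binRms <- sqrt(tapply(sq, bin, mean, na.rm = TRUE))
    est <- numeric(M)
    est[ord] <- binRms[bin]
    names(est) <- rownames(dnull)
  }
  pos <- est[is.finite(est) & est > 0]
  if (!length(pos)) stop("all Dnull contrasts are zero; SD(Dnull) undefined")
  floorVal <- as.numeric(quantile(pos, 0.001))
  floored <- !is.finite(est) | est <= 0
  est[floored] <- floorVal
  if (calibrate) est <- est * sqrt(1 / nSubpools)
  attr(est, "floored") <- rownames(dnull)[floored]
  est
}

#' The Z / chi-square(1) pool test
#'
#' `z = dTest / sdDnull`; `chi2 = z^2` is referred to a chi-square with one
#' degree of freedom (identically, the two-sided normal test of `z`).
#' Underflowing p-values are floored at the smallest positive double so the
#' result is always in (0, 1].
#'
#' @param dTest numeric vector of between-tail contrasts.
#' @param sdDnull matching vector of null SDs, all `> 0`.
#' @return data.frame with columns `z`, `chi2`, `p_value`.
#' @export
zTest <- function(dTest, sdDnull) {
  if (any(!is.na(sdDnull) & sdDnull <= 0))
    stop("sdDnull must be positive")
  z <- dTest / sdDnull
  chi2 <- z^2
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p[!is.na(p) & p == 0] <- .Machine$double.xmin
  data.frame(z = z, chi2 = chi2, p_value = p)
}

#' Bonferroni per-test threshold
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param nTests number of tests (>= 1).
#' @return the nominal per-test threshold `alpha / nTests`.
#' @examples
#' bonferroniThreshold(0.05, 655665)  # ~7.62e-08
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (nTests < 1) stop("nTests must be >= 1")
  alpha / nTests
}

#' Flag significant SNPs
#'
#' Significance uses `p_value <= threshold` (the boundary is significant).
#'
#' @param results data.frame with a `p_value` column.
#' @param threshold nominal per-test threshold in (0, 1).
#' @return `results` with a logical `significant` column.
#' @export
callSignificant <- function(results, threshold) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  results$significant <- !is.na(results$p_value) &
    results$p_value <= threshold
  results
}

#' Per-SNP selective-pooling association test
#'
#' Computes sub-pool means, the Dtest and Dnull contrasts, the SD(Dnull)
#' estimate, z / chi-square(1) p-values, and Bonferroni significance calls
#' at `alpha / n_retained`. SNPs whose design is incomplete (a tail with
#' fewer than two non-missing sub-pool means) are skipped and recorded in
#' `attr(, "skipped")`.
#'
#' @param x a [BafExperiment-class], normally QC-filtered, with a SNP map
#'   attached (see [attachSnpMap()]).
#' @param config an [SdpConfig-class].
#' @return data.frame with columns `snp_id`, `rs_id`, `chromosome`,
#'   `position`, `d_test`, `sd_dnull`, `z`, `chi2`, `p_value`,
#'   `significant`; attributes `threshold`, `n_tests`, `skipped`.
#' @export
sdpTest <- function(x, config = sdpConfig()) {
  keep <- missingDesignFilter(x)
  skipped <- keep$dropped
  x <- x[keep$kept, ]
  if (!nrow(x)) stop("no SNP has a complete pooling design")
  spm <- subpoolMeans(x)
  d <- dTest(spm)
  dn <- dNull(spm)
  info <- attr(spm, "groups")
  nSub <- min(table(info$tail))
  # tail-balanced mean BAF: invariant (bit-level) to relabelling the tails
  meanBaf <- (rowMeans(spm[, info$tail == "high", drop = FALSE], na.rm = TRUE) +
              rowMeans(spm[, info$tail == "low", drop = FALSE], na.rm = TRUE)) / 2
  sdn <- sdDnull(dn, method = config@sdDnullMethod, binSize = config@binSize,
                 meanBaf = meanBaf, nSubpools = nSub)
  zt <- zTest(d, sdn)
  rd <- snpInfo(x)
  res <- data.frame(
    snp_id = rd$snp_id,
    rs_id = if ("rs_id" %in% names(rd)) rd$rs_id else NA_character_,
    chromosome = if ("chromosome" %in% names(rd)) rd$chromosome else
      NA_character_,
    position = if ("position" %in% names(rd)) rd$position else NA_real_,
    d_test = as.numeric(d), sd_dnull = as.numeric(sdn),
    z = zt$z, chi2 = zt$chi2, p_value = zt$p_value,
    row.names = NULL)
  threshold <- bonferroniThreshold(config@alpha, nrow(res))
  res <- callSignificant(res, threshold)
  attr(res, "threshold") <- threshold
  attr(res, "n_tests") <- nrow(res)
  attr(res, "skipped") <- skipped
  res
}
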