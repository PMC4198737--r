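#' BafExperiment: pooled B-allele frequencies with the pooling design
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one assay
#' `"baf"` (SNP x measurement matrix of pooled B-allele frequencies in
#' \[0,1\], `NA` allowed) whose columns are labelled by the pooling design:
#' `colData` carries `tail` (`"high"`/`"low"`), `subpool`, `duplicate` and
#' `replicate` indices, and column names follow the on-disk grammar
#' `tail:subpool:duplicate:replicate` (e.g. `"high:1:2:3"`). `rowData`
#' carries `snp_id` and, once a SNP map is attached, `chromosome`,
#' `position` (1-based) and optional `rs_id`.
#'
#' @aliases BafExperiment-class
#' @exportClass BafExperiment
setClass("BafExperiment", contains = "SummarizedExperiment")

.validBafExperiment <- function(object) {
  msg <- NULL
  if (!"baf" %in% SummarizedExperiment::assayNames(object))
    return("assay 'baf' is missing")
  a <- SummarizedExperiment::assay(object, "baf")
  bad <- which(!is.na(a) & (a < 0 | a > 1))
  if (length(bad))
    msg <- c(msg, sprintf("%d BAF value(s) outside [0, 1]", length(bad)))
  cd <- SummarizedExperiment::colData(object)
  need <- c("tail", "subpool", "duplicate", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(c(msg, paste("colData lacks column(s):", paste(miss, collapse = ", "))))
  if (!all(cd$tail %in% c("high", "low")))
    msg <- c(msg, "tail labels must be 'high' or 'low'")
  for (tl in c("high", "low")) {
    nsub <- length(unique(cd$subpool[cd$tail == tl]))
    if (nsub < 2)
      msg <- c(msg, sprintf("tail '%s' has %d sub-pool(s); >= 2 required", tl, nsub))
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "measurement column labels are not unique")
  if (is.null(msg)) TRUE else msg
}
setValidity("BafExperiment", .validBafExperiment)

#' Construct a BafExperiment
#'
#' @param baf numeric matrix, SNPs in rows, measurements in columns; values
#'   in \[0,1\] or `NA`.
#' @param labels data.frame with columns `tail`, `subpool`, `duplicate`,
#'   `replicate`, one row per column of `baf` (see
#'   [enumerateMeasurements()]).
#' @param snpInfo optional data.frame of per-SNP metadata (`snp_id`,
#'   `chromosome`, `position`, `rs_id`); defaults to the rownames of `baf`.
#' @return a validated [BafExperiment-class] object.
#' @examples
#' lab <- enumerateMeasurements(2, 1, 1)
#' m <- matrix(0.5, 2, nrow(lab), dimnames = list(c("snp1", "snp2"), NULL))
#' BafExperiment(m, lab)
#' @export
BafExperiment <- function(baf, labels, snpInfo = NULL) {
  baf <- as.matrix(baf)
  labels <- as.data.frame(labels)
  stopifnot(ncol(baf) == nrow(labels))
  cn <- paste(labels$tail, labels$subpool, labels$duplicate,
              labels$replicate, sep = ":")
  colnames(baf) <- cn
  if (is.null(snpInfo)) {
    if (is.null(rownames(baf)))
      rownames(baf) <- sprintf("snp%d", seq_len(nrow(baf)))
    snpInfo <- S4Vectors::DataFrame(snp_id = rownames(baf))
  } else {
    snpInfo <- S4Vectors::DataFrame(snpInfo)
    rownames(baf) <- snpInfo$snp_id
  }
  rownames(snpInfo) <- snpInfo$snp_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(baf = baf),
    rowData = snpInfo,
    colData = S4Vectors::DataFrame(labels, row.names = cn))
  new("BafExperiment", se)
}

#' @describeIn BafExperiment the BAF assay matrix.
#' @param x,object a `BafExperiment`.
#' @export
bafValues <- function(x) SummarizedExperiment::assay(x, "baf")

#' @describeIn BafExperiment the measurement design labels (one row per
#'   column) as a data.frame.
#' @export
measurementInfo <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn BafExperiment per-SNP metadata as a data.frame.
#' @export
snpInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' Attach a SNP map to a BafExperiment
#'
#' Joins chromosome/position (and optional rs id) onto the rows. Every SNP
#' in the experiment must appear in the map.
#'
#' @param x a [BafExperiment-class].
#' @param map data.frame from [readSnpMap()].
#' @return `x` with completed `rowData`.
#' @export
attachSnpMap <- function(x, map) {
  ids <- rownames(x)
  hit <- match(ids, map$snp_id)
  if (anyNA(hit))
    stop("SNP(s) absent from map: ",
         paste(head(ids[is.na(hit)], 5), collapse = ", "))
  rd <- S4Vectors::DataFrame(
    snp_id = ids,
    rs_id = if ("rs_id" %in% names(map)) map$rs_id[hit] else NA_character_,
    chromosome = as.character(map$chromosome[hit]),
    position = as.numeric(map$position[hit]),
    row.names = ids)
  SummarizedExperiment::rowData(x) <- rd
  validObject(x)
  x
}

setMethod("show", "BafExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf(
    "BafExperiment: %d SNPs x %d measurements (%d tails, %d sub-pools, %d duplicates, %d replicates)\n",
    nrow(object), ncol(object), length(unique(cd$tail)),
    length(unique(cd$subpool)), length(unique(cd$duplicate)),
    length(unique(cd$replicate))))
  callNextMethod()
})

#' PoolDesign: tail/sub-pool membership and the measurement schedule
#'
#' @slot tailFraction fraction of ranked sires selected into each tail.
#' @slot nSubpools,nDuplicates,nReplicates design counts.
#' @slot membership `DataFrame` with columns `sire_id`, `tail`, `subpool`,
#'   `rank` (rank within tail, most extreme first).
#' @aliases PoolDesign-class
#' @exportClass PoolDesign
setClass("PoolDesign",
  representation(tailFraction = "numeric", nSubpools = "integer",
                 nDuplicates = "integer", nReplicates = "integer",
                 membership = "DataFrame"),
  prototype(tailFraction = 0.2, nSubpools = 2L, nDuplicates = 2L,
            nReplicates = 3L))

setValidity("PoolDesign", function(object) {
  msg <- NULL
  if (object@tailFraction <= 0 || object@tailFraction >= 0.5)
    msg <- c(msg, "tailFraction must lie in (0, 0.5)")
  if (any(c(object@nSubpools, object@nDuplicates, object@nReplicates) < 1L))
    msg <- c(msg, "design counts must be >= 1")
  m <- object@membership
  if (nrow(m)) {
    if (anyDuplicated(m$sire_id))
      msg <- c(msg, "a sire is assigned to more than one (tail, subpool)")
    if (!all(m$tail %in% c("high", "low")))
      msg <- c(msg, "membership tails must be 'high' or 'low'")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn PoolDesign sire membership as a data.frame.
#' @param x,object a `PoolDesign`.
#' @export
membership <- function(x) as.data.frame(x@membership)

setMethod("show", "PoolDesign", function(object) {
  m <- object@membership
  cat(sprintf("PoolDesign: tail fraction %.2f, %d sub-pools x %d duplicates x %d replicates\n",
              object@tailFraction, object@nSubpools, object@nDuplicates,
              object@nReplicates))
  if (nrow(m)) {
    tab <- table(m$tail, m$subpool)
    cat("sires per (tail, sub-pool):\n")
    print(tab)
  } else cat("(no membership assigned)\n")
})

#' ErrorModel: the two technical noise strata of pooled genotyping
#'
#' Gaussian noise on the BAF scale: `sigmaPool` is drawn once per duplicate
#' DNA pool (pool-construction error, shared by that pool's array
#' replicates); `sigmaArray` is drawn independently per array replicate.
#'
#' @slot sigmaPool,sigmaArray non-negative SDs in BAF units.
#' @aliases ErrorModel-class
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(sigmaPool = "numeric", sigmaArray = "numeric"),
  prototype(sigmaPool = 0.01, sigmaArray = 0.015))

setValidity("ErrorModel", function(object) {
  if (object@sigmaPool < 0 || object@sigmaArray < 0)
    "noise SDs must be >= 0" else TRUE
})

#' @rdname ErrorModel-class
#' @param sigmaPool,sigmaArray noise SDs in BAF units.
#' @export
errorModel <- function(sigmaPool = 0.01, sigmaArray = 0.015)
  new("ErrorModel", sigmaPool = sigmaPool, sigmaArray = sigmaArray)

setMethod("show", "ErrorModel", function(object)
  cat(sprintf("ErrorModel: sigma_pool = %g, sigma_array = %g (BAF units)\n",
              object@sigmaPool, object@sigmaArray)))

#' SdpConfig: analysis configuration
#'
#' @slot alpha genome-wide (family-wise) significance level.
#' @slot qcVariabilityFraction fraction of most variable SNPs excluded.
#' @slot monomorphicEpsilon BAF tolerance declaring a SNP monomorphic.
#' @slot sdDnullMethod `"binned_smoothed"` or `"per_snp_rms"`.
#' @slot binSize SNPs per bin for the smoothed SD(Dnull) estimator.
#' @slot regionMaxGap maximum inter-SNP distance (bp) merged into a region.
#' @slot regionMinSnps minimum SNPs per reported region.
#' @slot annotationWindow gene-proximity window (bp).
#' @slot seed integer seed for any stochastic step.
#' @aliases SdpConfig-class
#' @exportClass SdpConfig
setClass("SdpConfig",
  representation(alpha = "numeric", qcVariabilityFraction = "numeric",
                 monomorphicEpsilon = "numeric", sdDnullMethod = "character",
                 binSize = "integer", regionMaxGap = "numeric",
                 regionMinSnps = "integer", annotationWindow = "numeric",
                 seed = "integer"),
  prototype(alpha = 0.05, qcVariabilityFraction = 0.01,
            monomorphicEpsilon = 0.02, sdDnullMethod = "binned_smoothed",
            binSize = 1000L, regionMaxGap = 1e6, regionMinSnps = 3L,
            annotationWindow = 1e6, seed = 1L))

setValidity("SdpConfig", function(object) {
  msg <- NULL
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (object@qcVariabilityFraction < 0 || object@qcVariabilityFraction >= 1)
    msg <- c(msg, "qcVariabilityFraction must lie in [0, 1)")
  if (object@monomorphicEpsilon < 0 || object@monomorphicEpsilon >= 0.5)
    msg <- c(msg, "monomorphicEpsilon must lie in [0, 0.5)")
  if (!object@sdDnullMethod %in% c("binned_smoothed", "per_snp_rms"))
    msg <- c(msg, "sdDnullMethod must be 'binned_smoothed' or 'per_snp_rms'")
  if (object@regionMaxGap <= 0 || object@annotationWindow <= 0)
    msg <- c(msg, "gaps and windows must be positive")
  if (object@regionMinSnps < 1L || object@binSize < 1L)
    msg <- c(msg, "counts must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SdpConfig-class
#' @param alpha,qcVariabilityFraction,monomorphicEpsilon,sdDnullMethod
#'   see slots.
#' @param binSize,regionMaxGap,regionMinSnps,annotationWindow,seed see slots.
#' @export
sdpConfig <- function(alpha = 0.05, qcVariabilityFraction = 0.01,
                      monomorphicEpsilon = 0.02,
                      sdDnullMethod = "binned_smoothed", binSize = 1000,
                      regionMaxGap = 1e6, regionMinSnps = 3,
                      annotationWindow = 1e6, seed = 1) {
  new("SdpConfig", alpha = alpha,
      qcVariabilityFraction = qcVariabilityFraction,
      monomorphicEpsilon = monomorphicEpsilon,
      sdDnullMethod = sdDnullMethod, binSize = as.integer(binSize),
      regionMaxGap = regionMaxGap, regionMinSnps = as.integer(regionMinSnps),
      annotationWindow = annotationWindow, seed = as.integer(seed))
}

setMethod("show", "SdpConfig", function(object) {
  cat("SdpConfig:\n",
      sprintf("  alpha                 %g\n", object@alpha),
      sprintf("  qcVariabilityFraction %g\n", object@qcVariabilityFraction),
      sprintf("  monomorphicEpsilon    %g\n", object@monomorphicEpsilon),
      sprintf("  sdDnullMethod         %s (binSize %d)\n",
              object@sdDnullMethod, object@binSize),
      sprintf("  regionMaxGap          %g bp (minSnps %d)\n",
              object@regionMaxGap, object@regionMinSnps),
      sprintf("  annotationWindow      %g bp\n", object@annotationWindow),
      sprintf("  seed                  %d\n", object@seed), sep = "")
})

#' QcReport: accounting of the pre-test SNP filters
#'
#' @slot nInput SNPs entering QC.
#' @slot droppedVariability,droppedMonomorphic,droppedMissingDesign ids of
#'   SNPs removed by each filter (applied in that order).
#' @slot nRetained SNPs surviving all filters.
#' @slot normality data.frame of normality tests on the Dnull distribution
#'   (Anderson-Darling, Shapiro-Wilk, Kolmogorov-Smirnov).
#' @aliases QcReport-class
#' @exportClass QcReport
setClass("QcReport",
  representation(nInput = "integer", droppedVariability = "character",
                 droppedMonomorphic = "character",
                 droppedMissingDesign = "character",
                 nRetained = "integer", normality = "data.frame"))

setValidity("QcReport", function(object) {
  dropped <- unique(c(object@droppedVariability, object@droppedMonomorphic,
                      object@droppedMissingDesign))
  if (object@nRetained != object@nInput - length(dropped))
    "nRetained must equal nInput minus the union of dropped sets" else TRUE
})

setMethod("show", "QcReport", function(object) {
  cat(sprintf("QcReport: %d SNPs in, %d retained\n",
              object@nInput, object@nRetained))
  cat(sprintf("  dropped: %d high-variability, %d monomorphic, %d incomplete design\n",
              length(object@droppedVariability),
              length(object@droppedMonomorphic),
              length(object@droppedMissingDesign)))
  if (nrow(object@normality)) {
    cat("  Dnull normality:\n")
    print(object@normality, row.names = FALSE)
  }
})
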