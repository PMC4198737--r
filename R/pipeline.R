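# End-to-end orchestration: QC -> association -> regions -> annotation ->
# report.

#' Run the full selective-pooling scan
#'
#' Reads the BAF matrix, SNP map and gene BED, applies QC, runs the per-SNP
#' test with Bonferroni control at `alpha / n_retained`, assembles candidate
#' regions from the significant SNPs, annotates them by gene proximity,
#' writes all result tables, the Q-Q/Manhattan plots and a YAML run
#' summary.
#'
#' @param config an [SdpConfig-class].
#' @param bafPath BAF matrix TSV (see [readBafMatrix()]).
#' @param mapPath SNP map TSV (see [readSnpMap()]).
#' @param genesPath gene BED file (see [readGeneBed()]); `NULL` skips
#'   annotation.
#' @param outDir output directory.
#' @return invisibly, a list with `summary` (stage counts and thresholds),
#'   `results`, `regions`, `annotations`, `qc` (the [QcReport-class]) and
#'   `paths`.
#' @export
runPipeline <- function(config, bafPath, mapPath, genesPath = NULL, outDir) {
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  baf <- stage("input", {
    be <- readBafMatrix(bafPath)
    attachSnpMap(be, readSnpMap(mapPath))
  })
  genes <- if (is.null(genesPath)) NULL else
    stage("input", readGeneBed(genesPath))
  qc <- stage("qc", runQc(baf, config))
  results <- stage("association", sdpTest(qc$baf, config))
  sig <- results[results$significant, , drop = FALSE]
  regions <- stage("regions",
    buildRegions(sig, maxGap = config@regionMaxGap,
                 minSnps = config@regionMinSnps))
  annotations <- if (is.null(genes) || !nrow(sig))
    data.frame(snp_id = character(0), status = character(0),
               genes = character(0), distance = numeric(0))
  else stage("annotation",
    annotateSnps(sig, genes, window = config@annotationWindow))
  paths <- stage("report", {
    p <- writeResults(results, regions, annotations, outDir)
    qq <- qqData(results$p_value)
    man <- manhattanData(results, threshold = attr(results, "threshold"))
    c(p, renderPlots(qq, man, outDir))
  })
  rpt <- qc$report
  summary <- list(
    n_input = rpt@nInput,
    n_dropped_variability = length(rpt@droppedVariability),
    n_dropped_monomorphic = length(rpt@droppedMonomorphic),
    n_dropped_missing_design = length(rpt@droppedMissingDesign),
    n_retained = rpt@nRetained,
    n_tested = attr(results, "n_tests"),
    alpha = config@alpha,
    nominal_threshold = attr(results, "threshold"),
    n_significant = sum(results$significant),
    n_regions = length(regions))
  summaryPath <- file.path(outDir, "summary.yaml")
  yaml::write_yaml(summary, summaryPath)
  invisible(list(summary = summary, results = results, regions = regions,
                 annotations = annotations, qc = rpt,
                 paths = c(paths, summary = summaryPath)))
}
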