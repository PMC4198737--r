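# Readers and writers for the plain-text interchange formats.
#
# BAF matrix TSV: header "snp_id" then one column per measurement named
# "tail:subpool:duplicate:replicate"; body rows are snp_id followed by
# numeric BAF values (NA allowed). SNP map TSV: snp_id, chromosome,
# position[, rs_id]. Genes: BED (0-based half-open), converted to 1-based
# inclusive coordinates at this boundary.

.labelRegex <- "^(high|low):([0-9]+):([0-9]+):([0-9]+)$"

parseMeasurementLabels <- function(labels) {
  bad <- labels[!grepl(.labelRegex, labels)]
  if (length(bad))
    stop("malformed measurement column label(s): ",
         paste(bad, collapse = ", "),
         " (expected tail:subpool:duplicate:replicate, e.g. high:1:2:3)")
  parts <- strsplit(labels, ":", fixed = TRUE)
  out <- data.frame(
    tail = vapply(parts, `[`, "", 1L),
    subpool = as.integer(vapply(parts, `[`, "", 2L)),
    duplicate = as.integer(vapply(parts, `[`, "", 3L)),
    replicate = as.integer(vapply(parts, `[`, "", 4L)))
  if (anyDuplicated(labels))
    stop("duplicated measurement column label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  out
}

#' Read a pooled BAF matrix
#'
#' @param path TSV file; header `snp_id` plus one column per measurement
#'   named `tail:subpool:duplicate:replicate`.
#' @return a [BafExperiment-class].
#' @export
readBafMatrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "snp_id")
    stop("BAF matrix header must start with 'snp_id': ", path)
  labels <- parseMeasurementLabels(header[-1L])
  df <- read.delim(path, colClasses = c("character",
                                        rep("numeric", nrow(labels))),
                   check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$snp_id
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("BAF value out of [0, 1] at SNP '%s', column '%s': %g",
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]],
                 m[bad[1L, , drop = FALSE]]))
  BafExperiment(m, labels)
}

#' Write a pooled BAF matrix
#'
#' Inverse of [readBafMatrix()]; lossless up to float formatting.
#'
#' @param x a [BafExperiment-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeBafMatrix <- function(x, path) {
  m <- bafValues(x)
  df <- data.frame(snp_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP map
#'
#' @param path TSV with columns `snp_id`, `chromosome`, `position` (1-based)
#'   and optionally `rs_id`.
#' @return data.frame sorted by (chromosome, position), chromosomes in
#'   natural order (1..29 then X, ...).
#' @export
readSnpMap <- function(path) {
  df <- read.delim(path, colClasses = "character")
  need <- c("snp_id", "chromosome", "position")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("SNP map lacks column(s): ", paste(miss, collapse = ", "))
  badPos <- !grepl("^[0-9]+$", df$position)
  if (any(badPos))
    stop("non-integer position for SNP(s): ",
         paste(head(df$snp_id[badPos], 5), collapse = ", "))
  df$position <- as.numeric(df$position)
  if (any(df$position < 1))
    stop("positions must be >= 1 (1-based coordinates)")
  if (anyDuplicated(df$snp_id))
    stop("duplicated snp_id(s): ",
         paste(unique(df$snp_id[duplicated(df$snp_id)]), collapse = ", "))
  lev <- chromosomeLevels(df$chromosome)
  df <- df[order(match(df$chromosome, lev), df$position), , drop = FALSE]
  rownames(df) <- NULL
  df[, intersect(c("snp_id", "chromosome", "position", "rs_id"), names(df))]
}

#' Read gene intervals from BED
#'
#' BED is 0-based half-open; the returned `GRanges` is 1-based inclusive
#' (`start_1based = start + 1`, `end_1based = end`), with the BED name
#' column as `symbol`.
#'
#' @param path BED file with at least chrom, start, end, name.
#' @return a [GenomicRanges::GRanges] with metadata column `symbol`.
#' @export
readGeneBed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop("invalid BED file '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  if (length(gr) && (is.null(gr$name) || anyNA(gr$name)))
    stop("BED name column (gene symbol) is required: ", path)
  mc <- S4Vectors::DataFrame(symbol = if (length(gr)) gr$name else character(0))
  S4Vectors::mcols(gr) <- mc
  gr
}

#' Write per-SNP results, regions and annotations
#'
#' `results.tsv` holds every per-SNP field; `regions.tsv` follows the
#' candidate-region table shape (chromosome, start, end, length, n_snps,
#' members); `annotations.tsv` one row per significant SNP.
#'
#' @param results data.frame from [sdpTest()].
#' @param regions `GRanges` from [buildRegions()] (may be empty).
#' @param annotations data.frame from [annotateSnps()] (may be empty).
#' @param outDir output directory, created if needed.
#' @return named character vector of the files written.
#' @export
writeResults <- function(results, regions, annotations, outDir) {
  if (!nrow(results)) stop("results must be non-empty")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  paths <- c(results = file.path(outDir, "results.tsv"),
             regions = file.path(outDir, "regions.tsv"),
             annotations = file.path(outDir, "annotations.tsv"))
  write.table(results, paths["results"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(regionsAsFrame(regions), paths["regions"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  ann <- if (nrow(as.data.frame(annotations))) as.data.frame(annotations) else
    data.frame(snp_id = character(0), status = character(0),
               genes = character(0), distance = numeric(0))
  write.table(ann, paths["annotations"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

#' Read back files written by [writeResults()]
#'
#' @param outDir directory holding `results.tsv`, `regions.tsv`,
#'   `annotations.tsv`.
#' @return list with elements `results`, `regions`, `annotations`.
#' @export
readResults <- function(outDir) {
  res <- read.delim(file.path(outDir, "results.tsv"),
                    colClasses = c(snp_id = "character",
                                   chromosome = "character"))
  reg <- read.delim(file.path(outDir, "regions.tsv"),
                    colClasses = c(chromosome = "character"))
  ann <- read.delim(file.path(outDir, "annotations.tsv"),
                    colClasses = c(snp_id = "character"))
  list(results = res, regions = reg, annotations = ann)
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [sdpConfig()] defaults.
#'
#' @param path YAML file.
#' @return an [SdpConfig-class].
#' @export
readSdpConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(sdpConfig))
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  do.call(sdpConfig, y)
}

#' Write an analysis configuration to YAML
#'
#' @param config an [SdpConfig-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSdpConfig <- function(config, path) {
  yaml::write_yaml(list(
    alpha = config@alpha,
    qcVariabilityFraction = config@qcVariabilityFraction,
    monomorphicEpsilon = config@monomorphicEpsilon,
    sdDnullMethod = config@sdDnullMethod,
    binSize = config@binSize,
    regionMaxGap = config@regionMaxGap,
    regionMinSnps = config@regionMinSnps,
    annotationWindow = config@annotationWindow,
    seed = config@seed), path)
  invisible(path)
}
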