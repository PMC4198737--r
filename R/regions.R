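# Candidate chromosome regions and gene-proximity annotation.

#' Assemble significant SNPs into candidate regions
#'
#' Single-linkage merge within chromosomes: consecutive significant SNPs
#' closer than or equal to `maxGap` base pairs join one region; regions
#' carrying at least `minSnps` SNPs are reported. Region length is
#' `end - start` (the convention of the published candidate-region tables).
#'
#' @param snps data.frame of significant SNPs with columns `chromosome`,
#'   `position` and `snp_id` (optionally `rs_id`, preferred for member
#'   lists). Unsorted input is sorted internally.
#' @param maxGap maximum inter-SNP distance merged (bp, default 1e6).
#' @param minSnps minimum SNPs per reported region (default 3).
#' @return a [GenomicRanges::GRanges], sorted, with metadata columns
#'   `region_length` (= end - start), `n_snps` and `members`
#'   (a `CharacterList` in position order).
#' @export
buildRegions <- function(snps, maxGap = 1e6, minSnps = 3) {
  if (maxGap <= 0) stop("maxGap must be positive")
  if (minSnps < 1) stop("minSnps must be >= 1")
  lev <- chromosomeLevels(snps$chromosome)
  emptyOut <- GenomicRanges::GRanges(seqnames = factor(levels = lev),
    ranges = IRanges::IRanges(),
    region_length = numeric(0), n_snps = integer(0),
    members = IRanges::CharacterList())
  if (!nrow(snps)) return(emptyOut)
  snps <- snps[order(match(snps$chromosome, lev), snps$position), ,
               drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = factor(snps$chromosome, levels = lev),
    ranges = IRanges::IRanges(start = snps$position, width = 1L))
  # reduce() merges ranges whose gap is < min.gapwidth; two point SNPs at
  # distance d have gap d - 1, so min.gapwidth = maxGap merges iff d <= maxGap
  red <- GenomicRanges::reduce(gr, min.gapwidth = maxGap)
  hits <- GenomicRanges::findOverlaps(gr, red)
  counts <- tabulate(S4Vectors::subjectHits(hits), length(red))
  keep <- counts >= minSnps
  red <- red[keep]
  if (!length(red)) return(emptyOut)
  ids <- snps$snp_id
  if ("rs_id" %in% names(snps)) {
    use <- !is.na(snps$rs_id) & snps$rs_id != ""
    ids[use] <- snps$rs_id[use]
  }
  hits <- GenomicRanges::findOverlaps(gr, red)
  members <- unname(S4Vectors::splitAsList(
    ids[S4Vectors::queryHits(hits)],
    factor(S4Vectors::subjectHits(hits), levels = seq_along(red))))
  S4Vectors::mcols(red) <- S4Vectors::DataFrame(
    region_length = GenomicRanges::end(red) - GenomicRanges::start(red),
    n_snps = lengths(members),
    members = members)
  GenomicRanges::sort(red)
}

#' Flatten a regions GRanges into the export table shape
#'
#' @param regions `GRanges` from [buildRegions()].
#' @return data.frame with columns `chromosome`, `start`, `end`, `length`,
#'   `n_snps`, `members` (semicolon-separated).
#' @export
regionsAsFrame <- function(regions) {
  if (!length(regions))
    return(data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0),
                      n_snps = integer(0), members = character(0)))
  data.frame(
    chromosome = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions),
    end = GenomicRanges::end(regions),
    length = regions$region_length,
    n_snps = regions$n_snps,
    members = vapply(regions$members, paste, "", collapse = ";"))
}

#' Annotate SNPs by gene proximity
#'
#' A SNP inside a gene interval is `intragenic` (distance 0, all containing
#' genes listed); otherwise, if the nearest gene boundary lies within
#' `window` base pairs it is `nearby` (distance
#' `min_g min(|pos - start_g|, |pos - end_g|)`, nearest gene(s) listed,
#' boundary `<= window` inclusive); otherwise `intergenic`. Statuses are
#' exclusive with intragenic priority, and the result is invariant to gene
#' list order.
#'
#' @param snps data.frame with columns `snp_id`, `chromosome`, `position`.
#' @param genes `GRanges` with metadata column `symbol` (see
#'   [readGeneBed()]).
#' @param window proximity window in bp (default 1e6).
#' @return data.frame with columns `snp_id`, `status`, `genes`
#'   (semicolon-separated, alphabetical; `""` if intergenic) and `distance`
#'   (0 if intragenic, `NA` if intergenic).
#' @export
annotateSnps <- function(snps, genes, window = 1e6) {
  if (window <= 0) stop("window must be positive")
  n <- nrow(snps)
  status <- rep("intergenic", n)
  geneStr <- rep("", n)
  dist <- rep(NA_real_, n)
  gChrom <- as.character(GenomicRanges::seqnames(genes))
  gStart <- GenomicRanges::start(genes)
  gEnd <- GenomicRanges::end(genes)
  gSym <- genes$symbol
  for (i in seq_len(n)) {
    onChrom <- which(gChrom == snps$chromosome[i])
    if (!length(onChrom)) next
    pos <- snps$position[i]
    inside <- onChrom[gStart[onChrom] <= pos & pos <= gEnd[onChrom]]
    if (length(inside)) {
      status[i] <- "intragenic"
      geneStr[i] <- paste(sort(unique(gSym[inside])), collapse = ";")
      dist[i] <- 0
      next
    }
    d <- pmin(abs(pos - gStart[onChrom]), abs(pos - gEnd[onChrom]))
    dmin <- min(d)
    if (dmin <= window) {
      status[i] <- "nearby"
      geneStr[i] <- paste(sort(unique(gSym[onChrom[d == dmin]])),
                          collapse = ";")
      dist[i] <- dmin
    }
  }
  data.frame(snp_id = snps$snp_id, status = status, genes = geneStr,
             distance = dist)
}
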