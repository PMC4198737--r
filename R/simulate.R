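# Synthetic cohorts, genotypes and pooled BAF measurements.
#
# The generator emulates the full selective-pooling design: sires carry a
# deregressed breeding value (DP-EBV) driven by planted QTL plus Gaussian
# polygenic/record noise; tails are pooled and each (tail, sub-pool) is
# measured through duplicate DNA pools (shared construction error) and
# array replicates (independent error), clipped to [0, 1].

#' Simulate a sire cohort with planted QTL
#'
#' Per SNP m a population B-allele frequency p_m ~ Uniform(0.05, 0.95) is
#' drawn and genotypes g ~ Binomial(2, p_m) independently across SNPs (no
#' linkage disequilibrium). Each sire's DP-EBV is
#' sum_q effect_q * (g_q - 2 p_q) + N(0, noiseSd^2), so with `noiseSd = 1`
#' effects are expressed in residual trait-SD units. Reliability is drawn
#' Uniform(0.45, 0.65) and carried for descriptive summaries only (the test
#' does not weight by it).
#'
#' @param nSires cohort size (>= 4).
#' @param snpMap data.frame from [readSnpMap()] (defines SNP ids and order).
#' @param qtls optional data.frame with columns `snp_index` (row index into
#'   `snpMap`, distinct) and `effect` (trait units per B-allele copy).
#' @param noiseSd SD of the non-QTL component of the DP-EBV.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return list with `sires` (data.frame `sire_id`, `dp_ebv`, `reliability`,
#'   `father_id`), `genotypes` (SNP x sire integer matrix of B-allele
#'   counts) and `truth` (list: `qtls`, `pop_freqs`, `seed`).
#' @export
simulateCohort <- function(nSires, snpMap, qtls = NULL, noiseSd = 1,
                           seed = 1) {
  if (nSires < 4L) stop("nSires must be >= 4")
  M <- nrow(snpMap)
  if (!is.null(qtls) && nrow(qtls)) {
    if (anyDuplicated(qtls$snp_index)) stop("duplicate QTL snp_index")
    if (any(qtls$snp_index < 1L | qtls$snp_index > M))
      stop("QTL snp_index out of range")
    if (any(!is.finite(qtls$effect))) stop("QTL effects must be finite")
  }
  withSeed(seed, {
    p <- runif(M, 0.05, 0.95)
    G <- matrix(rbinom(M * nSires, 2L, p), nrow = M, ncol = nSires)
    ebv <- rnorm(nSires, 0, noiseSd)
    if (!is.null(qtls) && nrow(qtls)) {
      idx <- qtls$snp_index
      centred <- G[idx, , drop = FALSE] - 2 * p[idx]
      ebv <- ebv + as.numeric(crossprod(centred, qtls$effect))
    }
    rel <- runif(nSires, 0.45, 0.65)
    ids <- sprintf("S%05d", seq_len(nSires))
    dimnames(G) <- list(snpMap$snp_id, ids)
    list(sires = data.frame(sire_id = ids, dp_ebv = ebv, reliability = rel,
                            father_id = NA_character_),
         genotypes = G,
         truth = list(qtls = qtls, pop_freqs = p, seed = as.integer(seed)))
  })
}

#' Simulate pooled BAF measurements under a pool design
#'
#' For each (tail, sub-pool) the true pool frequency is the mean B-allele
#' dosage of its member sires divided by two. Each duplicate DNA pool adds
#' one construction-error draw N(0, sigmaPool^2) shared by its replicates;
#' each array replicate adds an independent N(0, sigmaArray^2); measurements
#' are clipped to [0, 1]. Columns follow the full design crossing in
#' lexicographic order.
#'
#' @param design a [PoolDesign-class] with membership assigned.
#' @param genotypes SNP x sire matrix of B-allele counts (columns named by
#'   sire id), e.g. from [simulateCohort()].
#' @param snpMap optional SNP map attached to the result's rows.
#' @param error an [ErrorModel-class].
#' @param seed integer seed.
#' @return list with `baf` (a [BafExperiment-class]) and `truth` (list:
#'   `true_pool_freqs`, SNP x (tail, sub-pool) matrix; `seed`).
#' @export
simulatePoolMeasurements <- function(design, genotypes, snpMap = NULL,
                                     error = errorModel(), seed = 1) {
  mem <- membership(design)
  if (!nrow(mem)) stop("design has no membership assigned")
  groups <- split(mem$sire_id, list(tail = mem$tail, subpool = mem$subpool),
                  drop = TRUE)
  if (any(!lengths(groups))) stop("empty sub-pool in design")
  for (tl in unique(mem$tail))
    if (length(unique(mem$subpool[mem$tail == tl])) < 2L)
      stop(sprintf("tail '%s' needs >= 2 sub-pools", tl))
  missing <- setdiff(mem$sire_id, colnames(genotypes))
  if (length(missing))
    stop("sires without genotypes: ", paste(head(missing, 5), collapse = ", "))
  M <- nrow(genotypes)
  labels <- enumerateMeasurements(design@nSubpools, design@nDuplicates,
                                  design@nReplicates)
  tls <- unique(labels$tail)
  f <- sapply(tls, function(tl) sapply(seq_len(design@nSubpools), function(s) {
    ids <- mem$sire_id[mem$tail == tl & mem$subpool == s]
    rowMeans(genotypes[, ids, drop = FALSE]) / 2
  }), simplify = FALSE)
  withSeed(seed, {
    baf <- matrix(NA_real_, M, nrow(labels))
    col <- 0L
    for (tl in tls) for (s in seq_len(design@nSubpools)) {
      for (d in seq_len(design@nDuplicates)) {
        delta <- rnorm(M, 0, error@sigmaPool)
        for (r in seq_len(design@nReplicates)) {
          col <- col + 1L
          baf[, col] <- clip01(f[[tl]][, s] + delta +
                                 rnorm(M, 0, error@sigmaArray))
        }
      }
    }
    rownames(baf) <- rownames(genotypes)
    truthF <- do.call(cbind, lapply(tls, function(tl) {
      m <- f[[tl]]
      colnames(m) <- paste(tl, seq_len(ncol(m)), sep = ":")
      m
    }))
    be <- BafExperiment(baf, labels)
    if (!is.null(snpMap)) be <- attachSnpMap(be, snpMap)
    list(baf = be,
         truth = list(true_pool_freqs = truthF, seed = as.integer(seed)))
  })
}

#' Write a small deterministic end-to-end fixture
#'
#' Two chromosomes, 500 SNPs, 80 sires, two planted QTL of effect 1.0
#' residual-SD (one per chromosome) and three toy genes (one containing the
#' first QTL SNP, one within 1 Mb of the second, one far from both). Used
#' by the test-suite and documentation; the same seed always yields
#' byte-identical files.
#'
#' @param dir output directory (created).
#' @param seed integer seed.
#' @return invisibly, a list with the in-memory objects (`baf`, `snpMap`,
#'   `sires`, `genes`, `design`, `truth`) and the file `paths` written
#'   (`baf.tsv`, `snp_map.tsv`, `sires.tsv`, `genes.bed`, `truth.yaml`).
#' @export
makeToyFixture <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nSnp <- 500L; nChrom <- 2L; perChrom <- nSnp / nChrom
  snpMap <- withSeed(seed, {
    pos <- lapply(seq_len(nChrom), function(i)
      sort(sample.int(6e7, perChrom)))
    data.frame(
      snp_id = sprintf("SNP%02d%04d", rep(seq_len(nChrom), each = perChrom),
                       rep(seq_len(perChrom), nChrom)),
      chromosome = as.character(rep(seq_len(nChrom), each = perChrom)),
      position = unlist(pos),
      rs_id = sprintf("rs%07d", seq_len(nSnp)))
  })
  # one causal SNP mid-chromosome on each chromosome
  qtls <- data.frame(snp_index = c(perChrom %/% 2L, perChrom + perChrom %/% 2L),
                     effect = c(1.0, 1.0))
  cohort <- simulateCohort(80L, snpMap, qtls, noiseSd = 1, seed = seed + 1L)
  design <- buildPoolDesign(cohort$sires, tailFraction = 0.2)
  sim <- simulatePoolMeasurements(design, cohort$genotypes, snpMap,
                                  error = errorModel(), seed = seed + 2L)
  qtlPos <- snpMap$position[qtls$snp_index]
  qtlChrom <- snpMap$chromosome[qtls$snp_index]
  genes <- data.frame(
    chromosome = c(qtlChrom[1L], qtlChrom[2L], qtlChrom[2L]),
    start1 = c(qtlPos[1L] - 5e3, qtlPos[2L] + 5e5, qtlPos[2L] + 5e6),
    end1 = c(qtlPos[1L] + 5e3, qtlPos[2L] + 6e5, qtlPos[2L] + 5.1e6),
    symbol = c("TOYG1", "TOYG2", "TOYG3"))
  paths <- c(baf = file.path(dir, "baf.tsv"),
             map = file.path(dir, "snp_map.tsv"),
             sires = file.path(dir, "sires.tsv"),
             genes = file.path(dir, "genes.bed"),
             truth = file.path(dir, "truth.yaml"))
  writeBafMatrix(sim$baf, paths["baf"])
  write.table(snpMap, paths["map"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$sires, paths["sires"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  # BED is 0-based half-open: start0 = start1 - 1
  bed <- data.frame(genes$chromosome, genes$start1 - 1L, genes$end1,
                    genes$symbol)
  write.table(bed, paths["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(
    seed = as.integer(seed),
    qtls = lapply(seq_len(nrow(qtls)), function(i) list(
      snp_index = qtls$snp_index[i],
      snp_id = snpMap$snp_id[qtls$snp_index[i]],
      chromosome = qtlChrom[i], position = qtlPos[i],
      effect = qtls$effect[i]))), paths["truth"])
  invisible(list(baf = sim$baf, snpMap = snpMap, sires = cohort$sires,
                 genes = genes, design = design,
                 truth = c(cohort$truth, sim$truth), paths = paths))
}
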