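# Pool design: tail selection, even/odd sub-pooling, measurement schedule.

#' Rank sires and select the distribution tails
#'
#' Sires are sorted by `dp_ebv` descending (ties broken by `sire_id`, so the
#' selection is deterministic and invariant to input order). The top
#' `floor(tailFraction * n)` go to the high tail and the bottom
#' `floor(tailFraction * n)` to the low tail, optionally capped per tail —
#' the cap reproduces designs where fewer samples are physically available
#' than the nominal tail size (e.g. 40 high / 39 low from 275 candidates).
#'
#' @param sires data.frame with columns `sire_id`, `dp_ebv`.
#' @param tailFraction fraction in (0, 0.5) selected into each tail.
#' @param maxPerTail optional cap: a single count or `c(high =, low =)`.
#' @return data.frame `sire_id`, `tail`, `rank` (within tail, most extreme
#'   first).
#' @export
rankAndSelectTails <- function(sires, tailFraction = 0.2, maxPerTail = NULL) {
  if (nrow(sires) < 2L) stop("need at least 2 sires")
  if (tailFraction <= 0 || tailFraction >= 0.5)
    stop("tailFraction must lie in (0, 0.5)")
  stopifnot(all(is.finite(sires$dp_ebv)))
  if (anyDuplicated(sires$sire_id)) stop("sire_id values must be unique")
  nTail <- floor(tailFraction * nrow(sires))
  if (nTail < 1L) stop("tailFraction selects no sires")
  caps <- c(high = nTail, low = nTail)
  if (!is.null(maxPerTail)) {
    if (is.null(names(maxPerTail))) maxPerTail <- rep(maxPerTail, length.out = 2)
    else maxPerTail <- maxPerTail[c("high", "low")]
    caps <- pmin(caps, maxPerTail)
  }
  ord <- order(-sires$dp_ebv, sires$sire_id)
  high <- sires$sire_id[ord][seq_len(caps["high"])]
  low <- sires$sire_id[rev(ord)][seq_len(caps["low"])]  # most extreme first
  if (length(intersect(high, low)))
    stop("tails overlap: cohort too small for this tailFraction")
  data.frame(
    sire_id = c(high, low),
    tail = rep(c("high", "low"), c(length(high), length(low))),
    rank = c(seq_along(high), seq_along(low)))
}

#' Split a ranked tail into even/odd sub-pools
#'
#' Members must be in rank order (most extreme first); odd ranks (1st, 3rd,
#' ...) form sub-pool 1 and even ranks sub-pool 2, so the two sub-pools have
#' comparable mean phenotype by construction and sizes differing by at most
#' one.
#'
#' @param members character vector of sire ids in rank order.
#' @return list of two character vectors, `subpool1` and `subpool2`.
#' @export
splitEvenOdd <- function(members) {
  if (length(members) < 2L) stop("need at least 2 members to split")
  list(subpool1 = members[seq(1L, length(members), by = 2L)],
       subpool2 = members[seq(2L, length(members), by = 2L)])
}

#' Enumerate the measurement schedule
#'
#' Full crossing tail x sub-pool x duplicate x replicate in lexicographic
#' order (tail `high` before `low`, then sub-pool, duplicate, replicate).
#' A (2, 2, 3) design yields the 24 chip positions of a standard two-tail
#' pooled genotyping run.
#'
#' @param nSubpools,nDuplicates,nReplicates counts, all >= 1.
#' @return data.frame with columns `tail`, `subpool`, `duplicate`,
#'   `replicate`, one row per measurement.
#' @export
enumerateMeasurements <- function(nSubpools = 2, nDuplicates = 2,
                                  nReplicates = 3) {
  if (any(c(nSubpools, nDuplicates, nReplicates) < 1L))
    stop("all design counts must be >= 1")
  g <- expand.grid(replicate = seq_len(nReplicates),
                   duplicate = seq_len(nDuplicates),
                   subpool = seq_len(nSubpools),
                   tail = c("high", "low"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("tail", "subpool", "duplicate", "replicate")]
  rownames(g) <- NULL
  g
}

#' Build a complete pool design from a sire cohort
#'
#' Combines [rankAndSelectTails()] and the even/odd split (generalised to
#' `nSubpools` by round-robin over ranks) into a [PoolDesign-class].
#'
#' @inheritParams rankAndSelectTails
#' @param nSubpools,nDuplicates,nReplicates design counts.
#' @return a [PoolDesign-class].
#' @export
buildPoolDesign <- function(sires, tailFraction = 0.2, maxPerTail = NULL,
                            nSubpools = 2, nDuplicates = 2, nReplicates = 3) {
  sel <- rankAndSelectTails(sires, tailFraction, maxPerTail)
  sel$subpool <- ((sel$rank - 1L) %% as.integer(nSubpools)) + 1L
  for (tl in c("high", "low")) {
    nsub <- length(unique(sel$subpool[sel$tail == tl]))
    if (nsub < nSubpools)
      stop(sprintf("tail '%s' too small to fill %d sub-pools", tl, nSubpools))
  }
  new("PoolDesign", tailFraction = tailFraction,
      nSubpools = as.integer(nSubpools), nDuplicates = as.integer(nDuplicates),
      nReplicates = as.integer(nReplicates),
      membership = S4Vectors::DataFrame(
        sel[, c("sire_id", "tail", "subpool", "rank")]))
}

#' Check family structure of the selected sires
#'
#' Advisory check against over-representation of one sire family: one
#' warning string per father contributing more than `maxSons` selected sons.
#' Never alters the selection.
#'
#' @param sires data.frame with columns `sire_id` and `father_id`
#'   (`NA` allowed); typically the selected subset.
#' @param maxSons maximum tolerated selected sons per father.
#' @return character vector of warnings (empty if none, or if no father
#'   information is present).
#' @export
checkFamilyStructure <- function(sires, maxSons = 6) {
  if (!"father_id" %in% names(sires)) return(character(0))
  fathers <- sires$father_id[!is.na(sires$father_id)]
  if (!length(fathers)) return(character(0))
  tab <- table(fathers)
  over <- tab[tab > maxSons]
  if (!length(over)) return(character(0))
  sprintf("father '%s' has %d selected sons (more than %d)",
          names(over), as.integer(over), maxSons)
}
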