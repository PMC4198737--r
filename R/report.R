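# Q-Q and Manhattan plot data and rendering.

#' Q-Q plot data on the -log10 scale
#'
#' Expected quantile for the i-th smallest of n p-values is `(i - 0.5) / n`.
#' Rows are returned with the `expected` column strictly increasing (the
#' largest p first). Zero p-values are clamped to the smallest positive
#' double, with a message.
#'
#' @param p numeric vector of p-values in (0, 1\].
#' @return data.frame with columns `expected`, `observed` (-log10 scale).
#' @export
qqData <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    message(sum(p == 0), " zero p-value(s) clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  n <- length(p)
  i <- n:1                       # rank of the sorted (ascending) p-values
  data.frame(expected = -log10((i - 0.5) / n),
             observed = -log10(sort(p)[i]))
}

#' Manhattan plot data
#'
#' Cumulative x-coordinate: the SNP position plus the summed maximum
#' positions of all preceding chromosomes, in natural chromosome order
#' unless `chromOrder` is given.
#'
#' @param results data.frame with columns `snp_id`, `chromosome`,
#'   `position`, `p_value`.
#' @param chromOrder optional character vector fixing chromosome order;
#'   every chromosome present in `results` must appear in it.
#' @param threshold optional nominal per-test threshold; drawn as the
#'   genome-wide significance line.
#' @return list with `data` (data.frame `snp_id`, `chromosome`, `x`,
#'   `neg_log10_p`) and `threshold_line` (`-log10(threshold)` or `NA`).
#' @export
manhattanData <- function(results, chromOrder = NULL, threshold = NULL) {
  chroms <- chromosomeLevels(results$chromosome)
  if (is.null(chromOrder)) chromOrder <- chroms
  unknown <- setdiff(chroms, chromOrder)
  if (length(unknown))
    stop("chromosome(s) not in chromOrder: ", paste(unknown, collapse = ", "))
  maxPos <- vapply(chromOrder, function(ch) {
    v <- results$position[results$chromosome == ch]
    if (length(v)) max(v) else 0
  }, 0)
  offset <- setNames(cumsum(c(0, head(maxPos, -1L))), chromOrder)
  data.frame(snp_id = results$snp_id, chromosome = results$chromosome,
             x = results$position + offset[results$chromosome],
             neg_log10_p = -log10(results$p_value), row.names = NULL) -> df
  list(data = df,
       threshold_line = if (is.null(threshold)) NA_real_ else
         -log10(threshold))
}

#' Render the Q-Q and Manhattan plots
#'
#' Deterministic given the data tables; the Manhattan threshold is drawn as
#' a horizontal line.
#'
#' @param qq data.frame from [qqData()].
#' @param manhattan list from [manhattanData()].
#' @param outDir output directory (created).
#' @return named character vector with the paths of `qq.png` and
#'   `manhattan.png`.
#' @export
renderPlots <- function(qq, manhattan, outDir) {
  if (!nrow(qq) || !nrow(manhattan$data)) stop("plot tables must be non-empty")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(qq = file.path(outDir, "qq.png"),
             manhattan = file.path(outDir, "manhattan.png"))
  pQq <- ggplot2::ggplot(qq, ggplot2::aes(x = expected, y = observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_bw()
  ggplot2::ggsave(paths["qq"], pQq, width = 5, height = 5, dpi = 120)
  md <- manhattan$data
  md$chromosome <- factor(md$chromosome,
                          levels = chromosomeLevels(md$chromosome))
  pMan <- ggplot2::ggplot(md, ggplot2::aes(x = x, y = neg_log10_p,
                                           colour = chromosome)) +
    ggplot2::geom_point(size = 0.5, show.legend = FALSE) +
    ggplot2::scale_colour_manual(
      values = rep(c("grey30", "steelblue"),
                   length.out = nlevels(md$chromosome))) +
    ggplot2::labs(x = "Genome position", y = expression(-log[10](p))) +
    ggplot2::theme_bw()
  if (is.finite(manhattan$threshold_line))
    pMan <- pMan + ggplot2::geom_hline(yintercept = manhattan$threshold_line,
                                       colour = "red")
  ggplot2::ggsave(paths["manhattan"], pMan, width = 8, height = 4, dpi = 120)
  paths
}
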