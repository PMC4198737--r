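# internal helpers

# evaluate `code` under a fixed RNG state, restoring the caller's stream
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# natural chromosome order: numeric labels ascending, then others (X, Y, MT)
orderChromosomes <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  order(is.na(num), num, labels)
}

chromosomeLevels <- function(labels) {
  u <- unique(as.character(labels))
  u[orderChromosomes(u)]
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
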