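#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats dbinom dhyper median quantile rbeta rbinom rpois runif sd setNames cor rnbinom
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; summary tables here follow the
#' conventional half-up rule (4/5 renders as 80.0, 29/32 as 90.6).
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a per-stage RNG seed from a global seed
#'
#' Keeps stages independently reproducible under one pipeline seed. The
#' result always fits a 32-bit signed integer.
#'
#' @param seed global integer seed
#' @param stage stage name (character) or integer offset
#' @return integer seed
#' @export
derive_seed <- function(seed, stage) {
  off <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.integer(stage)
  }
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Centered rolling mean with truncated edge windows
#'
#' Window of width `w` centered on each position (for even `w`, floor((w-1)/2)
#' positions to the left and the remainder to the right), truncated at the
#' track edges so the output has the same length as the input. `NA` bins are
#' ignored within each window; a window with no data yields `NA`.
#'
#' @param x numeric vector (may contain NA)
#' @param w window width in bins
#' @return numeric vector, same length as `x`
#' @export
rolling_mean <- function(x, w = 10) {
  n <- length(x)
  if (n == 0L) return(x)
  lft <- floor((w - 1) / 2)
  rgt <- w - 1 - lft
  vapply(seq_len(n), function(i) {
    win <- x[max(1L, i - lft):min(n, i + rgt)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
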