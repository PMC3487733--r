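#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all percentages printed in
#' reports. Base [round()] rounds half to even, which would turn e.g. a
#' 28.5% increase into 28%; survey tables conventionally print 29%.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. With seed = NULL the
# current stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Percent shares of a count vector, rounded half-up to integers.
#' Percentage share of each count in a vector
#'
#' Used for "order X composes NN% of total diversity" style summaries:
#' each count as a percentage of the vector total, rounded half-up to
#' the nearest integer.
#'
#' @param counts non-negative numeric vector (optionally named).
#' @return numeric vector of integer percentages, same names as `counts`.
#' @export
percent_share <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0), sum(counts) > 0)
  round_half_up(100 * counts / sum(counts))
}
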