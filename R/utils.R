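# Internal helpers shared across modules.

#' @importFrom stats rbinom rexp runif rmultinom median sd quantile density
#'   lowess approx pbinom setNames
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL leaves the global stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Greatest common divisor and least common multiple
#'
#' Integer-valued gcd/lcm on doubles (exact for values below 2^53), used for
#' the lcm lineage weighting of the optimal-transport comparison.
#'
#' @param a,b Positive integers (may be stored as doubles).
#' @return A single number.
#' @examples
#' gcd(4, 6)   # 2
#' lcm(4, 6)   # 12
#' @export
gcd <- function(a, b) {
  stopifnot(a >= 1, b >= 1)
  a <- round(a); b <- round(b)
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

#' @rdname gcd
#' @export
lcm <- function(a, b) {
  (a / gcd(a, b)) * b
}

# Pairwise Hamming distance between equal-length strings, via a byte matrix.
# Returns the full n x m integer matrix; intended for modest n*m.
hamming_matrix <- function(x, y = x) {
  stopifnot(length(unique(nchar(c(x, y)))) == 1L)
  mx <- vapply(x, charToRaw, raw(nchar(x[1L])))
  my <- vapply(y, charToRaw, raw(nchar(y[1L])))
  out <- matrix(0L, length(x), length(y))
  for (j in seq_along(y)) {
    out[, j] <- colSums(mx != my[, j])
  }
  out
}

# Hamming distance of each string in `x` to the single string `ref`.
hamming_to <- function(x, ref) {
  stopifnot(all(nchar(x) == nchar(ref)))
  m <- vapply(x, charToRaw, raw(nchar(ref)))
  as.integer(colSums(m != charToRaw(ref)))
}

stop_user <- function(...) stop(..., call. = FALSE)
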