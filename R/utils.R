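#' @keywords internal
"_PACKAGE"

#' @importFrom stats kmeans prcomp rnorm runif sd var quantile setNames dist median
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a prefix-stable stream of sub-seeds from a master seed
#'
#' Draws `n` integers one at a time from a generator seeded with `seed`, so the
#' first `m` sub-seeds are identical whatever `n >= m` is requested. Every
#' randomized stage of the package draws its seeds from such a stream, which is
#' what makes whole pipelines byte-reproducible from a single seed and gives
#' multi-restart searches their prefix property.
#'
#' @param seed integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 0)
  if (n == 0) return(integer(0))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  vapply(seq_len(n), function(i) sample.int(2147483646L, 1L), integer(1))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# squared Euclidean distances between rows of x and rows of centers
rowdist2 <- function(x, centers) {
  x <- as.matrix(x); centers <- as.matrix(centers)
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same units;
#' 1 means identical partitions (up to label permutation), 0 is the
#' expectation under independent random labelings.
#'
#' @param a,b label vectors of equal length.
#' @return a single number, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  abort_if(length(a) != length(b), "label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
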