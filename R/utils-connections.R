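#' Canonical connection (region-pair) indexing
#'
#' All connection vectors in this package use a single canonical order: the
#' row-major upper triangle of the region x region matrix, i.e. pairs
#' (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R).
#'
#' @param n_regions Number of regions R.
#' @return A data.frame with columns `s` (connection index, 1..S), `i`, `j`
#'   (region indices, i < j), where S = R(R-1)/2.
#' @export
#' @examples
#' connection_index(4)
connection_index <- function(n_regions) {
  R <- as.integer(n_regions)
  if (R < 2) stop("need at least 2 regions")
  i <- rep(seq_len(R - 1L), times = (R - 1L):1L)
  j <- sequence((R - 1L):1L) + i
  data.frame(s = seq_along(i), i = i, j = j)
}

#' Number of connections for a given region count
#' @param n_regions Number of regions.
#' @return R(R-1)/2.
#' @export
n_connections <- function(n_regions) {
  n_regions * (n_regions - 1L) / 2L
}

#' Convert a connection vector to a symmetric matrix
#'
#' @param x Connection vector in canonical order (length R(R-1)/2).
#' @param n_regions Number of regions R.
#' @param diag Value placed on the diagonal (default 0).
#' @return R x R symmetric matrix.
#' @export
vec_to_sym <- function(x, n_regions, diag = 0) {
  ci <- connection_index(n_regions)
  if (length(x) != nrow(ci)) {
    stop("length of x (", length(x), ") does not match R(R-1)/2 = ", nrow(ci))
  }
  M <- matrix(diag, n_regions, n_regions)
  M[cbind(ci$i, ci$j)] <- x
  M[cbind(ci$j, ci$i)] <- x
  M
}

#' Extract the canonical connection vector from a symmetric matrix
#' @param M Symmetric R x R matrix.
#' @return Vector of length R(R-1)/2 in canonical order.
#' @export
sym_to_vec <- function(M) {
  ci <- connection_index(nrow(M))
  M[cbind(ci$i, ci$j)]
}

# population z-score (divisor n, not n-1); errors on constant input
zscore_pop <- function(x, what = "vector") {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("cannot z-score a constant ", what)
  (x - m) / s
}

# sample SD threshold used by all mean + SD selection rules
mean_plus_sd <- function(x) mean(x) + stats::sd(x)

# seed handling: run `expr` under a local RNG state seeded with `seed`
# (NULL leaves the global stream untouched)
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
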