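# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Half-vectorization of a symmetric matrix
#'
#' Stacks the unique elements of a symmetric `k x k` matrix into a vector of
#' length `k(k+1)/2`, taking the lower triangle in column-major order:
#' (1,1), (2,1), ..., (k,1), (2,2), (3,2), ... This ordering is fixed across
#' the package and stamped into serialized covariance-structure files.
#'
#' @param m symmetric numeric matrix.
#' @return numeric vector of length `k(k+1)/2`.
#' @seealso [vech_index()], [unvech()]
#' @export
vech <- function(m) {
  m[lower.tri(m, diag = TRUE)]
}

#' Index table for the half-vectorization order
#'
#' @param k matrix dimension.
#' @return data.frame with columns `row`, `col` giving, for each position of
#'   the half-vectorized vector, the (row, col) entry of the lower triangle
#'   it holds (column-major order).
#' @export
vech_index <- function(k) {
  idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  data.frame(row = idx[, "row"], col = idx[, "col"])
}

#' Rebuild a symmetric matrix from its half-vectorization
#'
#' @param v numeric vector of length `k(k+1)/2`.
#' @return symmetric `k x k` matrix.
#' @export
unvech <- function(v) {
  k <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (abs(k - round(k)) > 1e-8)
    stop("length of `v` is not a triangular number")
  k <- round(k)
  m <- matrix(0, k, k)
  m[lower.tri(m, diag = TRUE)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

# Watson-Crick complement for allele strand flips.
flip_strand <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Two-sided p-value from a z statistic, guarded against underflow to 0.
p_from_z <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
msgf <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))
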