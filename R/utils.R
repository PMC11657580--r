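#' @importFrom stats median rnorm runif sd quantile
#' @importFrom utils head tail modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib shapegrade, .registration = TRUE
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Squared Euclidean cross-distance matrix
#'
#' @param X numeric matrix, rows are points.
#' @param Y numeric matrix with the same number of columns.
#' @return matrix of squared distances, `nrow(X)` by `nrow(Y)`; tiny negative
#'   round-off is clamped to zero.
#' @keywords internal
cross_dist2 <- function(X, Y) {
  D <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  D[D < 0] <- 0
  D
}

# Row-wise nearest neighbour of X among rows of Y; ties broken by smallest
# index. Uses argmax_j (2 x.y_j - |y_j|^2), dropping the |x|^2 term that is
# constant per row; the scan runs in compiled code.
nearest_index <- function(X, Y) {
  cpp_nearest_index(X, Y)
}

# Deterministic sign convention: first entry of each column whose magnitude
# exceeds tol * max|column| is made positive.
fix_signs <- function(M, tol = 1e-8) {
  for (j in seq_len(ncol(M))) {
    col <- M[, j]
    big <- which(abs(col) > tol * max(abs(col), .Machine$double.eps))
    if (length(big) && col[big[1L]] < 0) M[, j] <- -col
  }
  M
}

# Farthest point sampling on rows of V (Euclidean), seeded start vertex.
farthest_point_sample <- function(V, n, seed = 1L) {
  nv <- nrow(V)
  if (n > nv) stopf("requested %d samples from %d points", n, nv)
  set.seed(as.integer(seed))
  idx <- integer(n)
  idx[1L] <- sample.int(nv, 1L)
  d <- colSums((t(V) - V[idx[1L], ])^2)
  if (n > 1L) for (i in 2:n) {
    idx[i] <- which.max(d)
    d <- pmin(d, colSums((t(V) - V[idx[i], ])^2))
  }
  idx
}

# Symmetric eigendecomposition helpers for SPD matrix functions.
sym_part <- function(M) (M + t(M)) / 2

#' Principal matrix logarithm of an SPD matrix
#' @param D symmetric positive-definite matrix.
#' @return symmetric matrix log(D).
#' @keywords internal
logm_spd <- function(D) {
  e <- eigen(sym_part(D), symmetric = TRUE)
  if (any(e$values <= 0))
    stopf("matrix is not positive definite (min eigenvalue %.3e); apply spd_project() first",
          min(e$values))
  sym_part(e$vectors %*% (log(e$values) * t(e$vectors)))
}

# Serialize-and-hash used for cache keys and provenance records.
object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
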