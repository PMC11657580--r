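#' Functional maps between surfaces
#'
#' A functional map F: X_M -> X_N transports real-valued functions instead of
#' points and is encoded, in truncated Laplace-Beltrami eigenbases, by a
#' small matrix C such that a_N ~ C a_M for corresponding functions with
#' coefficients a_M, a_N. Maps are initialized from approximate landmark
#' correspondences, refined by ZoomOut spectral upsampling, and converted to
#' and from pointwise vertex maps T: N -> M.
#'
#' @name functional_maps
NULL

new_functional_map <- function(C, source_id, target_id) {
  structure(list(C = C, source_id = source_id, target_id = target_id,
                 k_M = ncol(C), k_N = nrow(C)),
            class = "functional_map")
}

#' @export
print.functional_map <- function(x, ...) {
  cat(sprintf("functional_map %s -> %s: C is %d x %d\n",
              x$source_id, x$target_id, x$k_N, x$k_M))
  invisible(x)
}

kabsch <- function(P, Q) {
  # rigid transform (R, t) minimizing ||R P + t - Q||, rows are points
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  Rm <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = Rm, t = cq - as.vector(Rm %*% cp))
}

#' Rigid point-set registration
#'
#' Rigidly aligns a moving point set to a fixed one, by coherent point drift
#' (EM over a Gaussian mixture with uniform outlier component) or iterative
#' closest point; `"none"` returns the identity transform.
#'
#' @param fixed,moving numeric matrices of 3D points (rows).
#' @param method `"cpd"`, `"icp"`, or `"none"`.
#' @param max_iter,tol iteration control.
#' @param outlier_weight CPD uniform-component weight in \[0, 1).
#' @return list with rotation `R`, translation `t`, and final mean nearest
#'   neighbour `residual`.
#' @export
rigid_register <- function(fixed, moving, method = c("cpd", "icp", "none"),
                           max_iter = 50, tol = 1e-8, outlier_weight = 0.1) {
  method <- match.arg(method)
  Rm <- diag(3); tv <- c(0, 0, 0)
  if (method == "cpd") {
    X <- fixed; Y <- moving
    Nx <- nrow(X); Ny <- nrow(Y); D <- 3
    Tm <- Y
    sigma2 <- sum(cross_dist2(X, Y)) / (D * Nx * Ny)
    w <- outlier_weight
    vol <- prod(apply(X, 2, function(z) diff(range(z)) + 1e-9))
    for (it in seq_len(max_iter)) {
      num <- exp(-cross_dist2(X, Tm) / (2 * sigma2))
      cst <- w / (1 - w) * Ny / Nx * (2 * pi * sigma2)^(D / 2) / vol
      P <- num / (rowSums(num) + cst)  # Nx x Ny responsibilities
      Np <- sum(P)
      mu_x <- colSums(rowSums(P) * X) / Np
      mu_y <- colSums(colSums(P) * Y) / Np
      Xc <- sweep(X, 2, mu_x); Yc <- sweep(Y, 2, mu_y)
      A <- t(Xc) %*% P %*% Yc
      s <- svd(A)
      d <- sign(det(tcrossprod(s$u, s$v)))
      Rm <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
      tv <- mu_x - as.vector(Rm %*% mu_y)
      Tm <- t(Rm %*% t(Y)) + rep(tv, each = Ny)
      s2_new <- (sum(rowSums(P) * rowSums(Xc^2)) +
                   sum(colSums(P) * rowSums(Yc^2)) -
                   2 * sum(s$d * c(1, 1, d))) / (Np * D)
      s2_new <- max(s2_new, 1e-12)
      if (abs(s2_new - sigma2) < tol * max(sigma2, 1e-12)) { sigma2 <- s2_new; break }
      sigma2 <- s2_new
    }
  } else if (method == "icp") {
    Tm <- moving
    prev <- Inf
    for (it in seq_len(max_iter)) {
      nn <- nearest_index(Tm, fixed)
      tr <- kabsch(moving, fixed[nn, , drop = FALSE])
      Rm <- tr$R; tv <- tr$t
      Tm <- t(Rm %*% t(moving)) + rep(tv, each = nrow(moving))
      res <- mean(rowSums((fixed[nn, , drop = FALSE] - Tm)^2))
      if (abs(prev - res) < tol) break
      prev <- res
    }
  }
  Tm <- t(Rm %*% t(moving)) + rep(tv, each = nrow(moving))
  nn <- nearest_index(Tm, fixed)
  residual <- sqrt(mean(rowSums((fixed[nn, , drop = FALSE] - Tm)^2)))
  if (!is.finite(residual))
    stopf("rigid registration diverged (non-finite residual)")
  list(R = Rm, t = tv, residual = residual)
}

#' Approximate landmark correspondences
#'
#' Rigidly aligns mesh N to mesh M (coherent point drift on a vertex
#' subsample by default), picks `n_landmarks` farthest-point samples on M,
#' and pairs each with the nearest vertex of the aligned N. Deterministic
#' given `seed`.
#'
#' @param mesh_M,mesh_N source and target meshes.
#' @param n_landmarks number of landmark pairs (default 130).
#' @param seed integer seed driving subsampling and farthest-point start.
#' @param method registration method passed to [rigid_register].
#' @param subsample number of vertices used for registration.
#' @return integer matrix with columns `vertex_M`, `vertex_N`.
#' @export
initial_landmarks <- function(mesh_M, mesh_N, n_landmarks = 130, seed = 1L,
                              method = c("cpd", "icp", "none"), subsample = 300) {
  method <- match.arg(method)
  VM <- mesh_M$vertices; VN <- mesh_N$vertices
  if (n_landmarks > min(nrow(VM), nrow(VN)))
    stopf("n_landmarks = %d exceeds vertex count %d", n_landmarks, min(nrow(VM), nrow(VN)))
  if (method == "none") {
    VN_aligned <- VN
  } else {
    set.seed(as.integer(seed))
    sm <- if (nrow(VM) > subsample) VM[sort(sample.int(nrow(VM), subsample)), , drop = FALSE] else VM
    sn <- if (nrow(VN) > subsample) VN[sort(sample.int(nrow(VN), subsample)), , drop = FALSE] else VN
    tr <- rigid_register(sm, sn, method = method)
    VN_aligned <- t(tr$R %*% t(VN)) + rep(tr$t, each = nrow(VN))
  }
  lm_M <- farthest_point_sample(VM, n_landmarks, seed = seed)
  lm_N <- nearest_index(VM[lm_M, , drop = FALSE], VN_aligned)
  cbind(vertex_M = lm_M, vertex_N = lm_N)
}

#' Functional map from landmark correspondences
#'
#' Least-squares fit of the k0 x k0 matrix C mapping the source eigenbasis
#' rows at the M-landmarks to the target eigenbasis rows at the N-landmarks,
#' with a small ridge term for conditioning.
#'
#' @param basis_M,basis_N [eigenbasis] objects of source and target.
#' @param landmarks integer matrix from [initial_landmarks].
#' @param k0 initial spectral dimension (default 30).
#' @param ridge ridge regularization (default 1e-8).
#' @return a `functional_map` with C of size k0 x k0.
#' @export
fmap_from_landmarks <- function(basis_M, basis_N, landmarks, k0 = 30,
                                ridge = 1e-8) {
  if (k0 > basis_M$k || k0 > basis_N$k)
    stopf("k0 = %d exceeds basis size (%d, %d)", k0, basis_M$k, basis_N$k)
  if (nrow(landmarks) < k0)
    stopf("underdetermined: %d landmarks for k0 = %d; supply more landmarks",
          nrow(landmarks), k0)
  PM <- basis_M$vectors[landmarks[, 1], seq_len(k0), drop = FALSE]
  PN <- basis_N$vectors[landmarks[, 2], seq_len(k0), drop = FALSE]
  G <- crossprod(PM) + ridge * diag(k0)
  cond_est <- tryCatch(rcond(G), error = function(e) 0)
  if (cond_est < 1e-14)
    stopf("rank-deficient landmark system (rcond %.2e); supply more landmarks", cond_est)
  C <- t(solve(G, crossprod(PM, PN)))
  new_functional_map(C, basis_M$subject_id %||% "M", basis_N$subject_id %||% "N")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pointwise map from a functional map
#'
#' Nearest-neighbour conversion in the spectral embedding: each target vertex
#' of N is matched to the source vertex of M minimizing
#' ||C phi_M - phi_N||; ties broken by smallest source index.
#'
#' @param fmap a `functional_map` (C of size kN x kM).
#' @param basis_M,basis_N source and target eigenbases.
#' @return integer vector, one source-vertex index per target vertex.
#' @export
pointwise_from_fmap <- function(fmap, basis_M, basis_N) {
  kM <- fmap$k_M; kN <- fmap$k_N
  if (kM > basis_M$k || kN > basis_N$k)
    stopf("map dimensions (%d, %d) exceed basis sizes (%d, %d)",
          kN, kM, basis_N$k, basis_M$k)
  EM <- basis_M$vectors[, seq_len(kM), drop = FALSE] %*% t(fmap$C)
  EN <- basis_N$vectors[, seq_len(kN), drop = FALSE]
  nearest_index(EN, EM)
}

#' Functional map from a pointwise map
#'
#' The mass-orthogonal projection C = Phi_N' A_N Pi Phi_M of the pulled-back
#' basis functions, where Pi is the 0/1 pullback matrix of the vertex map.
#'
#' @param vmap integer vector, source index per target vertex (T: N -> M).
#' @param basis_M,basis_N source and target eigenbases (the target basis
#'   carries the lumped mass used for the projection).
#' @param k output dimension.
#' @return a `functional_map` with C of size k x k.
#' @export
fmap_from_pointwise <- function(vmap, basis_M, basis_N, k) {
  if (k > basis_M$k || k > basis_N$k)
    stopf("k = %d exceeds basis sizes (%d, %d)", k, basis_M$k, basis_N$k)
  pulled <- basis_M$vectors[vmap, seq_len(k), drop = FALSE]
  C <- crossprod(basis_N$vectors[, seq_len(k), drop = FALSE],
                 basis_N$mass_diag * pulled)
  new_functional_map(C, basis_M$subject_id %||% "M", basis_N$subject_id %||% "N")
}

#' ZoomOut spectral upsampling
#'
#' Alternates pointwise conversion and functional projection, growing the
#' spectral dimension by one per step; with the defaults (30 + 12) this grows
#' a 30 x 30 initialization to the full 42-dimensional basis.
#'
#' @param fmap0 initial `functional_map` (square).
#' @param basis_M,basis_N source and target eigenbases.
#' @param steps number of dimension-growing steps.
#' @return refined `functional_map` of size (k0 + steps)^2.
#' @export
zoomout_refine <- function(fmap0, basis_M, basis_N, steps = 12) {
  k <- fmap0$k_M
  if (k + steps > min(basis_M$k, basis_N$k))
    stopf("k0 + steps = %d exceeds basis size %d", k + steps,
          min(basis_M$k, basis_N$k))
  C <- cpp_zoomout(fmap0$C, basis_M$vectors, basis_N$vectors,
                   basis_N$mass_diag, as.integer(steps))
  out <- new_functional_map(C, fmap0$source_id, fmap0$target_id)
  out
}

# Subsampled ZoomOut inner loop: the spectral nearest-neighbour search and
# the mass-weighted projection run on farthest-point vertex subsets, with the
# subset masses rescaled to the total area (quadrature). This is the standard
# acceleration of spectral upsampling; the exact full-vertex path is
# zoomout_refine(). Returns the refined coefficient matrix.
zoomout_refine_sub <- function(C, basis_M, basis_N, steps, sub_M, sub_N) {
  k <- nrow(C)
  PhiM <- basis_M$vectors
  PhiN <- basis_N$vectors
  wN <- basis_N$mass_diag[sub_N]
  wN <- wN * (basis_N$total_area / sum(wN))
  for (s in seq_len(steps)) {
    EM <- PhiM[sub_M, seq_len(k), drop = FALSE] %*% t(C)
    nn <- nearest_index(PhiN[sub_N, seq_len(k), drop = FALSE], EM)
    k <- k + 1L
    C <- crossprod(PhiN[sub_N, seq_len(k), drop = FALSE],
                   wN * PhiM[sub_M[nn], seq_len(k), drop = FALSE])
  }
  C
}

#' Two-cycle consistency of a map pair
#'
#' Frobenius norm || C_NM C_MN - I ||; zero for exactly inverse maps.
#'
#' @param fmap_MN map M -> N; `fmap_NM` map N -> M.
#' @param fmap_NM see above.
#' @return nonnegative scalar.
#' @export
cycle_consistency <- function(fmap_MN, fmap_NM) {
  if (fmap_NM$k_M != fmap_MN$k_N || fmap_NM$k_N != fmap_MN$k_M)
    stopf("incompatible map dimensions: (%d x %d) and (%d x %d)",
          fmap_MN$k_N, fmap_MN$k_M, fmap_NM$k_N, fmap_NM$k_M)
  P <- fmap_NM$C %*% fmap_MN$C
  norm(P - diag(nrow(P)), type = "F")
}

#' Edge-length distortion of a pointwise map
#'
#' Diagnostic: mean relative change of target edge lengths under pullback to
#' the source, a cheap surrogate for deformation strain.
#'
#' @param vmap integer vector (source index per target vertex).
#' @param mesh_M,mesh_N source and target meshes.
#' @return nonnegative scalar (0 for an isometric correspondence).
#' @export
map_distortion <- function(vmap, mesh_M, mesh_N) {
  e <- mesh_edges(mesh_N)[, 1:2, drop = FALSE]
  lN <- sqrt(rowSums((mesh_N$vertices[e[, 1], ] - mesh_N$vertices[e[, 2], ])^2))
  lM <- sqrt(rowSums((mesh_M$vertices[vmap[e[, 1]], ] -
                        mesh_M$vertices[vmap[e[, 2]], ])^2))
  mean(abs(lM - lN) / pmax(lN, 1e-15))
}
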