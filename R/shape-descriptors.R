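#' Shape-difference descriptors
#'
#' Given latent functions shared across the collection (CLB columns), each
#' shape is summarized by the Gram matrices of two inner products evaluated
#' on them: the area-based product (L2 integral against the isophotic
#' density) and the conformal product (Dirichlet energy of zero-mean
#' functions). A correspondence preserves the area-based product iff it is
#' locally area-preserving, the conformal product iff it is conformal, and
#' both iff it is an isometry; with omega > 0 both also sense extrinsic
#' curvature. The SPD Gram matrices are linearized by the matrix logarithm
#' (Log-Euclidean framework) into unit-norm lower-triangle feature vectors.
#'
#' @name shape_descriptors
NULL

# Latent functions as vertex values: Phi[, 1:k] %*% Y  (V x m)
latent_functions <- function(Y, basis) {
  k <- nrow(Y)
  if (k > basis$k) stopf("latent coefficients use %d basis functions but basis has %d", k, basis$k)
  basis$vectors[, seq_len(k), drop = FALSE] %*% Y
}

#' Area-based descriptor
#'
#' D = F' A_omega F for latent functions F, where A_omega is the lumped mass
#' of the isophotic metric; symmetrized. With omega = 0 and mass-orthonormal
#' latent functions this is the identity.
#'
#' @param Y latent coefficient block for the shape (k x m).
#' @param basis the shape's [eigenbasis] (computed at omega = 0).
#' @param ops_omega [metric_operators] of the same mesh at the working omega.
#' @return symmetric m x m matrix.
#' @export
area_descriptor <- function(Y, basis, ops_omega) {
  if (length(ops_omega$mass_diag) != nrow(basis$vectors))
    stopf("operators and basis come from different meshes (%d vs %d vertices)",
          length(ops_omega$mass_diag), nrow(basis$vectors))
  F <- latent_functions(Y, basis)
  sym_part(crossprod(F, ops_omega$mass_diag * F))
}

#' Conformal descriptor
#'
#' D = F' W_omega F after projecting the latent functions to zero mean with
#' respect to the isophotic density (membership in the zero-mean Sobolev
#' space); symmetrized. Constants carry no Dirichlet energy, so the raw Gram
#' is only positive semidefinite; use [spd_project] before taking logs.
#'
#' @inheritParams area_descriptor
#' @return symmetric m x m matrix (PSD).
#' @export
conformal_descriptor <- function(Y, basis, ops_omega) {
  if (length(ops_omega$mass_diag) != nrow(basis$vectors))
    stopf("operators and basis come from different meshes (%d vs %d vertices)",
          length(ops_omega$mass_diag), nrow(basis$vectors))
  F <- latent_functions(Y, basis)
  mu <- colSums(ops_omega$mass_diag * F) / ops_omega$total_area
  F <- sweep(F, 2, mu)
  WF <- as.matrix(ops_omega$stiffness %*% F)
  sym_part(crossprod(F, WF))
}

#' Project a symmetric matrix to the SPD cone
#'
#' Eigenvalues below `epsilon * max(1, lambda_max)` are raised to that floor,
#' making the matrix logarithm well defined with minimal distortion.
#'
#' @param D symmetric matrix.
#' @param epsilon relative eigenvalue floor (default 1e-8).
#' @return SPD matrix of the same size.
#' @export
spd_project <- function(D, epsilon = 1e-8) {
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D))))
    stopf("input is not symmetric (max asymmetry %.3e)", max(abs(D - t(D))))
  e <- eigen(sym_part(D), symmetric = TRUE)
  floor_val <- epsilon * max(1, max(e$values))
  vals <- pmax(e$values, floor_val)
  sym_part(e$vectors %*% (vals * t(e$vectors)))
}

#' Log-Euclidean feature vector
#'
#' Matrix logarithm, lower triangle (including the diagonal) in row-major
#' order, divided by its 2-norm. An exactly zero logarithm (identity
#' descriptor) yields the zero vector, since the unit-norm rule is undefined
#' there and an identity descriptor carries no information.
#'
#' @param D an SPD matrix.
#' @return numeric vector of length m (m + 1) / 2 with unit 2-norm (or all
#'   zeros).
#' @export
le_feature <- function(D) {
  L <- logm_spd(D)
  v <- t(L)[upper.tri(t(L), diag = TRUE)]  # row-major lower triangle
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) return(v)
  v / nrm
}

#' Log-Euclidean distance between SPD matrices
#'
#' || log D1 - log D2 ||_F; a metric on the SPD cone.
#'
#' @param D1,D2 SPD matrices of equal size.
#' @return nonnegative scalar.
#' @export
le_distance <- function(D1, D2) {
  if (!all(dim(D1) == dim(D2)))
    stopf("dimension mismatch: %d x %d vs %d x %d",
          nrow(D1), ncol(D1), nrow(D2), ncol(D2))
  norm(logm_spd(D1) - logm_spd(D2), type = "F")
}

#' Shape descriptor for one shape
#'
#' Convenience constructor bundling the area-based and conformal descriptors,
#' their SPD projections, and Log-Euclidean features.
#'
#' @inheritParams area_descriptor
#' @param epsilon SPD floor passed to [spd_project].
#' @return object of class `shape_descriptor` with `D_area`, `D_conf`,
#'   `feature_area`, `feature_conf`, `omega`.
#' @export
shape_descriptor <- function(Y, basis, ops_omega, epsilon = 1e-8) {
  Da <- spd_project(area_descriptor(Y, basis, ops_omega), epsilon)
  Dc <- spd_project(conformal_descriptor(Y, basis, ops_omega), epsilon)
  structure(list(D_area = Da, D_conf = Dc,
                 feature_area = le_feature(Da), feature_conf = le_feature(Dc),
                 omega = ops_omega$omega),
            class = "shape_descriptor")
}

#' @export
print.shape_descriptor <- function(x, ...) {
  cat(sprintf("shape_descriptor: m=%d, omega=%g, ||logDa||=%.3g, ||logDc||=%.3g\n",
              nrow(x$D_area), x$omega,
              norm(logm_spd(x$D_area), "F"), norm(logm_spd(x$D_conf), "F")))
  invisible(x)
}

#' Pairwise Log-Euclidean distance matrix
#'
#' Distances between shape descriptors, using the unnormalized matrix
#' logarithms (the Log-Euclidean metric proper, as used for the similarity
#' kernel), combining the area-based and conformal parts as the Euclidean
#' norm of the stacked log differences.
#'
#' @param descriptors list of `shape_descriptor` objects.
#' @param which `"area"`, `"conformal"`, or `"both"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
descriptor_distances <- function(descriptors, which = c("both", "area", "conformal")) {
  which <- match.arg(which)
  n <- length(descriptors)
  logs_a <- if (which != "conformal") lapply(descriptors, function(d) logm_spd(d$D_area))
  logs_c <- if (which != "area") lapply(descriptors, function(d) logm_spd(d$D_conf))
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d2 <- 0
    if (!is.null(logs_a)) d2 <- d2 + sum((logs_a[[i]] - logs_a[[j]])^2)
    if (!is.null(logs_c)) d2 <- d2 + sum((logs_c[[i]] - logs_c[[j]])^2)
    D[i, j] <- D[j, i] <- sqrt(d2)
  }
  dimnames(D) <- list(names(descriptors), names(descriptors))
  D
}

#' Feature matrix from descriptors
#'
#' Concatenates per-descriptor unit-norm Log-Euclidean feature vectors
#' (area-based, conformal, or both); the concatenation is not re-normalized,
#' preserving each part's unit norm.
#'
#' @inheritParams descriptor_distances
#' @return numeric matrix, one row per shape.
#' @export
descriptor_features <- function(descriptors, which = c("both", "area", "conformal")) {
  which <- match.arg(which)
  rows <- lapply(descriptors, function(d) switch(which,
    area = d$feature_area,
    conformal = d$feature_conf,
    both = c(d$feature_area, d$feature_conf)))
  X <- do.call(rbind, rows)
  rownames(X) <- names(descriptors)
  X
}
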