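#' Discrete operators of the regularized isophotic metric
#'
#' The metric g = I + omega * III blends the surface's intrinsic metric
#' (first fundamental form I) with the pullback metric of the Gauss map
#' (third fundamental form III), which measures the variation of the surface
#' normals, i.e. extrinsic curvature. It is discretized through the
#' 6-dimensional lift v -> (v, sqrt(omega) * n(v)), whose pullback metric is
#' exactly I + omega * III: edge lengths of the lifted mesh feed the
#' intrinsic cotangent scheme (stiffness) and Heron's formula (lumped mass).
#' At omega = 0 this reduces to the standard weighted cotangent scheme.
#'
#' @name discrete_geometry
NULL

face_corner_cross <- function(mesh) {
  f <- mesh$faces; v <- mesh$vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Area-weighted vertex normals
#'
#' Average of incident face normals weighted by face area, normalized to unit
#' length; covariant with orientation (flipping all faces negates normals).
#'
#' @param mesh an oriented manifold [triangle_mesh].
#' @return numeric matrix, one unit normal per vertex.
#' @export
vertex_normals <- function(mesh) {
  cr <- face_corner_cross(mesh)  # = 2 * area * unit face normal
  N <- matrix(0, nrow(mesh$vertices), 3)
  for (c in 1:3) {
    s <- rowsum(cr, mesh$faces[, c])
    rows <- as.integer(rownames(s))
    N[rows, ] <- N[rows, ] + s
  }
  nrm <- sqrt(rowSums(N^2))
  bad <- which(nrm < 1e-14)
  if (length(bad))
    stopf("zero-area normal umbrella at vertex %s", paste(head(bad, 5), collapse = ", "))
  N / nrm
}

#' Isophotic edge lengths
#'
#' Length of edge (i, j) under the lifted metric:
#' sqrt(|v_i - v_j|^2 + omega * |n_i - n_j|^2). At omega = 0 this is the
#' Euclidean edge length; on a planar mesh it is omega-independent.
#'
#' @param mesh a [triangle_mesh].
#' @param normals per-vertex unit normals (default [vertex_normals]).
#' @param omega nonnegative metric blending weight (squared-length units).
#' @return list with `edges` (E x 2 matrix, i < j) and `lengths`.
#' @export
isophotic_edge_lengths <- function(mesh, normals = vertex_normals(mesh), omega = 0) {
  if (omega < 0) stopf("omega must be nonnegative, got %g", omega)
  e <- mesh_edges(mesh)[, 1:2, drop = FALSE]
  dv <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  dn <- normals[e[, 1], , drop = FALSE] - normals[e[, 2], , drop = FALSE]
  list(edges = e, lengths = sqrt(rowSums(dv^2) + omega * rowSums(dn^2)))
}

# Per-face squared isophotic lengths of the edges opposite corners 1..3.
face_isophotic_len2 <- function(mesh, normals, omega) {
  f <- mesh$faces; v <- mesh$vertices
  len2 <- function(i, j) {
    d <- rowSums((v[i, , drop = FALSE] - v[j, , drop = FALSE])^2)
    if (omega > 0)
      d <- d + omega * rowSums((normals[i, , drop = FALSE] - normals[j, , drop = FALSE])^2)
    d
  }
  cbind(a2 = len2(f[, 2], f[, 3]),  # opposite corner 1
        b2 = len2(f[, 3], f[, 1]),  # opposite corner 2
        c2 = len2(f[, 1], f[, 2]))  # opposite corner 3
}

#' Mass and stiffness operators of (S, g_omega)
#'
#' Intrinsic cotangent stiffness (discrete Dirichlet form) and barycentric
#' lumped mass built from the isophotic edge lengths; see
#' [discrete_geometry]. Faces whose lifted edge lengths violate the triangle
#' inequality (possible for very large omega on coarse meshes) have their
#' cotangent weights clamped to zero with a warning.
#'
#' @param mesh a [triangle_mesh].
#' @param omega nonnegative metric blending weight.
#' @param normals optional precomputed unit vertex normals.
#' @return object of class `metric_operators`: `omega`, `mass` (sparse
#'   diagonal, positive), `stiffness` (sparse symmetric PSD, zero row sums),
#'   `mass_diag`, `total_area`.
#' @export
metric_operators <- function(mesh, omega = 0, normals = NULL) {
  if (omega < 0) stopf("omega must be nonnegative, got %g", omega)
  V <- nrow(mesh$vertices)
  if (is.null(normals)) normals <- if (omega > 0) vertex_normals(mesh) else NULL
  L2 <- face_isophotic_len2(mesh, normals, omega)
  a2 <- L2[, 1]; b2 <- L2[, 2]; c2 <- L2[, 3]
  # Heron in squared-length form: 16 T^2 = 2(a2 b2 + b2 c2 + c2 a2) - a2^2 - b2^2 - c2^2
  T2 <- (2 * (a2 * b2 + b2 * c2 + c2 * a2) - a2^2 - b2^2 - c2^2) / 16
  scale2 <- pmax(a2, b2, c2)
  degen <- which(T2 <= 1e-24 * scale2^2 & T2 > -1e-12 * scale2^2)
  if (length(degen))
    stopf("degenerate (zero-area) face %s", paste(head(degen, 5), collapse = ", "))
  viol <- which(T2 <= 0)
  if (length(viol)) {
    warnf("%d face(s) violate the lifted triangle inequality at omega=%g; cotangent weights clamped to 0 (e.g. face %d)",
          length(viol), omega, viol[1])
    T2[viol] <- NA
  }
  area <- sqrt(pmax(T2, 0))
  cot1 <- (b2 + c2 - a2) / (4 * area)  # angle at corner 1, opposite edge a
  cot2 <- (c2 + a2 - b2) / (4 * area)
  cot3 <- (a2 + b2 - c2) / (4 * area)
  if (length(viol)) {
    cot1[viol] <- 0; cot2[viol] <- 0; cot3[viol] <- 0
    area[viol] <- 0
  }
  f <- mesh$faces
  w <- c(cot1, cot2, cot3) / 2
  ii <- c(f[, 2], f[, 3], f[, 1])
  jj <- c(f[, 3], f[, 1], f[, 2])
  Wmat <- Matrix::sparseMatrix(
    i = c(ii, jj, ii, jj),
    j = c(jj, ii, ii, jj),
    x = c(-w, -w, w, w),
    dims = c(V, V))
  Wmat <- Matrix::forceSymmetric((Wmat + Matrix::t(Wmat)) / 2)
  md <- rep(0, V)
  for (c in 1:3) {
    s <- rowsum(area / 3, f[, c])
    md[as.integer(rownames(s))] <- md[as.integer(rownames(s))] + s
  }
  if (any(md <= 0)) stopf("mass matrix not positive definite (isolated vertex?)")
  structure(list(omega = omega,
                 mass = Matrix::Diagonal(x = md),
                 stiffness = Wmat,
                 mass_diag = md,
                 total_area = sum(area)),
            class = "metric_operators")
}

#' @export
print.metric_operators <- function(x, ...) {
  cat(sprintf("metric_operators: %d vertices, omega=%g, total area %.6g\n",
              length(x$mass_diag), x$omega, x$total_area))
  invisible(x)
}

#' Truncated Laplace-Beltrami eigenbasis
#'
#' Smallest-k generalized eigenpairs W phi = lambda A phi of the stiffness
#' and (diagonal) mass operators, A-orthonormal, eigenvalues ascending,
#' eigenvector signs fixed so the first non-negligible entry is positive.
#' Because the lumped mass is diagonal, the problem is solved as a dense
#' symmetric eigenproblem of D^{-1/2} W D^{-1/2}.
#'
#' @param ops a [metric_operators].
#' @param k number of eigenpairs, `k < V`.
#' @return object of class `spectral_basis`: `values` (length k),
#'   `vectors` (V x k), `k`, `omega`, `mass_diag`, `total_area`.
#' @export
eigenbasis <- function(ops, k) {
  V <- length(ops$mass_diag)
  if (k >= V) stopf("k = %d must be smaller than the vertex count %d", k, V)
  dinv <- 1 / sqrt(ops$mass_diag)
  B <- as.matrix(ops$stiffness) * tcrossprod(dinv)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ord <- seq(V, V - k + 1L)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE] * dinv
  if (any(vals < -1e-6 * max(abs(vals))))
    stopf("eigen solver returned significantly negative eigenvalues (min %.3e)", min(vals))
  vals[vals < 0] <- 0
  vecs <- fix_signs(vecs)
  structure(list(values = vals, vectors = vecs, k = as.integer(k),
                 omega = ops$omega, mass_diag = ops$mass_diag,
                 total_area = ops$total_area),
            class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("spectral_basis: k=%d on %d vertices (omega=%g), lambda in [%.3g, %.3g]\n",
              x$k, nrow(x$vectors), x$omega, min(x$values), max(x$values)))
  invisible(x)
}

#' Metric blending weight from a scale-free factor
#'
#' omega = alpha * ell^2 with ell the bounding box diagonal; because III is
#' scale-invariant while I scales quadratically, this makes the blend alpha
#' unit-free.
#'
#' @param mesh a [triangle_mesh].
#' @param alpha nonnegative scale-free blending factor.
#' @return omega (squared-length units).
#' @export
omega_from_alpha <- function(mesh, alpha) {
  if (alpha < 0) stopf("alpha must be nonnegative, got %g", alpha)
  alpha * bounding_box_diagonal(mesh)^2
}
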