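# Fixtures are generated in code; nothing is read from disk.

# Ellipsoidal blob with smooth band-limited radial noise: anisotropic enough
# for rigid registration to be well posed, asymmetric enough to avoid the
# sphere's repeated Laplace-Beltrami eigenvalues.
blob_mesh <- function(seed = 1, amp = 0.08, subdivisions = 2,
                      axes = c(1.0, 0.7, 0.55), id = paste0("blob", seed)) {
  m <- mesh_icosphere(subdivisions, subject_id = id)
  sh <- shapegrade:::real_sph_harm(m$vertices, 4)
  set.seed(seed)
  r <- 1 + amp * as.vector(sh %*% rnorm(ncol(sh))) / 3
  m$vertices <- sweep(m$vertices * r, 2, axes, "*")
  m
}

# Copy of a mesh with vertices stored in a random order (same surface).
permuted_copy <- function(mesh, seed = 1) {
  set.seed(seed)
  perm <- sample(nrow(mesh$vertices))  # perm[new] = old
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  out <- mesh
  out$vertices <- mesh$vertices[perm, ]
  out$faces <- matrix(inv[mesh$faces], ncol = 3)
  out$subject_id <- paste0(mesh$subject_id, "_perm")
  list(mesh = out, perm = perm, inv = inv)
}

rotate_mesh <- function(mesh, degrees = 20, axis = 3, shift = c(0.1, -0.2, 0.05)) {
  th <- degrees * pi / 180
  R <- diag(3)
  ij <- setdiff(1:3, axis)
  R[ij, ij] <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  out <- mesh
  out$vertices <- t(R %*% t(mesh$vertices)) + rep(shift, each = nrow(mesh$vertices))
  out
}

# Independent reference implementation of the omega = 0 cotangent scheme,
# computed from 3D coordinates via cross/dot products (not from edge
# lengths): the oracle for the intrinsic-length-based path.
reference_cotan <- function(mesh) {
  V <- nrow(mesh$vertices)
  f <- mesh$faces
  W <- matrix(0, V, V)
  mass <- rep(0, V)
  for (t in seq_len(nrow(f))) {
    idx <- f[t, ]
    p <- mesh$vertices[idx, ]
    area <- 0.5 * sqrt(sum(crossp(p[2, ] - p[1, ], p[3, ] - p[1, ])^2))
    for (c in 1:3) {
      i <- idx[c]; j <- idx[c %% 3 + 1]; k <- idx[(c + 1) %% 3 + 1]
      # angle at vertex i, opposite edge (j, k)
      u <- mesh$vertices[j, ] - mesh$vertices[i, ]
      v <- mesh$vertices[k, ] - mesh$vertices[i, ]
      cot <- sum(u * v) / sqrt(sum(crossp(u, v)^2))
      W[j, k] <- W[j, k] - cot / 2
      W[k, j] <- W[k, j] - cot / 2
      W[j, j] <- W[j, j] + cot / 2
      W[k, k] <- W[k, k] + cot / 2
      mass[i] <- mass[i] + area / 3
    }
  }
  list(stiffness = W, mass = mass)
}

crossp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Shared small shape collection with 42-dim bases (costly; built once).
shared_shapes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      meshes <- lapply(1:4, function(s) blob_mesh(seed = s))
      names(meshes) <- paste0("s", 1:4)
      cache <<- build_shapes(meshes, k_eigen = 42)
    }
    cache
  }
})

random_spd <- function(m, seed) {
  set.seed(seed)
  A <- matrix(rnorm(m * m), m)
  crossprod(A) + diag(m) * 0.1
}
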