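test_that("vertex normals match analytic expectations and flip with orientation", {
  ico <- mesh_icosphere(2)
  N <- vertex_normals(ico)
  # on a sphere the outward normal is the (normalized) position
  pos <- ico$vertices / sqrt(rowSums(ico$vertices^2))
  expect_lt(max(abs(N - pos)), 3e-2)  # discretization error of the coarse umbrellas

  grid <- mesh_planar_grid(6, 6)
  Ng <- vertex_normals(grid)
  expect_equal(Ng, matrix(rep(c(0, 0, 1), each = nrow(Ng)), ncol = 3))

  flipped <- ico
  flipped$faces <- ico$faces[, c(1, 3, 2)]
  expect_equal(vertex_normals(flipped), -N)
})

test_that("isophotic edge lengths: omega = 0 Euclidean, plane invariant, sphere sqrt(2)", {
  ico <- mesh_icosphere(2)
  ico$vertices <- ico$vertices / sqrt(rowSums(ico$vertices^2))  # exact unit sphere
  N <- ico$vertices  # exact normals on the unit sphere
  l0 <- isophotic_edge_lengths(ico, N, omega = 0)
  dv <- ico$vertices[l0$edges[, 1], ] - ico$vertices[l0$edges[, 2], ]
  expect_equal(l0$lengths, sqrt(rowSums(dv^2)))
  # on the unit sphere I = III, so omega = 1 scales all lengths by sqrt(2)
  l1 <- isophotic_edge_lengths(ico, N, omega = 1)
  expect_equal(l1$lengths, sqrt(2) * l0$lengths, tolerance = 1e-12)

  grid <- mesh_planar_grid(5, 5)
  lg0 <- isophotic_edge_lengths(grid, omega = 0)
  lg9 <- isophotic_edge_lengths(grid, omega = 9)
  expect_equal(lg9$lengths, lg0$lengths)
  expect_error(isophotic_edge_lengths(ico, N, omega = -1), "nonnegative")
})

test_that("omega = 0 operators match an independent coordinate-based cotangent scheme", {
  fixtures <- list(mesh_tetrahedron(), mesh_icosphere(1), mesh_torus(n_major = 10, n_minor = 6),
                   mesh_planar_grid(5, 4), blob_mesh(seed = 3, subdivisions = 1))
  for (m in fixtures) {
    ops <- suppressWarnings(metric_operators(m, omega = 0))
    ref <- reference_cotan(m)
    expect_lt(max(abs(as.matrix(ops$stiffness) - ref$stiffness)), 1e-10)
    expect_lt(max(abs(ops$mass_diag - ref$mass)), 1e-10)
    expect_lt(max(abs(Matrix::rowSums(ops$stiffness))), 1e-10)
  }
})

test_that("unit-square stiffness weights match the hand-derived cotangent values", {
  # unit square split along the diagonal 1-3: boundary edges see one 45-degree
  # angle (weight cot(45)/2 = 1/2); the diagonal sees two 90-degree angles
  # (weight 0)
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 4))
  m <- suppressWarnings(triangle_mesh(v, f))
  W <- as.matrix(suppressWarnings(metric_operators(m, 0))$stiffness)
  expect_equal(W[1, 2], -0.5)
  expect_equal(W[2, 3], -0.5)
  expect_equal(W[1, 3], 0)
  expect_equal(rowSums(W), rep(0, 4))
  expect_equal(sum(suppressWarnings(metric_operators(m, 0))$mass_diag), 1)
})

test_that("icosphere mass and spectrum converge to the analytic sphere", {
  ops <- metric_operators(mesh_icosphere(2), 0)
  expect_equal(ops$total_area, 4 * pi, tolerance = 0.02)
  b <- eigenbasis(ops, 5)
  expect_lt(b$values[1], 1e-10)
  expect_equal(b$values[2:4], rep(2, 3), tolerance = 0.02)
  # A-orthonormality and the normalized constant mode
  G <- crossprod(b$vectors, ops$mass_diag * b$vectors)
  expect_lt(max(abs(G - diag(5))), 1e-8)
  expect_equal(b$vectors[, 1], rep(1 / sqrt(ops$total_area), length(ops$mass_diag)),
               tolerance = 1e-8)
  b1 <- eigenbasis(ops, 1)
  expect_equal(b1$vectors[, 1], rep(1 / sqrt(ops$total_area), length(ops$mass_diag)),
               tolerance = 1e-8)
})

test_that("planar operators are omega-independent; edge lengths and area are monotone in omega", {
  grid <- mesh_planar_grid(6, 5)
  o0 <- suppressWarnings(metric_operators(grid, 0))
  o10 <- suppressWarnings(metric_operators(grid, 10))
  expect_equal(as.matrix(o10$stiffness), as.matrix(o0$stiffness))
  expect_equal(o10$mass_diag, o0$mass_diag)

  m <- blob_mesh(seed = 5, subdivisions = 1)
  omegas <- c(0, 0.01, 0.1, 1)
  lens <- sapply(omegas, function(w) isophotic_edge_lengths(m, omega = w)$lengths)
  areas <- sapply(omegas, function(w) metric_operators(m, w)$total_area)
  for (i in seq_len(length(omegas) - 1)) {
    expect_true(all(lens[, i + 1] >= lens[, i]))
    expect_gt(areas[i + 1], areas[i])
  }
})

test_that("spectrum scales as 1/s^2 under vertex scaling and is rigid-motion invariant", {
  m <- blob_mesh(seed = 7, subdivisions = 1)
  v0 <- eigenbasis(metric_operators(m, 0), 8)$values
  ms <- m; ms$vertices <- 2.5 * m$vertices
  vs <- eigenbasis(metric_operators(ms, 0), 8)$values
  expect_equal(vs[-1], v0[-1] / 2.5^2, tolerance = 1e-8)
  for (w in c(0, 0.05)) {
    mr <- rotate_mesh(m, degrees = 33, axis = 2)
    vr <- eigenbasis(metric_operators(mr, w), 8)$values
    vo <- eigenbasis(metric_operators(m, w), 8)$values
    expect_equal(vr, vo, tolerance = 1e-8)
  }
})

test_that("degenerate faces are rejected and omega scaling from alpha is exact", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4))  # first face has zero area
  m <- suppressWarnings(triangle_mesh(v, f))
  expect_error(suppressWarnings(metric_operators(m, 0)), "degenerate")

  ico <- mesh_icosphere(1)
  expect_equal(omega_from_alpha(ico, 0), 0)
  expect_equal(omega_from_alpha(ico, 2^-6), 2^-6 * 12, tolerance = 1e-12)
  cube <- suppressWarnings(triangle_mesh(as.matrix(expand.grid(0:1, 0:1, 0:1)),
                                         rbind(c(1, 2, 3))))
  expect_equal(omega_from_alpha(cube, 1), 3)
  expect_error(omega_from_alpha(ico, -0.1), "nonnegative")
})
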