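test_that("landmark pairing is the identity for identical and rigidly moved copies", {
  m <- blob_mesh(seed = 2)
  lm <- initial_landmarks(m, m, n_landmarks = 50, seed = 4)
  expect_identical(lm[, 1], lm[, 2])
  lm_full <- initial_landmarks(m, m, n_landmarks = nrow(m$vertices), seed = 4,
                               method = "none")
  expect_identical(sort(lm_full[, 1]), seq_len(nrow(m$vertices)))
  expect_identical(lm_full[, 1], lm_full[, 2])

  mr <- rotate_mesh(m, degrees = 20)
  lm_r <- initial_landmarks(m, mr, n_landmarks = 50, seed = 4, method = "cpd")
  expect_identical(lm_r[, 1], lm_r[, 2])
  expect_error(initial_landmarks(m, m, n_landmarks = 10 * nrow(m$vertices)),
               "exceeds")
})

test_that("landmark functional map is identity on a shape against itself", {
  shapes <- shared_shapes()
  b <- shapes[[1]]$basis
  lm <- cbind(1:130, 1:130)
  f <- fmap_from_landmarks(b, b, lm, k0 = 30)
  expect_equal(dim(f$C), c(30L, 30L))
  expect_lt(max(abs(f$C - diag(30))), 1e-6)
  expect_error(fmap_from_landmarks(b, b, lm[1:20, ], k0 = 30), "landmarks")
})

test_that("pointwise conversion recovers identity and known permutations", {
  shapes <- shared_shapes()
  m <- shapes[[1]]$mesh; b <- shapes[[1]]$basis
  fI <- fmap_from_landmarks(b, b, cbind(1:130, 1:130), k0 = 30)
  expect_identical(pointwise_from_fmap(fI, b, b), seq_len(nrow(m$vertices)))

  pc <- permuted_copy(m, seed = 9)
  b2 <- eigenbasis(metric_operators(pc$mesh, 0), 42)
  lm <- cbind(vertex_M = 1:130, vertex_N = pc$inv[1:130])  # exact landmarks
  f <- fmap_from_landmarks(b, b2, lm, k0 = 30)
  f <- zoomout_refine(f, b, b2, steps = 12)
  vmap <- pointwise_from_fmap(f, b, b2)
  expect_gte(mean(vmap == pc$perm), 0.99)

  # k = 1: a constant-only embedding is degenerate; every target vertex ties
  # and the smallest source index wins
  const_basis <- function(V) structure(list(vectors = matrix(1, V, 1),
                                            values = 0, k = 1L,
                                            mass_diag = rep(1 / V, V),
                                            total_area = 1),
                                       class = "spectral_basis")
  f1 <- shapegrade:::new_functional_map(matrix(1, 1, 1), "a", "b")
  vm1 <- pointwise_from_fmap(f1, const_basis(50), const_basis(30))
  expect_identical(vm1, rep(1L, 30))
})

test_that("functional projection of the identity vertex map is the identity matrix", {
  shapes <- shared_shapes()
  b <- shapes[[1]]$basis
  V <- nrow(b$vectors)
  f <- fmap_from_pointwise(seq_len(V), b, b, k = 20)
  expect_lt(max(abs(f$C - diag(20))), 1e-8)
  # constants transport to constants (+/- first coordinate vector)
  e1 <- c(1, rep(0, 19))
  expect_equal(abs(as.vector(f$C %*% e1)), e1, tolerance = 1e-8)
})

test_that("full landmark-to-pointwise pipeline recovers a vertex permutation", {
  m <- blob_mesh(seed = 12)
  pc <- permuted_copy(m, seed = 13)
  shapes <- build_shapes(list(a = m, b = pc$mesh), k_eigen = 42)
  lm <- initial_landmarks(m, pc$mesh, n_landmarks = 130, seed = 5, method = "cpd")
  f0 <- fmap_from_landmarks(shapes$a$basis, shapes$b$basis, lm, k0 = 30)
  f <- zoomout_refine(f0, shapes$a$basis, shapes$b$basis, steps = 12)
  vmap <- pointwise_from_fmap(f, shapes$a$basis, shapes$b$basis)
  expect_gte(mean(vmap == pc$perm), 0.99)
  expect_lt(map_distortion(vmap, m, pc$mesh), 1e-8)
})

test_that("ZoomOut grows identity to identity and does not worsen near-isometric pairs", {
  shapes <- shared_shapes()
  b <- shapes[[1]]$basis
  fI <- shapegrade:::new_functional_map(diag(30), "a", "a")
  fz <- zoomout_refine(fI, b, b, steps = 12)
  expect_equal(dim(fz$C), c(42L, 42L))
  expect_lt(max(abs(fz$C - diag(42))), 1e-8)
  expect_error(zoomout_refine(fI, b, b, steps = 1000), "exceeds")

  # 2 percent bump of the same mesh: spectral matching error must not grow
  m <- shapes[[1]]$mesh
  m2 <- m
  m2$vertices <- m$vertices * (1 + 0.02 * sin(3 * m$vertices[, 1]))
  b2 <- eigenbasis(metric_operators(m2, 0), 42)
  lm <- initial_landmarks(m, m2, 130, seed = 2, method = "icp")
  f0 <- fmap_from_landmarks(b, b2, lm, k0 = 30)
  # ground-truth correspondence is the identity (shared vertex order); score a
  # map by the mean 3D displacement of its pointwise conversion
  err <- function(f) {
    vm <- pointwise_from_fmap(f, b, b2)
    mean(sqrt(rowSums((m$vertices[vm, ] - m$vertices)^2)))
  }
  f1 <- zoomout_refine(f0, b, b2, steps = 12)
  expect_lte(err(f1), err(f0))
})

test_that("cycle consistency matches hand computations in both orders", {
  I2 <- shapegrade:::new_functional_map(diag(2), "a", "b")
  expect_equal(cycle_consistency(I2, I2), 0)
  th <- 0.7
  Q <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  fQ <- shapegrade:::new_functional_map(Q, "a", "b")
  fQt <- shapegrade:::new_functional_map(t(Q), "b", "a")
  expect_lt(cycle_consistency(fQ, fQt), 1e-12)
  expect_lt(cycle_consistency(fQt, fQ), 1e-12)
  f2 <- shapegrade:::new_functional_map(2 * diag(2), "a", "b")
  expect_equal(cycle_consistency(f2, I2), sqrt(2))  # ||2I - I||_F
  expect_equal(cycle_consistency(I2, f2), sqrt(2))
  f3 <- shapegrade:::new_functional_map(diag(3), "a", "b")
  expect_error(cycle_consistency(f3, I2), "incompatible")
})

test_that("maps compose functorially across copies of one shape", {
  shapes <- shared_shapes()
  b <- shapes[[1]]$basis
  V <- nrow(b$vectors)
  mk <- function() fmap_from_pointwise(seq_len(V), b, b, k = 30)
  C_AB <- mk()$C; C_BC <- mk()$C; C_AC <- mk()$C
  expect_lt(norm(C_AC - C_BC %*% C_AB, "F"), 1e-6)
})
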