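# Small network of identical shapes: every map should be (numerically) the
# identity, every consistency score ~ 0, and the CLB exactly consistent.
identical_network <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- blob_mesh(seed = 21)
      meshes <- list(a = m, b = m, c = m)
      shapes <- build_shapes(meshes, k_eigen = 42)
      cache <<- prune_network(all_pairs_fmaps(shapes, seed = 3))
    }
    cache
  }
})

test_that("all-pairs maps on identical shapes are consistent and complete", {
  net <- identical_network()
  expect_equal(length(net$maps), 3 * 2)  # n(n-1) ordered maps
  off <- net$consistency[upper.tri(net$consistency)]
  expect_lt(max(off), 1e-6)
  expect_equal(net$consistency, t(net$consistency))
  expect_equal(net$k_used, 1L)
})

test_that("consistency k-NN graph finds the smallest connecting k", {
  # chain: 1-2 and 2-3 close, 1-3 far
  chain <- rbind(c(0, 1, 10), c(1, 0, 1), c(10, 1, 0))
  g <- consistency_knn_graph(chain)
  expect_equal(g$k_used, 1L)
  und <- unique(t(apply(g$edges, 1, sort)))
  expect_equal(und[order(und[, 1], und[, 2]), ], rbind(c(1, 2), c(2, 3)))

  # equal scores: union of 1-NN already connects
  eq <- matrix(1, 3, 3); diag(eq) <- 0
  expect_equal(consistency_knn_graph(eq)$k_used, 1L)

  two <- rbind(c(0, 2), c(2, 0))
  g2 <- consistency_knn_graph(two)
  expect_equal(g2$k_used, 1L)
  expect_equal(nrow(g2$edges), 2L)

  expect_error(consistency_knn_graph(matrix(Inf, 2, 2)), "no usable")
})

test_that("k_used is minimal: k_used - 1 leaves the graph disconnected", {
  knn_adj <- function(sc, k) {
    n <- nrow(sc)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      s <- sc[i, ]; s[i] <- Inf
      adj[i, order(s)[seq_len(k)]] <- TRUE
    }
    adj | t(adj)
  }
  connected <- function(adj) {
    n <- nrow(adj); seen <- logical(n); seen[1] <- TRUE; repeat {
      nb <- which(colSums(adj[seen, , drop = FALSE]) > 0 & !seen)
      if (!length(nb)) break
      seen[nb] <- TRUE
    }
    all(seen)
  }
  for (trial in 1:20) {
    set.seed(trial)
    n <- sample(3:12, 1)
    # clustered scores so that small k is often disconnected
    centers <- sample(1:3, n, replace = TRUE)
    D <- abs(outer(centers, centers, "-")) * 5 + matrix(runif(n * n), n)
    D <- (D + t(D)) / 2; diag(D) <- 0
    g <- consistency_knn_graph(D)
    expect_true(connected(knn_adj(D, g$k_used)))
    if (g$k_used > 1) expect_false(connected(knn_adj(D, g$k_used - 1)))
  }
})

test_that("canonical latent basis is exact on identical shapes", {
  net <- identical_network()
  clb <- canonical_latent_basis(net, m = 6, k = 42)
  expect_lt(clb$residual, 1e-8)
  expect_equal(clb$Y[[1]], clb$Y[[2]], tolerance = 1e-6)
  expect_equal(clb$Y[[1]], clb$Y[[3]], tolerance = 1e-6)
  # stacked orthonormality sum_S Y_S' Y_S = n I
  G <- Reduce(`+`, lapply(clb$Y, crossprod))
  expect_lt(max(abs(G - 3 * diag(6))), 1e-8)
  # residual definition: recompute by brute force over edges
  brute <- 0
  for (r in seq_len(nrow(net$edges))) {
    i <- net$edges[r, 1]; j <- net$edges[r, 2]
    C <- net$maps[[paste0(net$ids[i], "->", net$ids[j])]]$C
    brute <- brute + norm(C %*% clb$Y[[i]] - clb$Y[[j]], "F")^2
  }
  expect_equal(clb$residual, brute, tolerance = 1e-12)
})

test_that("constants give a near-zero residual latent function at m = 1", {
  # distinct shapes: constants are the only exactly consistent direction
  shapes <- shared_shapes()
  net <- prune_network(all_pairs_fmaps(shapes, seed = 3))
  clb <- canonical_latent_basis(net, m = 1, k = 42)
  expect_lt(clb$residual, 1e-8)
  for (y in clb$Y)
    expect_gt(abs(y[1, 1]), 0.99 * sqrt(sum(y^2)))
})

test_that("relabeling the shapes leaves the residual invariant", {
  net <- identical_network()
  perm <- c(3, 1, 2)
  net2 <- net
  net2$ids <- net$ids[perm]
  net2$shapes <- net$shapes[perm]
  net2$consistency <- net$consistency[perm, perm]
  net2 <- prune_network(net2)
  c1 <- canonical_latent_basis(net, m = 5, k = 30)
  c2 <- canonical_latent_basis(net2, m = 5, k = 30)
  expect_equal(c1$residual, c2$residual, tolerance = 1e-8)
})

test_that("Consistent ZoomOut follows the growth schedule and reduces residual", {
  net <- identical_network()
  clb <- consistent_zoomout(net)  # defaults: 8 + 20 steps, +1 and +7/10
  final <- clb$schedule_log[nrow(clb$schedule_log), ]
  expect_equal(final$X_S, 28L)
  expect_equal(final$B_S, 22L)
  expect_equal(clb$k, 28L)
  expect_equal(clb$m, 22L)
  expect_lt(clb$residual, 1e-8)
  expect_lte(clb$residual_normalized, clb$init_residual_normalized + 1e-12)
  expect_error(consistent_zoomout(net, init_dim = 8, steps = 60), "dimension")
})

test_that("latent functions transport vertexwise across a permuted-copy edge", {
  m <- blob_mesh(seed = 31)
  pc <- permuted_copy(m, seed = 32)
  shapes <- build_shapes(list(a = m, b = pc$mesh), k_eigen = 42)
  net <- prune_network(all_pairs_fmaps(shapes, seed = 2))
  clb <- consistent_zoomout(net, init_dim = 8, steps = 10)
  # vertex values of the latent functions on each shape
  Fa <- shapes$a$basis$vectors[, seq_len(clb$k)] %*% clb$Y[["a"]]
  Fb <- shapes$b$basis$vectors[, seq_len(clb$k)] %*% clb$Y[["b"]]
  # pull b's values back to a through the known permutation
  expect_lt(max(abs(Fb[pc$inv, ] - Fa)), 1e-6)
})
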