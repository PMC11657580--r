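toy_distances <- function(n, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 3), n)
  as.matrix(dist(X))
}

test_that("similarity kernel uses the median-sigma RBF", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 1; D[1, 3] <- D[3, 1] <- 3; D[2, 3] <- D[3, 2] <- 2
  s <- similarity_matrix(D)
  expect_equal(s$sigma, 2)
  expect_equal(s$Sim[2, 3], exp(-0.5))
  expect_equal(diag(s$Sim), rep(1, 3))
  expect_equal(s$Sim[1, 2], exp(-0.5 * 1 / 4))
  expect_error(similarity_matrix(matrix(0, 3, 3)), "sigma")
})

test_that("phenotype gate is a conjunction with a one-way 30-NN rule", {
  # sexes differ -> 0 regardless of distance
  D <- toy_distances(6)
  ph <- data.frame(sex = c("F", "M", "F", "F", "M", "F"),
                   apoe = rep("E3", 6))
  g <- phenotype_gate(ph, D, knn = 5)
  expect_true(all(g[ph$sex == "F", ph$sex == "M"] == 0))
  expect_equal(g, t(g))
  expect_equal(diag(g), rep(0, 6))

  # asymmetric neighbour ranks: i in kNN(j) suffices (OR rule)
  n <- 40
  D <- matrix(100, n, n); diag(D) <- 0
  # subject 1 has 2..31 close (30-NN = 2..31); subject 40 is 1's 39th neighbour,
  # but 1 is 40's nearest: construct explicitly
  D[1, 2:31] <- D[2:31, 1] <- seq(1, 30) / 10
  D[1, 40] <- D[40, 1] <- 50
  D[40, 2:39] <- D[2:39, 40] <- 60:97
  ph <- data.frame(sex = rep("F", n), apoe = rep("E4", n))
  g <- phenotype_gate(ph, D, knn = 30)
  expect_equal(g[1, 40], 1)  # 1 is among 40's 30 closest although not vice versa
  ph_bad <- ph; ph_bad$apoe[3] <- NA
  expect_error(phenotype_gate(ph_bad, D), "subject 3")
})

test_that("adjacency is the gated similarity with controlled sparsity", {
  D <- toy_distances(8)
  s <- similarity_matrix(D)
  gate0 <- matrix(0, 8, 8)
  expect_equal(population_adjacency(s$Sim, gate0), gate0, ignore_attr = TRUE)
  gate1 <- matrix(1, 8, 8)
  W <- suppressMessages(population_adjacency(s$Sim, gate1))
  expect_equal(W[upper.tri(W)], s$Sim[upper.tri(s$Sim)])
  expect_equal(diag(W), rep(0, 8))
  # single gated pair
  gp <- matrix(0, 8, 8); gp[2, 5] <- gp[5, 2] <- 1
  Wp <- suppressMessages(population_adjacency(s$Sim, gp))
  expect_equal(sum(Wp > 0), 2)
  # gate sparsity bound: nnz(W) <= 2 n knn
  ph <- data.frame(sex = rep(c("F", "M"), 4), apoe = rep("E3", 8))
  for (knn in c(2, 4)) {
    gk <- phenotype_gate(ph, D, knn = knn)
    Wk <- suppressMessages(population_adjacency(s$Sim, gk))
    expect_lte(sum(Wk > 0), 2 * 8 * knn)
  }
})

test_that("scaled Laplacian matches hand computation and has spectrum in [-1, 1]", {
  W2 <- rbind(c(0, 1), c(1, 0))
  Lt <- scaled_laplacian(W2)
  expect_equal(Lt, rbind(c(0, -1), c(-1, 0)), tolerance = 1e-8)
  expect_equal(scaled_laplacian(matrix(0, 3, 3)), diag(3))
  for (trial in 1:5) {
    set.seed(trial)
    n <- 12
    W <- matrix(runif(n * n), n); W <- (W + t(W)) / 2; diag(W) <- 0
    W[W < 0.5] <- 0
    ev <- eigen(scaled_laplacian(W), symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev <= 1 + 1e-6) && all(ev >= -1 - 1e-6))
  }
})

test_that("Chebyshev convolution obeys the recurrence and permutation equivariance", {
  set.seed(4)
  n <- 10; f_in <- 3; f_out <- 2
  X <- matrix(rnorm(n * f_in), n)
  theta <- lapply(1:3, function(k) matrix(rnorm(f_in * f_out), f_in))
  # K = 0: no graph mixing
  expect_equal(cheb_conv(diag(n), X, theta[1], K = 0), X %*% theta[[1]])
  # Ltilde = 0: T_0 = I, T_1 = 0, T_2 = -I
  Z <- cheb_conv(matrix(0, n, n), X, theta, K = 2)
  expect_equal(Z, X %*% theta[[1]] - X %*% theta[[3]])
  # permutation equivariance
  W <- matrix(runif(n * n), n); W <- (W + t(W)) / 2; diag(W) <- 0
  Lt <- scaled_laplacian(W)
  P <- diag(n)[sample(n), ]
  lhs <- P %*% cheb_conv(Lt, X, theta, K = 2)
  rhs <- cheb_conv(P %*% Lt %*% t(P), P %*% X, theta, K = 2)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_error(cheb_conv(Lt, X, theta, K = 1), "coefficient")
})

make_blob_graph <- function(n = 24, sep = 3, seed = 7) {
  set.seed(seed)
  lab <- rep(c("CN", "AD"), each = n / 2)
  X <- matrix(rnorm(n * 4), n) + sep * (lab == "AD")
  D <- as.matrix(dist(X))
  ph <- data.frame(sex = rep("F", n), apoe = rep("E3", n))
  population_graph(X, D, ph, lab, knn = 5)
}

test_that("transductive training yields softmax rows and learns separable blobs", {
  g <- make_blob_graph()
  cfg <- gcn_config(hidden = c(16, 16), epochs = 120, dropout = 0.2, seed = 3)
  tr <- c(1:8, 13:20)
  fit <- train_transductive(g, cfg, tr)
  expect_equal(rowSums(fit$probabilities), rep(1, 24), tolerance = 1e-6)
  expect_lt(tail(fit$loss_trace, 1), fit$loss_trace[1])
  ev <- evaluate_split(fit$probabilities, g$labels, setdiff(1:24, tr))
  expect_equal(ev$accuracy, 1)

  # all-zero adjacency degenerates to a node-wise MLP and still separates
  g0 <- g; g0$W <- matrix(0, 24, 24)
  fit0 <- train_transductive(g0, cfg, tr)
  pred <- colnames(fit0$probabilities)[max.col(fit0$probabilities[tr, ])]
  expect_equal(mean(pred == as.character(g$labels[tr])), 1)

  # different seeds give different weights; same seed is bitwise reproducible
  fit_a <- train_transductive(g, gcn_config(hidden = 8, epochs = 10, seed = 1), tr)
  fit_b <- train_transductive(g, gcn_config(hidden = 8, epochs = 10, seed = 2), tr)
  fit_a2 <- train_transductive(g, gcn_config(hidden = 8, epochs = 10, seed = 1), tr)
  expect_false(identical(fit_a$model$theta, fit_b$model$theta))
  expect_identical(fit_a$model$theta, fit_a2$model$theta)
  expect_error(train_transductive(g, cfg, 1:5), "missing")
})

test_that("split metrics match hand-computed confusion counts", {
  # TP = 3, FN = 1, TN = 4, FP = 2
  probs <- matrix(0, 10, 2, dimnames = list(NULL, c("CN", "AD")))
  truth <- c(rep("AD", 4), rep("CN", 6))
  pred <- c("AD", "AD", "AD", "CN", "AD", "AD", "CN", "CN", "CN", "CN")
  probs[cbind(1:10, match(pred, colnames(probs)))] <- 1
  ev <- evaluate_split(probs, truth, 1:10, positive_class = "AD")
  expect_equal(ev$accuracy, 0.7)
  expect_equal(ev$precision, 0.6)
  expect_equal(ev$recall, 0.75)
  expect_equal(ev$specificity, 2 / 3)

  perfect <- probs
  perfect[, ] <- 0
  perfect[cbind(1:10, match(truth, colnames(probs)))] <- 1
  evp <- evaluate_split(perfect, truth, 1:10)
  expect_true(all(unlist(evp[c("accuracy", "precision", "recall", "specificity")]) == 1))

  none <- probs; none[, ] <- 0; none[, "CN"] <- 1
  expect_warning(evn <- evaluate_split(none, truth, 1:10), "precision")
  expect_true(is.nan(evn$precision))
  expect_equal(evn$specificity, 1)
  expect_error(evaluate_split(probs, truth, integer(0)), "empty")
})

test_that("stratified splits preserve class proportions within one subject", {
  for (seed in 1:5) {
    set.seed(seed)
    lab <- factor(sample(c(rep("CN", 17), rep("AD", 13))))
    tr <- stratified_split(lab, 0.7)
    expect_equal(length(tr), round(0.7 * 30))
    for (cl in levels(lab)) {
      got <- sum(lab[tr] == cl)
      expect_lte(abs(got - 0.7 * sum(lab == cl)), 1)
    }
  }
  expect_error(stratified_split(factor(c("A", "A", "B")), 0.7), "stratify")
})

test_that("Monte Carlo CV is reproducible and summarizes all four metrics", {
  g <- make_blob_graph()
  cfg <- gcn_config(hidden = 8, epochs = 40, dropout = 0.3, seed = 5)
  cv1 <- monte_carlo_cv(g, cfg, n_draws = 3, seed = 11)
  cv2 <- monte_carlo_cv(g, cfg, n_draws = 3, seed = 11)
  expect_identical(cv1$per_draw, cv2$per_draw)
  expect_equal(cv1$summary$metric, c("accuracy", "precision", "recall", "specificity"))
  expect_true(all(cv1$per_draw$accuracy >= 0 & cv1$per_draw$accuracy <= 1))
  expect_error(monte_carlo_cv(g, cfg, n_draws = 1, train_fraction = 1.2), "train_fraction")
})
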