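#' Population-graph GCN for transductive disease grading
#'
#' Subjects are nodes of a population graph whose edge weights combine a
#' radial-basis-function similarity of their shape descriptors with a
#' phenotype gate (sex and ApoE genotype must coincide and the subjects must
#' be mutual-or-one-way k-nearest neighbours). A feed-forward graph
#' convolutional network with Chebyshev-polynomial spectral convolutions is
#' trained transductively: labels of the training nodes drive a
#' cross-entropy loss while predictions are produced for every node.
#'
#' @name population_gcn
NULL

#' RBF similarity from descriptor distances
#'
#' Sim_ij = exp(-0.5 d_ij^2 / sigma^2) with sigma the median of the
#' off-diagonal pairwise distances.
#'
#' @param distances symmetric nonnegative matrix with zero diagonal.
#' @return list with `Sim` and `sigma`.
#' @export
similarity_matrix <- function(distances) {
  n <- nrow(distances)
  if (n < 2L) stopf("need at least 2 subjects")
  off <- distances[upper.tri(distances)]
  sigma <- median(off)
  if (!is.finite(sigma) || sigma <= 0)
    stopf("sigma undefined: median pairwise distance is %g", sigma)
  Sim <- exp(-0.5 * distances^2 / sigma^2)
  list(Sim = Sim, sigma = sigma)
}

#' Phenotype gate
#'
#' gate_ij = 1 iff sex and ApoE type coincide and one subject is among the
#' `knn` closest neighbours of the other (by descriptor distance); symmetric
#' with zero diagonal. `knn` is clipped to n - 1 for small cohorts.
#'
#' @param phenotypes data.frame with columns `sex` and `apoe` (row order =
#'   subject order of `distances`).
#' @param distances symmetric distance matrix.
#' @param knn neighbourhood size (default 30).
#' @return binary matrix.
#' @export
phenotype_gate <- function(phenotypes, distances, knn = 30) {
  n <- nrow(distances)
  if (nrow(phenotypes) != n)
    stopf("phenotype table has %d rows for %d subjects", nrow(phenotypes), n)
  for (col in c("sex", "apoe")) {
    miss <- which(is.na(phenotypes[[col]]) | !nzchar(phenotypes[[col]]))
    if (length(miss))
      stopf("missing %s for subject %s", col,
            paste(head(miss, 5), collapse = ", "))
  }
  knn <- min(knn, n - 1L)
  nnmask <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- distances[i, ]; d[i] <- Inf
    nnmask[i, order(d)[seq_len(knn)]] <- TRUE
  }
  nnmask <- nnmask | t(nnmask)
  same <- outer(phenotypes$sex, phenotypes$sex, "==") &
    outer(phenotypes$apoe, phenotypes$apoe, "==")
  gate <- (same & nnmask) * 1
  diag(gate) <- 0
  gate
}

#' Population adjacency
#'
#' Elementwise product of the similarity kernel and the phenotype gate, with
#' zero diagonal. Isolated nodes are permitted (the convolution then reduces
#' to its self term).
#'
#' @param Sim similarity matrix; `gate` binary matrix of the same size.
#' @param gate see above.
#' @return symmetric nonnegative adjacency.
#' @export
population_adjacency <- function(Sim, gate) {
  if (!all(dim(Sim) == dim(gate))) stopf("dimension mismatch")
  W <- unname(Sim * gate)
  diag(W) <- 0
  iso <- sum(rowSums(W) == 0)
  if (iso) message(sprintf("population graph has %d isolated node(s)", iso))
  W
}

#' Build a population graph
#'
#' @param features node feature matrix (subjects x features).
#' @param distances descriptor distance matrix for the kernel and gate.
#' @param phenotypes data.frame with `sex`, `apoe` (and optionally `label`).
#' @param labels factor or character vector of class labels.
#' @param knn gate neighbourhood size.
#' @return object of class `population_graph`.
#' @export
population_graph <- function(features, distances, phenotypes, labels, knn = 30) {
  sim <- similarity_matrix(distances)
  gate <- phenotype_gate(phenotypes, distances, knn = knn)
  W <- population_adjacency(sim$Sim, gate)
  structure(list(W = W, Sim = sim$Sim, sigma = sim$sigma, gate = gate,
                 distances = distances, features = as.matrix(features),
                 labels = factor(labels), phenotypes = phenotypes,
                 knn = knn),
            class = "population_graph")
}

#' @export
print.population_graph <- function(x, ...) {
  cat(sprintf("population_graph: %d subjects, %d features, %d nonzero edges, sigma=%.4g\n",
              nrow(x$features), ncol(x$features), sum(x$W > 0), x$sigma))
  invisible(x)
}

#' Scaled graph Laplacian
#'
#' L = I - D^{-1/2} W D^{-1/2} (zero-degree rows get D^{-1/2} = 0), rescaled
#' to Ltilde = 2 L / lambda_max - I so its spectrum lies in [-1, 1].
#' Population graphs are cohort-sized, so lambda_max defaults to the exact
#' largest eigenvalue, which guarantees the Chebyshev domain; `"power"`
#' (50 deterministic power iterations) and a fixed numeric value (the common
#' shortcut 2) are available.
#'
#' @param W symmetric nonnegative adjacency.
#' @param lmax `"exact"`, `"power"`, or a fixed numeric value (e.g. 2).
#' @param power_iter power iteration count.
#' @return dense symmetric matrix (no dimnames).
#' @export
scaled_laplacian <- function(W, lmax = "exact", power_iter = 50) {
  n <- nrow(W)
  deg <- rowSums(W)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(n) - (dinv * unname(as.matrix(W))) * rep(dinv, each = n)
  L <- sym_part(L)
  if (identical(lmax, "exact")) {
    lam <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values, 1)
  } else if (identical(lmax, "power")) {
    v <- rep(1, n) + seq_len(n) / n  # deterministic, not an eigenvector of I
    v <- v / sqrt(sum(v^2))
    lam <- 1
    for (i in seq_len(power_iter)) {
      u <- L %*% v
      lam <- sqrt(sum(u^2))
      if (lam < 1e-14) { lam <- 1; break }
      v <- u / lam
    }
    lam <- max(lam, 1)  # convention for degenerate graphs
  } else {
    lam <- as.numeric(lmax)
  }
  2 * L / lam - diag(n)
}

# Chebyshev basis applied to a matrix of node signals:
# returns list T_0 X, ..., T_K X via the recurrence.
cheb_apply <- function(Lt, X, K) {
  out <- vector("list", K + 1L)
  out[[1]] <- X
  if (K >= 1) out[[2]] <- Lt %*% X
  if (K >= 2) for (k in 2:K) out[[k + 1]] <- 2 * (Lt %*% out[[k]]) - out[[k - 1]]
  out
}

#' Chebyshev graph convolution
#'
#' sum_{k=0..K} T_k(Ltilde) X Theta_k with the Chebyshev recurrence
#' T_0 = I, T_1 = Ltilde, T_k = 2 Ltilde T_{k-1} - T_{k-2}; no explicit
#' polynomial powers are formed.
#'
#' @param Lt scaled Laplacian from [scaled_laplacian].
#' @param X node features (n x f_in).
#' @param theta list of K + 1 coefficient matrices (f_in x f_out).
#' @param K Chebyshev order (default `length(theta) - 1`).
#' @return n x f_out matrix.
#' @export
cheb_conv <- function(Lt, X, theta, K = length(theta) - 1L) {
  if (length(theta) != K + 1L) stopf("need K + 1 = %d coefficient matrices, got %d",
                                     K + 1L, length(theta))
  if (ncol(X) != nrow(theta[[1]]))
    stopf("feature dimension %d does not match theta (%d rows)", ncol(X), nrow(theta[[1]]))
  TX <- cheb_apply(Lt, X, K)
  Z <- TX[[1]] %*% theta[[1]]
  if (K >= 1) for (k in seq_len(K)) Z <- Z + TX[[k + 1]] %*% theta[[k + 1]]
  Z
}

#' GCN configuration
#'
#' @param cheb_order Chebyshev order K (default 2, "second-order").
#' @param hidden hidden layer widths (default c(64, 64); the network has
#'   three convolution layers: features -> 64 -> 64 -> classes).
#' @param epochs,learning_rate,weight_decay,dropout optimizer settings
#'   (adaptive-moments gradient descent).
#' @param lmax `"exact"`, `"power"`, or a fixed value for the Laplacian rescaling.
#' @param seed RNG seed for initialization and dropout.
#' @return list of class `gcn_config`.
#' @export
gcn_config <- function(cheb_order = 2L, hidden = c(64L, 64L), epochs = 200L,
                       learning_rate = 1e-2, weight_decay = 5e-4,
                       dropout = 0.5, lmax = "exact", seed = 1L) {
  stopifnot(cheb_order >= 1L, length(hidden) >= 1L)
  structure(list(cheb_order = as.integer(cheb_order), hidden = as.integer(hidden),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, dropout = dropout, lmax = lmax,
                 seed = as.integer(seed)),
            class = "gcn_config")
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

glorot <- function(fin, fout) {
  r <- sqrt(6 / (fin + fout))
  matrix(runif(fin * fout, -r, r), fin, fout)
}

#' Train the transductive GCN
#'
#' Three Chebyshev convolution layers (hidden widths from the config, output
#' width = number of classes), ReLU and dropout after the hidden layers,
#' node-wise softmax output; training minimizes the cross-entropy of the
#' training nodes by adaptive-moments gradient descent. Deterministic given
#' the config seed.
#'
#' @param graph a [population_graph].
#' @param config a [gcn_config].
#' @param train_idx indices of labeled training nodes.
#' @return list with `probabilities` (n x classes, rows sum to 1), `model`
#'   (parameters and scaled Laplacian), `loss_trace`.
#' @export
train_transductive <- function(graph, config = gcn_config(), train_idx) {
  labels <- graph$labels
  classes <- levels(labels)
  if (any(!classes %in% unique(as.character(labels[train_idx]))))
    stopf("class '%s' missing from the training split",
          setdiff(classes, unique(as.character(labels[train_idx])))[1])
  X <- graph$features
  n <- nrow(X)
  K <- config$cheb_order
  dims <- c(ncol(X), config$hidden, length(classes))
  nl <- length(dims) - 1L
  Lt <- scaled_laplacian(graph$W, lmax = config$lmax)

  set.seed(config$seed)
  theta <- lapply(seq_len(nl), function(l)
    lapply(seq_len(K + 1L), function(k) glorot(dims[l], dims[l + 1L])))
  bias <- lapply(seq_len(nl), function(l) rep(0, dims[l + 1L]))

  Yhot <- matrix(0, n, length(classes))
  Yhot[cbind(seq_len(n), as.integer(labels))] <- 1

  # Adam state
  zeros_like <- function(p) lapply(p, function(q) if (is.list(q)) zeros_like(q) else q * 0)
  m_t <- zeros_like(theta); v_t <- zeros_like(theta)
  m_b <- zeros_like(bias); v_b <- zeros_like(bias)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate; wd <- config$weight_decay; p_drop <- config$dropout
  ntr <- length(train_idx)
  loss_trace <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    H <- X
    cache <- vector("list", nl)
    for (l in seq_len(nl)) {
      TX <- cheb_apply(Lt, H, K)
      Z <- matrix(rep(bias[[l]], each = n), n, dims[l + 1L])
      for (k in seq_len(K + 1L)) Z <- Z + TX[[k]] %*% theta[[l]][[k]]
      relu_mask <- NULL; drop_mask <- NULL
      if (l < nl) {
        relu_mask <- Z > 0
        Z <- Z * relu_mask
        if (p_drop > 0) {
          drop_mask <- matrix(runif(length(Z)) > p_drop, n, ncol(Z)) / (1 - p_drop)
          Z <- Z * drop_mask
        }
      }
      cache[[l]] <- list(TX = TX, relu = relu_mask, drop = drop_mask)
      H <- Z
    }
    P <- softmax_rows(H)
    loss <- -sum(log(pmax(P[cbind(train_idx, as.integer(labels[train_idx]))], 1e-12))) / ntr
    loss_trace[ep] <- loss

    dZ <- matrix(0, n, ncol(P))
    dZ[train_idx, ] <- (P[train_idx, , drop = FALSE] - Yhot[train_idx, , drop = FALSE]) / ntr
    for (l in rev(seq_len(nl))) {
      TX <- cache[[l]]$TX
      gb <- colSums(dZ)
      gth <- lapply(seq_len(K + 1L), function(k) crossprod(TX[[k]], dZ) + wd * theta[[l]][[k]])
      if (l > 1L) {
        TdZ <- cheb_apply(Lt, dZ, K)
        dH <- TdZ[[1]] %*% t(theta[[l]][[1]])
        for (k in seq_len(K)) dH <- dH + TdZ[[k + 1]] %*% t(theta[[l]][[k + 1]])
        if (!is.null(cache[[l - 1L]]$drop)) dH <- dH * cache[[l - 1L]]$drop
        dH <- dH * cache[[l - 1L]]$relu
        dZ <- dH
      }
      # Adam updates
      for (k in seq_len(K + 1L)) {
        m_t[[l]][[k]] <- b1 * m_t[[l]][[k]] + (1 - b1) * gth[[k]]
        v_t[[l]][[k]] <- b2 * v_t[[l]][[k]] + (1 - b2) * gth[[k]]^2
        mh <- m_t[[l]][[k]] / (1 - b1^ep); vh <- v_t[[l]][[k]] / (1 - b2^ep)
        theta[[l]][[k]] <- theta[[l]][[k]] - lr * mh / (sqrt(vh) + eps)
      }
      m_b[[l]] <- b1 * m_b[[l]] + (1 - b1) * gb
      v_b[[l]] <- b2 * v_b[[l]] + (1 - b2) * gb^2
      bias[[l]] <- bias[[l]] - lr * (m_b[[l]] / (1 - b1^ep)) /
        (sqrt(v_b[[l]] / (1 - b2^ep)) + eps)
    }
  }

  # final forward pass without dropout
  H <- X
  for (l in seq_len(nl)) {
    TX <- cheb_apply(Lt, H, K)
    Z <- matrix(rep(bias[[l]], each = n), n, dims[l + 1L])
    for (k in seq_len(K + 1L)) Z <- Z + TX[[k]] %*% theta[[l]][[k]]
    if (l < nl) Z <- Z * (Z > 0)
    H <- Z
  }
  P <- unname(softmax_rows(H))
  colnames(P) <- classes
  list(probabilities = P,
       model = list(theta = theta, bias = bias, dims = dims, K = K, Lt = Lt,
                    classes = classes),
       loss_trace = loss_trace)
}

#' Classification metrics on a test split
#'
#' Argmax predictions scored by accuracy, precision, recall/sensitivity and
#' specificity with respect to `positive_class`; ratios with zero denominator
#' are reported as NaN with a warning.
#'
#' @param probabilities n x classes matrix (column names = classes).
#' @param labels true labels for all nodes.
#' @param test_idx indices of the test nodes.
#' @param positive_class label treated as positive (default `"AD"`).
#' @return list of class `eval_result` with the four metrics and the
#'   confusion counts.
#' @export
evaluate_split <- function(probabilities, labels, test_idx,
                           positive_class = "AD") {
  if (!length(test_idx)) stopf("empty test set")
  pred <- colnames(probabilities)[max.col(probabilities[test_idx, , drop = FALSE],
                                          ties.method = "first")]
  truth <- as.character(labels[test_idx])
  pos <- truth == positive_class
  ppos <- pred == positive_class
  TP <- sum(pos & ppos); FP <- sum(!pos & ppos)
  FN <- sum(pos & !ppos); TN <- sum(!pos & !ppos)
  ratio <- function(num, den, what) {
    if (den == 0) { warnf("%s undefined (zero denominator)", what); return(NaN) }
    num / den
  }
  structure(list(accuracy = (TP + TN) / length(test_idx),
                 precision = ratio(TP, TP + FP, "precision"),
                 recall = ratio(TP, TP + FN, "recall"),
                 specificity = ratio(TN, TN + FP, "specificity"),
                 counts = c(TP = TP, FP = FP, FN = FN, TN = TN)),
            class = "eval_result")
}

#' Stratified train indices
#'
#' Per-class training counts are floor(fraction * class size); the remainders
#' needed to reach round(fraction * n) are assigned by largest fractional
#' part. Deterministic given the RNG state.
#'
#' @param labels factor of class labels.
#' @param train_fraction fraction of subjects used for training.
#' @return integer vector of training indices.
#' @export
stratified_split <- function(labels, train_fraction = 0.7) {
  labels <- factor(labels)
  n <- length(labels)
  target <- round(train_fraction * n)
  sizes <- table(labels)
  raw <- train_fraction * as.numeric(sizes)
  cnt <- floor(raw)
  rem <- target - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  idx <- integer(0)
  for (ci in seq_along(sizes)) {
    members <- which(labels == names(sizes)[ci])
    take <- min(cnt[ci], length(members))
    if (take < 1 || take >= length(members))
      stopf("class '%s' too small to stratify (size %d)", names(sizes)[ci], length(members))
    idx <- c(idx, sample(members, take))
  }
  sort(idx)
}

#' Stratified Monte Carlo cross-validation
#'
#' Draws independent stratified train/test splits, retrains the GCN from
#' scratch on each, and summarizes accuracy, precision, recall and
#' specificity as mean and standard deviation. Reproducible given `seed`.
#'
#' @param graph a [population_graph].
#' @param config a [gcn_config].
#' @param n_draws number of Monte Carlo draws (the reference protocol uses
#'   100 or 300; tests use fewer).
#' @param train_fraction training fraction (default 0.7).
#' @param seed master seed; per-draw seeds are derived from it.
#' @param positive_class passed to [evaluate_split].
#' @return object of class `cv_result`: `per_draw` data.frame and `summary`
#'   (mean and sd per metric).
#' @export
monte_carlo_cv <- function(graph, config = gcn_config(), n_draws = 100,
                           train_fraction = 0.7, seed = 1L,
                           positive_class = "AD") {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  if (nlevels(graph$labels) < 2L) stopf("need at least two classes")
  set.seed(as.integer(seed))
  draw_seeds <- sample.int(.Machine$integer.max, n_draws)
  rows <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    set.seed(draw_seeds[d])
    tr <- stratified_split(graph$labels, train_fraction)
    te <- setdiff(seq_along(graph$labels), tr)
    cfg <- config
    cfg$seed <- draw_seeds[d] %% 1000003L
    fit <- train_transductive(graph, cfg, tr)
    ev <- suppressWarnings(evaluate_split(fit$probabilities, graph$labels, te,
                                          positive_class))
    rows[[d]] <- data.frame(draw = d, accuracy = ev$accuracy,
                            precision = ev$precision, recall = ev$recall,
                            specificity = ev$specificity)
  }
  per_draw <- do.call(rbind, rows)
  met <- c("accuracy", "precision", "recall", "specificity")
  summary <- data.frame(
    metric = met,
    mean = vapply(met, function(m) mean(per_draw[[m]], na.rm = TRUE), 0),
    sd = vapply(met, function(m) sd(per_draw[[m]], na.rm = TRUE), 0))
  structure(list(per_draw = per_draw, summary = summary,
                 n_draws = n_draws, train_fraction = train_fraction,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Monte Carlo CV (%d draws, %.0f%%/%.0f%% split):\n",
              x$n_draws, 100 * x$train_fraction, 100 * (1 - x$train_fraction)))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-11s %.3f +/- %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}
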