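#' Functional map networks and the consistent latent basis
#'
#' A map network holds ZoomOut-refined functional maps for every ordered pair
#' of shapes, pruned to a symmetrized k-nearest-neighbor graph by 2-cycle
#' consistency (smallest k that connects the collection). The consistent
#' latent basis (CLB) is a family of per-shape coefficient matrices Y_S whose
#' columns represent latent functions transported into each other by the
#' network's maps; it is computed as the smallest eigenvectors of the
#' network's quadratic consistency form and refined by Consistent ZoomOut.
#'
#' @name map_network
NULL

edge_key <- function(i, j) paste0(i, "->", j)

#' All-pairs functional maps
#'
#' Computes a ZoomOut-refined functional map for every ordered pair of
#' shapes, plus the symmetrized 2-cycle-consistency score matrix. By default
#' every mesh is rigidly aligned once to the first shape (`align_scope =
#' "reference"`) so the registration cost is linear, not quadratic, in the
#' collection size; `"pairwise"` re-registers per pair and `"none"` trusts
#' the input frames.
#'
#' @param shapes list; each element has `mesh` (a [triangle_mesh]) and
#'   `basis` (an [eigenbasis]).
#' @param n_landmarks,k0,zoomout_steps map estimation parameters
#'   (defaults 130, 30, 12).
#' @param seed integer seed for sampling.
#' @param align_method passed to [rigid_register].
#' @param align_scope `"reference"`, `"pairwise"` or `"none"`.
#' @param subsample registration subsample size.
#' @param nn_subsample optional vertex-subsample size for the ZoomOut inner
#'   loops (farthest-point subsets, mass-weighted quadrature); `NULL` runs
#'   the exact full-vertex refinement.
#' @return object of class `map_network` with `ids`, `shapes`, `maps` (list
#'   keyed `"i->j"`), `consistency` (symmetric matrix), `k_maps`.
#' @export
all_pairs_fmaps <- function(shapes, n_landmarks = 130, k0 = 30,
                            zoomout_steps = 12, seed = 1L,
                            align_method = c("cpd", "icp", "none"),
                            align_scope = c("reference", "pairwise", "none"),
                            subsample = 300, nn_subsample = NULL) {
  align_method <- match.arg(align_method)
  align_scope <- match.arg(align_scope)
  n <- length(shapes)
  if (n < 2L) stopf("need at least 2 shapes, got %d", n)
  ids <- names(shapes)
  if (is.null(ids)) ids <- vapply(shapes, function(s) s$mesh$subject_id, "")
  if (anyDuplicated(ids)) stopf("duplicate shape identifiers")
  names(shapes) <- ids
  ks <- vapply(shapes, function(s) s$basis$k, 0L)
  if (length(unique(ks)) != 1L) stopf("all bases must share one dimension")

  meshes_aligned <- lapply(shapes, function(s) s$mesh)
  if (align_scope == "reference" && align_method != "none") {
    ref <- shapes[[1L]]$mesh$vertices
    set.seed(as.integer(seed))
    refsub <- if (nrow(ref) > subsample) ref[sort(sample.int(nrow(ref), subsample)), ] else ref
    for (i in seq_len(n)[-1L]) {
      Vi <- shapes[[i]]$mesh$vertices
      sub <- if (nrow(Vi) > subsample) Vi[sort(sample.int(nrow(Vi), subsample)), ] else Vi
      tr <- rigid_register(refsub, sub, method = align_method)
      meshes_aligned[[i]]$vertices <- t(tr$R %*% t(Vi)) + rep(tr$t, each = nrow(Vi))
    }
  }

  # Farthest-point landmark sets are per-source-mesh; cache them.
  fps_cache <- lapply(seq_len(n), function(i)
    farthest_point_sample(meshes_aligned[[i]]$vertices, n_landmarks, seed = seed))
  nn_sub <- NULL
  if (!is.null(nn_subsample)) {
    nn_sub <- lapply(seq_len(n), function(i) {
      V <- nrow(shapes[[i]]$mesh$vertices)
      if (V <= nn_subsample) seq_len(V)
      else farthest_point_sample(shapes[[i]]$mesh$vertices, nn_subsample,
                                 seed = seed + 1L)
    })
  }

  maps <- list()
  failed <- character()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    res <- tryCatch({
      if (align_scope == "pairwise") {
        lm <- initial_landmarks(shapes[[i]]$mesh, shapes[[j]]$mesh,
                                n_landmarks = n_landmarks, seed = seed,
                                method = align_method, subsample = subsample)
      } else {
        lm_i <- fps_cache[[i]]
        lm_j <- nearest_index(meshes_aligned[[i]]$vertices[lm_i, , drop = FALSE],
                              meshes_aligned[[j]]$vertices)
        lm <- cbind(vertex_M = lm_i, vertex_N = lm_j)
      }
      f0 <- fmap_from_landmarks(shapes[[i]]$basis, shapes[[j]]$basis, lm, k0 = k0)
      f <- if (is.null(nn_sub)) {
        zoomout_refine(f0, shapes[[i]]$basis, shapes[[j]]$basis, steps = zoomout_steps)
      } else {
        new_functional_map(
          zoomout_refine_sub(f0$C, shapes[[i]]$basis, shapes[[j]]$basis,
                             zoomout_steps, nn_sub[[i]], nn_sub[[j]]),
          ids[i], ids[j])
      }
      f$source_id <- ids[i]; f$target_id <- ids[j]
      f
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, edge_key(ids[i], ids[j]))
      warnf("map %s -> %s failed: %s", ids[i], ids[j], conditionMessage(res))
    } else {
      maps[[edge_key(ids[i], ids[j])]] <- res
    }
  }

  cons <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(cons) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    mij <- maps[[edge_key(ids[i], ids[j])]]
    mji <- maps[[edge_key(ids[j], ids[i])]]
    if (!is.null(mij) && !is.null(mji)) {
      s <- (cycle_consistency(mij, mji) + cycle_consistency(mji, mij)) / 2
      cons[i, j] <- cons[j, i] <- s
    }
  }
  structure(list(ids = ids, shapes = shapes, maps = maps, consistency = cons,
                 k_maps = k0 + zoomout_steps, edges = NULL, k_used = NA_integer_,
                 failed = failed, nn_sub = nn_sub),
            class = "map_network")
}

#' @export
print.map_network <- function(x, ...) {
  cat(sprintf("map_network: %d shapes, %d maps (dim %d), %s\n",
              length(x$ids), length(x$maps), x$k_maps,
              if (is.null(x$edges)) "unpruned" else
                sprintf("%d directed edges (k_used = %d)", nrow(x$edges), x$k_used)))
  invisible(x)
}

graph_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n); seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- which(colSums(adj[frontier, , drop = FALSE] > 0) > 0)
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' Consistency-pruned k-NN graph
#'
#' Connects each shape to its k lowest-consistency-score neighbors,
#' symmetrizes by union, and returns the smallest k for which the resulting
#' graph is connected.
#'
#' @param consistency symmetric nonnegative score matrix (lower = better).
#' @return list with `edges` (two-column matrix of directed index pairs,
#'   both orders present) and `k_used`.
#' @export
consistency_knn_graph <- function(consistency) {
  n <- nrow(consistency)
  if (n < 2L || ncol(consistency) != n) stopf("need a square matrix with n >= 2")
  off <- consistency[upper.tri(consistency)]
  if (all(!is.finite(off))) stopf("no usable maps: all consistency scores are infinite")
  for (k in seq_len(n - 1L)) {
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      sc <- consistency[i, ]
      sc[i] <- Inf
      nb <- order(sc)[seq_len(k)]
      nb <- nb[is.finite(sc[nb])]
      adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj)
    if (graph_connected(adj)) {
      idx <- which(adj, arr.ind = TRUE)
      return(list(edges = unname(idx[order(idx[, 1], idx[, 2]), , drop = FALSE]),
                  k_used = k))
    }
  }
  stopf("no k connects the consistency graph")
}

#' Prune a map network by 2-cycle consistency
#'
#' @param network a `map_network` from [all_pairs_fmaps].
#' @return the network with `edges` and `k_used` filled in.
#' @export
prune_network <- function(network) {
  g <- consistency_knn_graph(network$consistency)
  network$edges <- g$edges
  network$k_used <- g$k_used
  network
}

network_edges <- function(network) {
  if (is.null(network$edges))
    stopf("network is unpruned; call prune_network() first")
  network$edges
}

# Quadratic consistency form over the stacked per-shape blocks.
clb_quadratic_form <- function(network, k) {
  n <- length(network$ids)
  H <- matrix(0, n * k, n * k)
  blk <- function(i) ((i - 1L) * k + 1L):(i * k)
  E <- network_edges(network)
  for (r in seq_len(nrow(E))) {
    i <- E[r, 1]; j <- E[r, 2]
    f <- network$maps[[edge_key(network$ids[i], network$ids[j])]]
    if (is.null(f)) next
    C <- f$C[seq_len(k), seq_len(k), drop = FALSE]
    H[blk(i), blk(i)] <- H[blk(i), blk(i)] + crossprod(C)
    H[blk(j), blk(j)] <- H[blk(j), blk(j)] + diag(k)
    H[blk(j), blk(i)] <- H[blk(j), blk(i)] - C
    H[blk(i), blk(j)] <- H[blk(i), blk(j)] - t(C)
  }
  (H + t(H)) / 2
}

clb_residual <- function(network, Y, k = nrow(Y[[1]])) {
  E <- network_edges(network)
  total <- 0; used <- 0L
  for (r in seq_len(nrow(E))) {
    i <- E[r, 1]; j <- E[r, 2]
    f <- network$maps[[edge_key(network$ids[i], network$ids[j])]]
    if (is.null(f)) next
    C <- f$C[seq_len(k), seq_len(k), drop = FALSE]
    total <- total + norm(C %*% Y[[i]] - Y[[j]], type = "F")^2
    used <- used + 1L
  }
  c(raw = total, normalized = total / (used * ncol(Y[[1]])))
}

#' Consistent latent basis
#'
#' Minimizes the network consistency energy
#' sum over edges of || C_MN Y_M - Y_N ||_F^2 subject to the stacked
#' orthonormality constraint sum_S Y_S' Y_S = n I_m, solved as the m smallest
#' eigenvectors of the quadratic form; eigenvector signs are fixed
#' deterministically.
#'
#' @param network a pruned `map_network`.
#' @param m latent dimension.
#' @param k spectral dimension at which maps are truncated (default: full
#'   map dimension).
#' @return object of class `consistent_latent_basis`: `Y` (list of k x m
#'   matrices, one per shape), `m`, `k`, `residual`, `residual_normalized`,
#'   `schedule_log`.
#' @export
canonical_latent_basis <- function(network, m, k = network$k_maps) {
  if (m > k) stopf("latent dimension m = %d exceeds map dimension %d", m, k)
  n <- length(network$ids)
  H <- clb_quadratic_form(network, k)
  e <- eigen(H, symmetric = TRUE)
  U <- e$vectors[, seq(ncol(H), ncol(H) - m + 1L), drop = FALSE]
  U <- fix_signs(U) * sqrt(n)
  Y <- lapply(seq_len(n), function(i) U[((i - 1L) * k + 1L):(i * k), , drop = FALSE])
  names(Y) <- network$ids
  res <- clb_residual(network, Y, k)
  structure(list(Y = Y, m = as.integer(m), k = as.integer(k),
                 residual = unname(res["raw"]),
                 residual_normalized = unname(res["normalized"]),
                 schedule_log = NULL),
            class = "consistent_latent_basis")
}

#' @export
print.consistent_latent_basis <- function(x, ...) {
  cat(sprintf("consistent_latent_basis: %d shapes, k=%d, m=%d, residual %.3e (%.3e per edge-column)\n",
              length(x$Y), x$k, x$m, x$residual, x$residual_normalized))
  invisible(x)
}

#' Consistent ZoomOut
#'
#' Network-wide spectral upsampling: starting from the leading
#' `init_dim` x `init_dim` principal submatrices of all edge maps, each step
#' (a) recomputes the CLB at the current dimensions, (b) refines every edge
#' map by one pointwise conversion through the latent embedding, and (c)
#' grows the spectral dimension by `basis_step` and the latent dimension
#' accumulator by `latent_step` (realized latent size is the floor of the
#' accumulator). Defaults (8 + 20 steps, +1 and +7/10) end at spectral
#' dimension 28 and latent dimension 22.
#'
#' @param network a pruned `map_network`.
#' @param init_dim initial spectral/latent dimension (default 8).
#' @param steps number of growth steps (default 20).
#' @param basis_step spectral increment per step (default 1).
#' @param latent_step latent increment per step (default 7/10).
#' @return a `consistent_latent_basis` at the final dimensions, with the
#'   refined maps in `attr(, "network")` and a `schedule_log` data frame.
#' @export
consistent_zoomout <- function(network, init_dim = 8, steps = 20,
                               basis_step = 1, latent_step = 7 / 10) {
  kmax <- network$k_maps
  if (init_dim + steps * basis_step > kmax)
    stopf("schedule ends at dimension %d but maps have dimension %d",
          init_dim + steps * basis_step, kmax)
  E <- network_edges(network)
  ids <- network$ids
  k <- as.integer(init_dim)
  # realized latent size after s steps; the small epsilon guards the floor
  # against accumulated floating-point error (e.g. 8 + 20 * 7/10 = 22 exactly)
  latent_at <- function(s) as.integer(floor(init_dim + s * latent_step + 1e-9))
  # truncate all edge maps to the initial principal submatrix
  for (r in seq_len(nrow(E))) {
    key <- edge_key(ids[E[r, 1]], ids[E[r, 2]])
    f <- network$maps[[key]]
    if (is.null(f)) next
    network$maps[[key]] <- new_functional_map(
      f$C[seq_len(k), seq_len(k), drop = FALSE], f$source_id, f$target_id)
  }
  net_k <- network; net_k$k_maps <- k
  init_clb <- canonical_latent_basis(net_k, m = latent_at(0), k = k)
  log <- data.frame(step = 0L, X_S = k, B_S = latent_at(0))

  for (s in seq_len(steps)) {
    m <- latent_at(s - 1L)
    net_k <- network; net_k$k_maps <- k
    clb <- canonical_latent_basis(net_k, m = m, k = k)
    k_next <- k + as.integer(basis_step)
    sub <- network$nn_sub
    emb <- lapply(seq_along(ids), function(i) {
      Phi <- network$shapes[[i]]$basis$vectors
      rows <- if (is.null(sub)) seq_len(nrow(Phi)) else sub[[i]]
      Phi[rows, seq_len(k), drop = FALSE] %*% clb$Y[[i]]
    })
    for (r in seq_len(nrow(E))) {
      i <- E[r, 1]; j <- E[r, 2]
      key <- edge_key(ids[i], ids[j])
      if (is.null(network$maps[[key]])) next
      nn <- nearest_index(emb[[j]], emb[[i]])
      if (is.null(sub)) {
        f <- fmap_from_pointwise(nn, network$shapes[[i]]$basis,
                                 network$shapes[[j]]$basis, k_next)
      } else {
        bi <- network$shapes[[i]]$basis; bj <- network$shapes[[j]]$basis
        wN <- bj$mass_diag[sub[[j]]]
        wN <- wN * (bj$total_area / sum(wN))
        f <- new_functional_map(
          crossprod(bj$vectors[sub[[j]], seq_len(k_next), drop = FALSE],
                    wN * bi$vectors[sub[[i]][nn], seq_len(k_next), drop = FALSE]),
          ids[i], ids[j])
      }
      f$source_id <- ids[i]; f$target_id <- ids[j]
      network$maps[[key]] <- f
    }
    k <- k_next
    log <- rbind(log, data.frame(step = s, X_S = k, B_S = latent_at(s)))
  }
  net_k <- network; net_k$k_maps <- k
  out <- canonical_latent_basis(net_k, m = latent_at(steps), k = k)
  out$schedule_log <- log
  out$init_residual <- init_clb$residual
  out$init_residual_normalized <- init_clb$residual_normalized
  attr(out, "network") <- network
  out
}
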