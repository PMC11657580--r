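#' Pipeline orchestration
#'
#' The full method runs in stages: operators (omega = 0 mass/stiffness and
#' 42-dimensional eigenbasis per shape) -> maps (all-pairs ZoomOut-refined
#' functional maps) -> network (2-cycle-consistency pruning) -> clb
#' (Consistent ZoomOut) -> descriptors (isophotic inner products at
#' omega = alpha * ell^2, Log-Euclidean features) -> graph (phenotype-gated
#' population graph) -> evaluate (stratified Monte Carlo CV of the GCN).
#' The basis is always computed at omega = 0 (the standard cotangent
#' scheme); omega enters only through the descriptor-stage inner products,
#' which makes alpha sweeps cheap. [run_stage] adds checksum-based RDS
#' caching with provenance records.
#'
#' @name cli_pipeline
NULL

#' Pipeline configuration
#'
#' Defaults are the reference processing constants: 42 eigenfunctions,
#' 130 landmarks, 30-dimensional map initialization with 12 ZoomOut steps,
#' Consistent ZoomOut from 8 x 8 with 20 steps growing the spectral dimension
#' by 1 and the latent dimension by 7/10 per step, alpha = 2^-6, 30-NN
#' phenotype gate, 70/30 stratified Monte Carlo cross-validation.
#'
#' @param ... overrides of any default.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # cohort simulation (used when no mesh directory is given)
    n = 60, effect_kind = "bump", effect_size = 0.15, genus1_fraction = 0,
    sides = "right", n_lat = 20, n_lon = 24, noise_amplitude = 0.025,
    apoe_association = 0.5,
    # spectral / map stages
    k_eigen = 42, landmark_count = 130, fmap_init_dim = 30, zoomout_steps = 12,
    align_method = "cpd", align_scope = "reference", zoomout_nn_subsample = NULL,
    clb_init_dim = 8, clb_steps = 20, clb_basis_step = 1, clb_latent_step = 7 / 10,
    # descriptor / graph / training stages
    alpha = 2^-6, descriptor = "both", epsilon = 1e-8, knn = 30,
    cv_draws = 100, train_fraction = 0.7, positive_class = "AD",
    cheb_order = 2, hidden = c(64, 64), epochs = 200, learning_rate = 1e-2,
    weight_decay = 5e-4, dropout = 0.5,
    seed = 1L, cache_dir = NULL, mesh_dir = NULL, phenotype_csv = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  structure(modifyList(cfg, over), class = c("pipeline_config", "list"))
}

#' Operators and eigenbasis for a mesh collection
#'
#' @param meshes named list of [triangle_mesh].
#' @param k_eigen basis dimension.
#' @return named list; each element has `mesh` and `basis`.
#' @export
build_shapes <- function(meshes, k_eigen = 42) {
  out <- lapply(meshes, function(m) {
    ops <- metric_operators(m, omega = 0)
    b <- eigenbasis(ops, k_eigen)
    b$subject_id <- m$subject_id
    list(mesh = m, basis = b)
  })
  names(out) <- names(meshes)
  out
}

#' Map network and consistent latent basis for one side
#'
#' @param shapes output of [build_shapes].
#' @param config a [pipeline_config].
#' @return the [consistent_zoomout] result (network in `attr(, "network")`).
#' @export
compute_clb <- function(shapes, config = pipeline_config()) {
  net <- all_pairs_fmaps(shapes,
                         n_landmarks = config$landmark_count,
                         k0 = config$fmap_init_dim,
                         zoomout_steps = config$zoomout_steps,
                         seed = config$seed,
                         align_method = config$align_method,
                         align_scope = config$align_scope,
                         nn_subsample = config$zoomout_nn_subsample)
  net <- prune_network(net)
  consistent_zoomout(net,
                     init_dim = config$clb_init_dim,
                     steps = config$clb_steps,
                     basis_step = config$clb_basis_step,
                     latent_step = config$clb_latent_step)
}

#' Shape descriptors for one side
#'
#' @param shapes output of [build_shapes].
#' @param clb a `consistent_latent_basis` over the same shapes.
#' @param alpha scale-free blending factor; per shape,
#'   omega = alpha * (bounding box diagonal)^2.
#' @param epsilon SPD floor.
#' @return named list of [shape_descriptor] objects.
#' @export
compute_descriptors <- function(shapes, clb, alpha = 2^-6, epsilon = 1e-8) {
  ids <- names(shapes)
  out <- lapply(ids, function(id) {
    mesh <- shapes[[id]]$mesh
    omega <- omega_from_alpha(mesh, alpha)
    normals <- if (omega > 0) vertex_normals(mesh) else NULL
    ops <- metric_operators(mesh, omega = omega, normals = normals)
    shape_descriptor(clb$Y[[id]], shapes[[id]]$basis, ops, epsilon = epsilon)
  })
  names(out) <- ids
  out
}

# Combine per-side features/distances (sides concatenate features; squared
# log-distances add).
combine_sides <- function(per_side, which = "both") {
  feats <- lapply(per_side, function(p) descriptor_features(p, which = which))
  dists <- lapply(per_side, function(p) descriptor_distances(p, which = which))
  X <- do.call(cbind, feats)
  D2 <- Reduce(`+`, lapply(dists, function(d) d^2))
  list(features = X, distances = sqrt(D2))
}

#' End-to-end features for a synthetic cohort
#'
#' Runs operators, maps, CLB and descriptors per side and combines sides.
#'
#' @param cohort a [synthetic_cohort] (or a compatible list of per-subject
#'   per-side meshes with `labels` and `phenotypes`).
#' @param config a [pipeline_config].
#' @param alpha optional override of `config$alpha`.
#' @param clb_by_side optional precomputed CLB per side (from a previous call
#'   with a different alpha; the omega = 0 map network does not depend on
#'   alpha).
#' @return list with `features`, `distances`, `labels`, `phenotypes`,
#'   `shapes_by_side`, `clb_by_side`.
#' @export
cohort_features <- function(cohort, config = pipeline_config(), alpha = NULL,
                            clb_by_side = NULL) {
  alpha <- alpha %||% config$alpha
  sides <- cohort$sides
  shapes_by_side <- lapply(sides, function(sd)
    build_shapes(lapply(cohort$meshes, `[[`, sd), k_eigen = config$k_eigen))
  names(shapes_by_side) <- sides
  if (is.null(clb_by_side)) {
    clb_by_side <- lapply(sides, function(sd) compute_clb(shapes_by_side[[sd]], config))
    names(clb_by_side) <- sides
  }
  desc_by_side <- lapply(sides, function(sd)
    compute_descriptors(shapes_by_side[[sd]], clb_by_side[[sd]],
                        alpha = alpha, epsilon = config$epsilon))
  comb <- combine_sides(desc_by_side, which = config$descriptor)
  list(features = comb$features, distances = comb$distances,
       labels = cohort$labels, phenotypes = cohort$phenotypes,
       shapes_by_side = shapes_by_side, clb_by_side = clb_by_side,
       descriptors_by_side = desc_by_side, alpha = alpha)
}

#' Grade a cohort end to end
#'
#' Convenience wrapper: [cohort_features] + [population_graph] +
#' [monte_carlo_cv].
#'
#' @inheritParams cohort_features
#' @param n_draws Monte Carlo draws (default `config$cv_draws`).
#' @param permute_labels if `TRUE`, labels are randomly permuted before
#'   training (permutation null; the graph and features are untouched).
#' @return a `cv_result` with the feature bundle in `attr(, "features")`.
#' @export
grade_cohort <- function(cohort, config = pipeline_config(), alpha = NULL,
                         n_draws = NULL, clb_by_side = NULL,
                         permute_labels = FALSE) {
  fb <- cohort_features(cohort, config, alpha = alpha, clb_by_side = clb_by_side)
  cv <- grade_features(fb, config, n_draws = n_draws,
                       permute_labels = permute_labels)
  attr(cv, "features") <- fb
  cv
}

#' Grade from a precomputed feature bundle
#'
#' @param fb output of [cohort_features].
#' @param config a [pipeline_config].
#' @inheritParams grade_cohort
#' @return a `cv_result`.
#' @export
grade_features <- function(fb, config = pipeline_config(), n_draws = NULL,
                           permute_labels = FALSE) {
  labels <- fb$labels
  if (permute_labels) {
    set.seed(config$seed + 424243L)
    labels <- sample(labels)
  }
  g <- population_graph(fb$features, fb$distances, fb$phenotypes, labels,
                        knn = config$knn)
  cfg <- gcn_config(cheb_order = config$cheb_order, hidden = config$hidden,
                    epochs = config$epochs, learning_rate = config$learning_rate,
                    weight_decay = config$weight_decay, dropout = config$dropout,
                    seed = config$seed)
  monte_carlo_cv(g, cfg, n_draws = n_draws %||% config$cv_draws,
                 train_fraction = config$train_fraction, seed = config$seed,
                 positive_class = config$positive_class)
}

#' Accuracy over a logarithmic alpha grid
#'
#' Recomputes descriptors, graph and CV per alpha, reusing the omega = 0
#' map network and CLB (which do not depend on alpha).
#'
#' @param cohort a [synthetic_cohort].
#' @param alphas vector of scale-free blending factors (0 = purely intrinsic).
#' @param config a [pipeline_config].
#' @param n_draws Monte Carlo draws per alpha.
#' @return data.frame with `alpha`, `accuracy_mean`, `accuracy_sd`.
#' @export
sweep_alpha <- function(cohort, alphas = 2^seq(-10, 0, by = 2),
                        config = pipeline_config(), n_draws = NULL) {
  fb0 <- cohort_features(cohort, config, alpha = alphas[1])
  rows <- lapply(alphas, function(a) {
    fb <- if (a == fb0$alpha) fb0 else
      cohort_features(cohort, config, alpha = a, clb_by_side = fb0$clb_by_side)
    cv <- grade_features(fb, config, n_draws = n_draws)
    acc <- cv$summary[cv$summary$metric == "accuracy", ]
    data.frame(alpha = a, accuracy_mean = acc$mean, accuracy_sd = acc$sd)
  })
  do.call(rbind, rows)
}

# ---- cached staged execution ----------------------------------------------

stage_order <- c("simulate", "operators", "maps", "network", "clb",
                 "descriptors", "graph", "train", "evaluate")

# Config keys each stage's result depends on (for cache keys).
stage_keys <- list(
  simulate = c("n", "effect_kind", "effect_size", "genus1_fraction", "sides",
               "n_lat", "n_lon", "noise_amplitude", "apoe_association", "seed",
               "mesh_dir", "phenotype_csv"),
  operators = "k_eigen",
  maps = c("landmark_count", "fmap_init_dim", "zoomout_steps", "align_method",
           "align_scope", "zoomout_nn_subsample", "seed"),
  network = character(0),
  clb = c("clb_init_dim", "clb_steps", "clb_basis_step", "clb_latent_step"),
  descriptors = c("alpha", "descriptor", "epsilon"),
  graph = "knn",
  train = c("cheb_order", "hidden", "epochs", "learning_rate", "weight_decay",
            "dropout", "seed", "train_fraction"),
  evaluate = c("cv_draws", "positive_class"))

stage_upstream <- function(stage) {
  i <- match(stage, stage_order)
  if (i == 1L) character(0) else stage_order[i - 1L]
}

compute_stage <- function(stage, config, upstream) {
  switch(stage,
    simulate = {
      if (!is.null(config$mesh_dir)) {
        ph <- read_phenotypes(config$phenotype_csv)
        subjects <- unique(ph$subject_id)
        sides <- unique(ph$side)
        meshes <- lapply(subjects, function(s) {
          per <- lapply(sides, function(sd) {
            hits <- list.files(config$mesh_dir, full.names = TRUE,
                               pattern = paste0("^", s, "_", sd, "\\.(off|ply|obj)$"))
            if (!length(hits)) stopf("no mesh for subject %s side %s", s, sd)
            read_mesh(hits[1], subject_id = s, side = sd)
          })
          names(per) <- sides
          per
        })
        names(meshes) <- subjects
        lab <- ph$label[match(subjects, ph$subject_id)]
        structure(list(meshes = meshes, labels = lab,
                       phenotypes = ph[match(subjects, ph$subject_id), ],
                       sides = sides, effect_kind = "real", effect_size = NA,
                       genus1_fraction = NA, seed = config$seed,
                       handle_subjects = integer(0)),
                  class = "synthetic_cohort")
      } else {
        synthetic_cohort(n = config$n, effect_kind = config$effect_kind,
                         effect_size = config$effect_size,
                         genus1_fraction = config$genus1_fraction,
                         sides = config$sides, seed = config$seed,
                         n_lat = config$n_lat, n_lon = config$n_lon,
                         noise_amplitude = config$noise_amplitude,
                         apoe_association = config$apoe_association)
      }
    },
    operators = {
      cohort <- upstream
      sh <- lapply(cohort$sides, function(sd)
        build_shapes(lapply(cohort$meshes, `[[`, sd), k_eigen = config$k_eigen))
      names(sh) <- cohort$sides
      list(cohort = cohort, shapes_by_side = sh)
    },
    maps = {
      nets <- lapply(upstream$shapes_by_side, function(sh)
        all_pairs_fmaps(sh, n_landmarks = config$landmark_count,
                        k0 = config$fmap_init_dim,
                        zoomout_steps = config$zoomout_steps,
                        seed = config$seed, align_method = config$align_method,
                        align_scope = config$align_scope,
                        nn_subsample = config$zoomout_nn_subsample))
      c(upstream, list(networks = nets))
    },
    network = {
      upstream$networks <- lapply(upstream$networks, prune_network)
      upstream
    },
    clb = {
      clbs <- lapply(upstream$networks, function(net)
        consistent_zoomout(net, init_dim = config$clb_init_dim,
                           steps = config$clb_steps,
                           basis_step = config$clb_basis_step,
                           latent_step = config$clb_latent_step))
      c(upstream, list(clb_by_side = clbs))
    },
    descriptors = {
      sides <- names(upstream$shapes_by_side)
      desc <- lapply(sides, function(sd)
        compute_descriptors(upstream$shapes_by_side[[sd]],
                            upstream$clb_by_side[[sd]],
                            alpha = config$alpha, epsilon = config$epsilon))
      names(desc) <- sides
      comb <- combine_sides(desc, which = config$descriptor)
      c(upstream, list(descriptors_by_side = desc,
                       features = comb$features, distances = comb$distances))
    },
    graph = {
      g <- population_graph(upstream$features, upstream$distances,
                            upstream$cohort$phenotypes, upstream$cohort$labels,
                            knn = config$knn)
      c(upstream, list(graph = g))
    },
    train = {
      cfg <- gcn_config(cheb_order = config$cheb_order, hidden = config$hidden,
                        epochs = config$epochs,
                        learning_rate = config$learning_rate,
                        weight_decay = config$weight_decay,
                        dropout = config$dropout, seed = config$seed)
      set.seed(config$seed)
      tr <- stratified_split(upstream$graph$labels, config$train_fraction)
      fit <- train_transductive(upstream$graph, cfg, tr)
      c(upstream, list(fit = fit, train_idx = tr, gcn = cfg))
    },
    evaluate = {
      cv <- monte_carlo_cv(upstream$graph, upstream$gcn,
                           n_draws = config$cv_draws,
                           train_fraction = config$train_fraction,
                           seed = config$seed,
                           positive_class = config$positive_class)
      c(upstream, list(cv = cv))
    },
    stopf("unknown stage '%s'", stage))
}

#' Run a pipeline stage with caching
#'
#' Stages run in the fixed order simulate, operators, maps, network, clb,
#' descriptors, graph, train, evaluate; upstream stages are (re)run as
#' needed. With a `cache_dir` in the config, each stage's result is stored as
#' RDS next to a JSON provenance record keyed by a checksum of the stage's
#' parameters and its upstream key, so reruns with unchanged inputs are cache
#' hits and a changed parameter (e.g. `alpha`) invalidates exactly the stages
#' downstream of it. Corrupt or stale cache files trigger recomputation with
#' a warning.
#'
#' @param stage one of the stage names above.
#' @param config a [pipeline_config].
#' @return list with the stage `result`, its cache `key`, and `hit`
#'   (logical: was the result loaded from cache).
#' @export
run_stage <- function(stage, config = pipeline_config()) {
  stage <- match.arg(stage, stage_order)
  up_name <- stage_upstream(stage)
  up <- if (length(up_name)) run_stage(up_name, config) else NULL
  params <- config[stage_keys[[stage]]]
  key <- object_checksum(list(stage = stage, params = params, upstream = up$key))
  if (!is.null(config$cache_dir)) {
    dir.create(config$cache_dir, showWarnings = FALSE, recursive = TRUE)
    rds <- file.path(config$cache_dir, paste0(stage, ".rds"))
    meta <- file.path(config$cache_dir, paste0(stage, ".json"))
    if (file.exists(rds) && file.exists(meta)) {
      prov <- tryCatch(jsonlite::read_json(meta), error = function(e) NULL)
      if (!is.null(prov) && identical(prov$key, key)) {
        res <- tryCatch(readRDS(rds), error = function(e) NULL)
        if (!is.null(res)) return(list(result = res, key = key, hit = TRUE))
        warnf("corrupt cache for stage '%s'; recomputing", stage)
      }
    }
  }
  res <- compute_stage(stage, config, up$result)
  if (!is.null(config$cache_dir)) {
    saveRDS(res, file.path(config$cache_dir, paste0(stage, ".rds")), version = 2)
    jsonlite::write_json(
      list(stage = stage, key = key, params = params,
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
           package_version = as.character(utils::packageVersion("shapegrade"))),
      file.path(config$cache_dir, paste0(stage, ".json")),
      auto_unbox = TRUE, null = "null", digits = NA)
  }
  list(result = res, key = key, hit = FALSE)
}
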