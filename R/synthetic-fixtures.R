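#' Synthetic study data
#'
#' Two generators make every pipeline stage testable without any external
#' data: (1) the sphere-dome interpolation series - linear interpolations S_t
#' between a sphere and the sphere with its upper dome mirrored at a cutting
#' plane, so that S_t and S_(1-t) are pairwise isometric but extrinsically
#' different; (2) a labeled two-class cohort of ellipsoidal blobs with
#' smooth per-subject spherical-harmonic noise, a class-dependent localized
#' deformation (`bump` = intrinsic+extrinsic atrophy, `bend` = near-isometric
#' mirrored-cap dent, mainly extrinsic), optional genus-1 handles emulating
#' segmentation artifacts, and class-correlated ApoE phenotypes.
#'
#' @name synthetic_fixtures
NULL

face_areas <- function(mesh) {
  cr <- face_corner_cross(mesh)
  sqrt(rowSums(cr^2)) / 2
}

#' Sphere-dome interpolation series
#'
#' S_0 is a unit latitude/longitude sphere with a vertex ring exactly at the
#' cutting plane z = `plane_height`; S_1 mirrors every vertex above the plane
#' (z -> 2c - z); S_t interpolates linearly with shared connectivity. Because
#' no edge crosses the plane, S_t and S_(1-t) have identical edge lengths
#' (pairwise isometric) while their extrinsic geometry differs; S_(1/2) is
#' flat on top.
#'
#' @param n_t number of interpolation values, uniform on \[0, 1\].
#' @param subdivisions resolution level; the sphere has 5 * 2^subdivisions
#'   latitude rings and 6 * 2^subdivisions longitudes.
#' @param plane_height cutting plane height c, strictly inside (0, 1).
#' @return object of class `sphere_dome_series`: `t_values`, `meshes`,
#'   `plane_height`.
#' @export
sphere_dome_series <- function(n_t = 9, subdivisions = 2, plane_height = 0.5) {
  if (n_t < 2) stopf("need n_t >= 2")
  if (plane_height <= 0 || plane_height >= 1)
    stopf("plane_height must lie strictly between 0 and the pole (1), got %g",
          plane_height)
  base <- mesh_uv_sphere(n_lat = 5 * 2^subdivisions, n_lon = 6 * 2^subdivisions,
                         ring_z = plane_height, subject_id = "S")
  z0 <- base$vertices[, 3]
  above <- z0 > plane_height + 1e-12
  z1 <- z0
  z1[above] <- 2 * plane_height - z0[above]
  tv <- seq(0, 1, length.out = n_t)
  meshes <- lapply(seq_along(tv), function(i) {
    m <- base
    m$vertices[, 3] <- (1 - tv[i]) * z0 + tv[i] * z1
    m$subject_id <- sprintf("S_t%.4f", tv[i])
    m
  })
  structure(list(t_values = tv, meshes = meshes, plane_height = plane_height),
            class = "sphere_dome_series")
}

# --- real spherical harmonics -------------------------------------------

# Orthonormal real spherical harmonics up to degree lmax at unit directions.
real_sph_harm <- function(dirs, lmax) {
  theta <- acos(pmin(pmax(dirs[, 3], -1), 1))
  phi <- atan2(dirs[, 2], dirs[, 1])
  ct <- cos(theta)
  out <- list()
  for (l in seq(2, lmax)) {
    P <- pracma::legendre(l, ct)  # (l+1) x n, rows m = 0..l, unnormalized
    for (m in 0:l) {
      nrm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - m) / factorial(l + m))
      if (m == 0) {
        out[[length(out) + 1L]] <- nrm * P[1, ]
      } else {
        out[[length(out) + 1L]] <- sqrt(2) * nrm * P[m + 1, ] * cos(m * phi)
        out[[length(out) + 1L]] <- sqrt(2) * nrm * P[m + 1, ] * sin(m * phi)
      }
    }
  }
  do.call(cbind, out)
}

# Smooth unit-variance random field on the sphere, band-limited to degrees
# 2..lmax (degree-0/1 terms would only rescale/translate the blob).
sh_noise_field <- function(sh_basis) {
  coef <- rnorm(ncol(sh_basis))
  f <- as.vector(sh_basis %*% coef)
  f / max(sd(f), 1e-12)
}

# --- deformations ---------------------------------------------------------

bump_weight <- function(dirs, axis = c(1, 0, 0), theta0 = pi / 3) {
  ang <- acos(pmin(pmax(dirs %*% axis, -1), 1))
  w <- numeric(length(ang))
  inside <- ang < theta0
  w[inside] <- cos(pi * ang[inside] / (2 * theta0))^2
  w
}

apply_bump <- function(vertices, w, amplitude) {
  vertices * (1 - amplitude * w)
}

# Amplitude such that the effect region (faces fully inside the cap) loses
# `effect_size` of its area. The response is not monotone on coarse meshes
# (a strongly contracted cap folds and regains area), so the smallest root is
# bracketed by a grid scan before the 1-d root search.
calibrate_bump_amplitude <- function(mesh, w, effect_size) {
  region <- which(rowSums(matrix(w[mesh$faces] > 0, ncol = 3)) == 3L)
  if (!length(region)) stopf("degenerate effect region (no faces in cap)")
  a0 <- sum(face_areas(mesh)[region])
  red <- function(a) {
    m2 <- mesh
    m2$vertices <- apply_bump(mesh$vertices, w, a)
    1 - sum(face_areas(m2)[region]) / a0 - effect_size
  }
  grid <- seq(0, 0.95, by = 0.01)
  vals <- vapply(grid, red, 0)
  hit <- which(vals >= 0)[1]
  if (is.na(hit))
    stopf("cannot realize an area reduction of %.2f in the effect region (max attainable %.2f)",
          effect_size, max(vals) + effect_size)
  if (vals[hit] == 0) return(grid[hit])
  stats::uniroot(red, c(grid[hit - 1L], grid[hit]), tol = 1e-8)$root
}

apply_cap_mirror <- function(vertices, plane_z) {
  above <- vertices[, 3] > plane_z
  vertices[above, 3] <- 2 * plane_z - vertices[above, 3]
  vertices
}

# --- genus-1 handle -------------------------------------------------------

oriented_ok <- function(faces) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  keyd <- paste(e[, 1], e[, 2])
  keyu <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  !any(duplicated(keyd)) && all(table(keyu) == 2L)
}

# Attach a thin handle by removing two vertex-disjoint faces near `axis` and
# stitching their boundary loops with a 6-triangle tube (no new vertices);
# raises the genus by one.
add_handle <- function(mesh, axis = c(0, 0, -1)) {
  f <- mesh$faces
  cent <- (mesh$vertices[f[, 1], ] + mesh$vertices[f[, 2], ] + mesh$vertices[f[, 3], ]) / 3
  score <- cent %*% axis / sqrt(rowSums(cent^2))
  i1 <- which.max(score)
  shared <- apply(f, 1, function(r) any(r %in% f[i1, ]))
  # second face: vertex-disjoint from the first, no shared neighbours
  nb <- unique(as.vector(f[apply(f, 1, function(r) any(r %in% f[i1, ])), ]))
  cand <- which(!shared & !apply(f, 1, function(r) any(r %in% nb)))
  if (!length(cand)) stopf("no candidate face for handle attachment")
  d <- rowSums((cent[cand, , drop = FALSE] -
                  matrix(cent[i1, ], length(cand), 3, byrow = TRUE))^2)
  i2 <- cand[which.min(d)]
  A <- f[i1, ]; B <- f[i2, ]
  tube <- function(a, b) rbind(
    c(a[1], a[2], b[2]), c(a[1], b[2], b[1]),
    c(a[2], a[3], b[3]), c(a[2], b[3], b[2]),
    c(a[3], a[1], b[1]), c(a[3], b[1], b[3]))
  rest <- f[-c(i1, i2), , drop = FALSE]
  for (rot in 0:2) for (ord in 1:2) {
    b <- B[(seq_len(3) + rot - 1L) %% 3L + 1L]
    if (ord == 2L) b <- rev(b)
    newf <- rbind(rest, tube(A, b))
    if (oriented_ok(newf)) {
      mesh$faces <- newf
      return(validate_mesh(mesh))
    }
  }
  stopf("could not stitch an orientation-consistent handle")
}

# --- cohort ---------------------------------------------------------------

#' Class-correlated synthetic phenotypes
#'
#' Sex uniform at random; ApoE drawn from class-conditional frequencies with
#' the E4 probability elevated in the diseased class by `association` (0 =
#' identical distributions, 1 = all diseased subjects E4). Baseline
#' frequencies (E2, E3, E4) = (0.10, 0.65, 0.25).
#'
#' @param labels character/factor class labels; the positive class is
#'   `positive_class`.
#' @param association E4 risk association in \[0, 1\] (default 0.5).
#' @param seed integer seed.
#' @param positive_class diseased label (default "AD").
#' @return data.frame with `subject_id`, `sex`, `apoe`, `label`.
#' @export
synthetic_phenotypes <- function(labels, association = 0.5, seed = 1L,
                                 positive_class = "AD") {
  stopifnot(association >= 0, association <= 1)
  set.seed(as.integer(seed))
  n <- length(labels)
  base <- c(E2 = 0.10, E3 = 0.65, E4 = 0.25)
  p4 <- base["E4"] + association * (1 - base["E4"])
  dis <- c(base[c("E2", "E3")] * (1 - p4) / (1 - base["E4"]), E4 = unname(p4))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  apoe <- character(n)
  for (i in seq_len(n)) {
    p <- if (as.character(labels[i]) == positive_class) dis else base
    apoe[i] <- sample(names(base), 1L, prob = p)
  }
  data.frame(subject_id = sprintf("subj%03d", seq_len(n)),
             sex = sex, apoe = apoe, label = as.character(labels),
             stringsAsFactors = FALSE)
}

#' Synthetic two-class cohort
#'
#' Per subject and side, an ellipsoidal blob with band-limited
#' spherical-harmonic radial noise; diseased subjects additionally receive a
#' localized deformation: `bump` contracts a cap around the +x axis so its
#' area shrinks by `effect_size` (intrinsic and extrinsic change), `bend`
#' mirrors the cap above the plane z/z_max = 1 - effect_size (a dent that
#' preserves edge lengths up to the noise, changing mainly extrinsic
#' geometry). A fraction of subjects gets a thin handle near -z (genus 1).
#' Regeneration with the same seed is bitwise identical.
#'
#' @param n number of subjects (>= 4).
#' @param effect_kind `"bump"` or `"bend"`.
#' @param effect_size nonnegative effect amplitude (area fraction; 0 = no
#'   class effect).
#' @param genus1_fraction fraction of subjects given a genus-1 handle.
#' @param sides `"right"`, `"left"`, or `"both"`.
#' @param seed integer master seed.
#' @param n_lat,n_lon blob resolution (default 20 x 24, 482 vertices).
#' @param noise_amplitude radial noise standard deviation (default 0.025).
#' @param noise_degree_max highest spherical-harmonic degree (default 6).
#' @param apoe_association passed to [synthetic_phenotypes].
#' @return object of class `synthetic_cohort`: `meshes` (list per subject of
#'   per-side meshes), `labels`, `phenotypes`, plus generation parameters.
#' @export
synthetic_cohort <- function(n = 60, effect_kind = c("bump", "bend"),
                             effect_size = 0.15, genus1_fraction = 0,
                             sides = c("right", "left", "both"), seed = 1L,
                             n_lat = 20, n_lon = 24,
                             noise_amplitude = 0.025, noise_degree_max = 6,
                             apoe_association = 0.5) {
  effect_kind <- match.arg(effect_kind)
  sides <- match.arg(sides)
  if (n < 4) stopf("need n >= 4 subjects")
  if (effect_size < 0) stopf("effect_size must be nonnegative")
  side_list <- if (sides == "both") c("right", "left") else sides
  axes <- list(right = c(1.0, 0.7, 0.55), left = c(1.05, 0.68, 0.57))

  labels <- rep(c("CN", "AD"), length.out = n)
  set.seed(as.integer(seed))
  subj_seeds <- sample.int(2^31 - 2, n)
  n_handle <- round(genus1_fraction * n)
  handle_subjects <- if (n_handle > 0) seq_len(n_handle) else integer(0)

  use_ring <- effect_kind == "bend" && effect_size > 0
  ring_z <- 1 - min(max(effect_size, 0), 0.8)  # bend cutting plane on the unit sphere
  base <- mesh_uv_sphere(n_lat = n_lat, n_lon = n_lon,
                         ring_z = if (use_ring) ring_z else NULL)
  dirs <- base$vertices
  # Vertices on the cutting plane: their height is pinned for every subject
  # (both classes, so the pin carries no label information); with the ring
  # fixed pointwise, the cap reflection preserves all edge lengths exactly.
  ring_idx <- if (use_ring) which(abs(dirs[, 3] - ring_z) < 1e-12) else integer(0)
  sh <- real_sph_harm(dirs, noise_degree_max)
  wb <- bump_weight(dirs, axis = c(1, 0, 0), theta0 = pi / 3)
  effect_vertices <- which(wb > 0)

  # per-side calibrated bump amplitude on the noise-free blob
  amp <- lapply(side_list, function(sd) {
    m <- base
    m$vertices <- sweep(dirs, 2, axes[[sd]], "*")
    if (effect_kind == "bump" && effect_size > 0)
      calibrate_bump_amplitude(m, wb, effect_size) else 0
  })
  names(amp) <- side_list

  meshes <- vector("list", n)
  for (i in seq_len(n)) {
    per_side <- list()
    for (sd in side_list) {
      sub_seed <- subj_seeds[i]
      repeat {
        set.seed(sub_seed)
        f <- sh_noise_field(sh)
        r <- 1 + noise_amplitude * f
        V <- sweep(r * dirs, 2, axes[[sd]], "*")
        if (length(ring_idx)) V[ring_idx, 3] <- axes[[sd]][3] * ring_z
        if (labels[i] == "AD" && effect_size > 0) {
          if (effect_kind == "bump") {
            V <- apply_bump(V, wb, amp[[sd]])
          } else {
            V <- apply_cap_mirror(V, axes[[sd]][3] * ring_z)
          }
        }
        m <- tryCatch({
          m0 <- triangle_mesh(V, base$faces,
                              subject_id = sprintf("subj%03d", i), side = sd)
          if (i %in% handle_subjects) m0 <- add_handle(m0)
          m0
        }, error = function(e) e)
        if (!inherits(m, "error")) break
        message(sprintf("subject %d (%s): degenerate after noise (%s); regenerating",
                        i, sd, conditionMessage(m)))
        sub_seed <- sub_seed + 1L
      }
      per_side[[sd]] <- m
    }
    meshes[[i]] <- per_side
  }
  names(meshes) <- sprintf("subj%03d", seq_len(n))
  phen <- synthetic_phenotypes(labels, association = apoe_association,
                               seed = subj_seeds[1] %% 1000003L)
  structure(list(meshes = meshes, labels = labels, phenotypes = phen,
                 effect_kind = effect_kind, effect_size = effect_size,
                 genus1_fraction = genus1_fraction, sides = side_list,
                 seed = seed, effect_vertices = effect_vertices,
                 handle_subjects = handle_subjects,
                 noise_amplitude = noise_amplitude),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects (%s), effect '%s' size %g, sides: %s, %d genus-1\n",
              length(x$meshes), paste(table(x$labels), collapse = "/"),
              x$effect_kind, x$effect_size, paste(x$sides, collapse = "+"),
              length(x$handle_subjects)))
  invisible(x)
}
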