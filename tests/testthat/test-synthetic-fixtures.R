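test_that("sphere-dome series realizes the mirrored-dome interpolation", {
  ser <- sphere_dome_series(n_t = 5, subdivisions = 1, plane_height = 0.5)
  expect_equal(ser$t_values, seq(0, 1, length.out = 5))
  # t = 0: the unit sphere
  r0 <- sqrt(rowSums(ser$meshes[[1]]$vertices^2))
  expect_lt(max(abs(r0 - 1)), 1e-9)
  # t = 1/2: flat at the top
  m_half <- ser$meshes[[3]]
  above <- ser$meshes[[1]]$vertices[, 3] > 0.5 + 1e-12
  expect_equal(max(m_half$vertices[above, 3]), 0.5, tolerance = 1e-12)
  expect_equal(min(m_half$vertices[above, 3]), 0.5, tolerance = 1e-12)
  # S_t and S_(1-t) are isometric: identical edge lengths, elementwise
  el <- function(m) isophotic_edge_lengths(m, omega = 0)$lengths
  expect_lt(max(abs(el(ser$meshes[[2]]) - el(ser$meshes[[4]]))), 1e-9)
  expect_lt(max(abs(el(ser$meshes[[1]]) - el(ser$meshes[[5]]))), 1e-9)
  # but the shapes differ extrinsically
  expect_gt(max(abs(ser$meshes[[2]]$vertices - ser$meshes[[4]]$vertices)), 0.1)
  expect_error(sphere_dome_series(plane_height = 1.2), "pole|between")
  expect_error(sphere_dome_series(n_t = 1), "n_t")
})

test_that("synthetic cohort is reproducible with balanced labels and requested genus", {
  coh1 <- synthetic_cohort(n = 8, effect_size = 0.15, genus1_fraction = 0.25, seed = 5)
  coh2 <- synthetic_cohort(n = 8, effect_size = 0.15, genus1_fraction = 0.25, seed = 5)
  expect_identical(coh1$meshes[["subj003"]]$right$vertices,
                   coh2$meshes[["subj003"]]$right$vertices)
  expect_identical(coh1$phenotypes, coh2$phenotypes)
  expect_lte(abs(sum(coh1$labels == "AD") - sum(coh1$labels == "CN")), 1)
  genera <- vapply(coh1$meshes, function(m) mesh_genus(m$right), 0L)
  expect_equal(sum(genera == 1L), 2L)  # round(0.25 * 8)
  expect_true(all(genera %in% c(0L, 1L)))
  # handles stay manifold and closed
  for (m in coh1$meshes) expect_true(mesh_is_closed(m$right))
})

test_that("bump effect shrinks the cap area by the requested fraction", {
  with_effect <- synthetic_cohort(n = 6, effect_kind = "bump", effect_size = 0.2, seed = 9)
  without <- synthetic_cohort(n = 6, effect_kind = "bump", effect_size = 0, seed = 9)
  wb <- shapegrade:::bump_weight(mesh_uv_sphere(20, 24)$vertices)
  region_area <- function(mesh) {
    inside <- which(rowSums(matrix(wb[mesh$faces] > 0, ncol = 3)) == 3L)
    sum(shapegrade:::face_areas(mesh)[inside])
  }
  red <- sapply(which(with_effect$labels == "AD"), function(i)
    1 - region_area(with_effect$meshes[[i]]$right) /
      region_area(without$meshes[[i]]$right))
  expect_equal(mean(red), 0.2, tolerance = 0.2)  # relative, within 20 percent
  # controls are untouched
  i_cn <- which(with_effect$labels == "CN")[1]
  expect_identical(with_effect$meshes[[i_cn]]$right$vertices,
                   without$meshes[[i_cn]]$right$vertices)
})

test_that("bend (mirrored cap) is near-isometric: edge lengths almost unchanged, geometry not", {
  # mechanism check on a single noisy blob: reflecting the cap above a vertex
  # ring preserves edge lengths up to the radial noise on the ring itself
  base <- mesh_uv_sphere(20, 24, ring_z = 0.85)
  sh <- shapegrade:::real_sph_harm(base$vertices, 6)
  set.seed(13)
  r <- 1 + 0.025 * shapegrade:::sh_noise_field(sh)
  axes <- c(1.0, 0.7, 0.55)
  flat <- base; flat$vertices <- sweep(r * base$vertices, 2, axes, "*")
  ring <- which(abs(base$vertices[, 3] - 0.85) < 1e-12)
  flat$vertices[ring, 3] <- axes[3] * 0.85  # pin the ring onto the plane
  bent <- flat
  bent$vertices <- shapegrade:::apply_cap_mirror(flat$vertices, axes[3] * 0.85)
  el <- function(m) isophotic_edge_lengths(m, omega = 0)$lengths
  rel <- abs(el(bent) - el(flat)) / el(flat)
  expect_lt(max(rel), 1e-12)            # exactly isometric with the pinned ring
  expect_gt(max(abs(bent$vertices - flat$vertices)), 0.02)  # extrinsically dented
  # the cohort generator applies it to diseased subjects only
  coh <- synthetic_cohort(n = 4, effect_kind = "bend", effect_size = 0.15, seed = 13)
  expect_equal(coh$effect_kind, "bend")
  expect_true(all(vapply(coh$meshes, function(m) mesh_is_closed(m$right), TRUE)))
})

test_that("phenotypes are class-correlated through ApoE", {
  labels <- rep(c("CN", "AD"), each = 200)
  ph0 <- synthetic_phenotypes(labels, association = 0, seed = 3)
  f0 <- tapply(ph0$apoe == "E4", ph0$label, mean)
  expect_lt(abs(f0["AD"] - f0["CN"]), 0.12)  # within binomial noise
  ph1 <- synthetic_phenotypes(labels, association = 1, seed = 3)
  expect_true(all(ph1$apoe[ph1$label == "AD"] == "E4"))
  ph <- synthetic_phenotypes(labels, association = 0.5, seed = 3)
  f <- tapply(ph$apoe == "E4", ph$label, mean)
  expect_gt(f["AD"], f["CN"] + 0.2)
  expect_identical(ph, synthetic_phenotypes(labels, association = 0.5, seed = 3))
  expect_true(all(ph$sex %in% c("F", "M")))
})

test_that("both sides are generated when requested", {
  coh <- synthetic_cohort(n = 4, sides = "both", seed = 2)
  expect_equal(coh$sides, c("right", "left"))
  m <- coh$meshes[[1]]
  expect_named(m, c("right", "left"))
  expect_false(identical(m$right$vertices, m$left$vertices))
})
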