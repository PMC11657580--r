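#' Primitive meshes
#'
#' Programmatic fixture meshes: tetrahedron, icosphere (subdivided
#' icosahedron projected to the unit sphere), latitude/longitude sphere
#' (optionally with a vertex ring at a prescribed height), torus, and planar
#' grid. All are generated in code; none are shipped as data files.
#'
#' @name primitives
NULL

#' @rdname primitives
#' @param subject_id,side metadata passed to [triangle_mesh].
#' @export
mesh_tetrahedron <- function(subject_id = "tetra", side = "none") {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  triangle_mesh(v, f, subject_id = subject_id, side = side)
}

#' @rdname primitives
#' @param subdivisions number of 4-to-1 triangle subdivisions of the
#'   icosahedron (0 gives 12 vertices; 3 gives 642).
#' @export
mesh_icosphere <- function(subdivisions = 2, subject_id = "icosphere", side = "none") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      p <- (vlist[[a]] + vlist[[b]]) / 2
      p <- p / sqrt(sum(p^2))
      vlist[[length(vlist) + 1L]] <<- p
      idx <- length(vlist)
      midcache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  triangle_mesh(v, f, subject_id = subject_id, side = side)
}

#' @rdname primitives
#' @param n_lat number of latitude rings strictly between the poles.
#' @param n_lon number of longitudes.
#' @param ring_z optional height in (-1, 1); one latitude ring is placed
#'   exactly at this z so that a cutting plane there crosses no edge.
#' @export
mesh_uv_sphere <- function(n_lat = 20, n_lon = 24, ring_z = NULL,
                           subject_id = "uvsphere", side = "none") {
  if (n_lat < 2 || n_lon < 3) stopf("need n_lat >= 2 and n_lon >= 3")
  thetas <- seq(0, pi, length.out = n_lat + 2)[2:(n_lat + 1)]  # from north pole
  if (!is.null(ring_z)) {
    if (abs(ring_z) >= 1) stopf("ring_z must lie strictly inside (-1, 1)")
    target <- acos(ring_z)
    thetas[which.min(abs(thetas - target))] <- target
  }
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[seq_len(n_lon)]
  v <- rbind(c(0, 0, 1))
  for (th in thetas)
    v <- rbind(v, cbind(sin(th) * cos(lon), sin(th) * sin(lon), cos(th)))
  v <- rbind(v, c(0, 0, -1))
  np <- 1L; sp <- nrow(v)
  ring <- function(r) 1L + (r - 1L) * n_lon + seq_len(n_lon)  # r in 1..n_lat
  f <- matrix(0L, 0, 3)
  r1 <- ring(1)
  f <- rbind(f, cbind(np, r1, c(r1[-1], r1[1])))
  for (r in seq_len(n_lat - 1)) {
    a <- ring(r); b <- ring(r + 1)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    f <- rbind(f, cbind(a, b, b2), cbind(a, b2, a2))
  }
  rl <- ring(n_lat)
  f <- rbind(f, cbind(sp, c(rl[-1], rl[1]), rl))
  triangle_mesh(v, f, subject_id = subject_id, side = side)
}

#' @rdname primitives
#' @param R,r major and minor torus radii.
#' @param n_major,n_minor grid resolution around the two circles.
#' @export
mesh_torus <- function(R = 1, r = 0.4, n_major = 24, n_minor = 12,
                       subject_id = "torus", side = "none") {
  u <- seq(0, 2 * pi, length.out = n_major + 1)[seq_len(n_major)]
  w <- seq(0, 2 * pi, length.out = n_minor + 1)[seq_len(n_minor)]
  g <- expand.grid(w = w, u = u)
  v <- cbind((R + r * cos(g$w)) * cos(g$u),
             (R + r * cos(g$w)) * sin(g$u),
             r * sin(g$w))
  idx <- function(i, j) ((i - 1L) %% n_major) * n_minor + ((j - 1L) %% n_minor) + 1L
  f <- matrix(0L, 0, 3)
  for (i in seq_len(n_major)) for (j in seq_len(n_minor)) {
    a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    f <- rbind(f, c(a, b, c), c(a, c, d))
  }
  triangle_mesh(v, f, subject_id = subject_id, side = side)
}

#' @rdname primitives
#' @param nx,ny grid vertices along x and y.
#' @param lx,ly grid extents.
#' @export
mesh_planar_grid <- function(nx = 8, ny = 8, lx = 1, ly = 1,
                             subject_id = "grid", side = "none") {
  xs <- seq(0, lx, length.out = nx); ys <- seq(0, ly, length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  v <- cbind(g$x, g$y, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  f <- matrix(0L, 0, 3)
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    f <- rbind(f, c(a, b, c), c(a, c, d))
  }
  suppressWarnings(triangle_mesh(v, f, subject_id = subject_id, side = side))
}
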