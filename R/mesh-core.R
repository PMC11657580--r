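#' Triangle surface meshes
#'
#' A `triangle_mesh` holds the vertices and faces of an (ideally closed,
#' orientable) triangle surface, plus subject metadata. Vertex indices are
#' 1-based internally; on-disk conventions (0-based OFF/PLY, 1-based OBJ) are
#' converted at the I/O boundary.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z.
#' @param faces integer matrix, one row per face, three 1-based vertex
#'   indices in counterclockwise order.
#' @param subject_id character scalar identifying the subject.
#' @param side one of `"left"`, `"right"`, `"none"`.
#' @param validate validate manifoldness and face indices (default `TRUE`).
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `subject_id`, `side`.
#' @examples
#' m <- triangle_mesh(
#'   vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   faces = rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
#' )
#' mesh_genus(m)  # tetrahedron: genus 0
#' @export
triangle_mesh <- function(vertices, faces, subject_id = "unnamed",
                          side = c("none", "left", "right"),
                          validate = TRUE) {
  side <- match.arg(side)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (length(faces)) {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
  } else {
    faces <- matrix(integer(0), 0, 3)
  }
  if (ncol(vertices) != 3L) stopf("vertices must have 3 columns, got %d", ncol(vertices))
  if (ncol(faces) != 3L) stopf("faces must have 3 columns, got %d", ncol(faces))
  m <- structure(list(vertices = vertices, faces = faces,
                      subject_id = as.character(subject_id), side = side),
                 class = "triangle_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cl <- mesh_is_closed(x)
  cat(sprintf("triangle_mesh '%s' (%s): %d vertices, %d faces, %s, genus %s\n",
              x$subject_id, x$side, nrow(x$vertices), nrow(x$faces),
              if (cl) "closed" else "open",
              if (cl) mesh_genus(x) else "undefined"))
  invisible(x)
}

# Undirected edge table: one row per unique edge, columns (i, j) with i < j,
# plus the number of incident faces.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE],
             f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  uniq <- !duplicated(key)
  cnt <- as.integer(tab[key[uniq]])
  cbind(e[uniq, , drop = FALSE], count = cnt)
}

#' Validate a triangle mesh
#'
#' Checks face indices, degenerate faces, and edge-manifoldness (each
#' undirected edge borders at most two faces). Non-closed meshes pass with a
#' warning; genus is only defined for closed meshes.
#'
#' @param mesh a [triangle_mesh].
#' @return the mesh, invisibly.
#' @export
validate_mesh <- function(mesh) {
  V <- nrow(mesh$vertices)
  f <- mesh$faces
  if (V == 0L) stopf("mesh has no vertices")
  if (nrow(f)) {
    if (min(f) < 1L || max(f) > V)
      stopf("face indices out of range [1, %d]", V)
    dg <- which(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])
    if (length(dg))
      stopf("degenerate faces with repeated vertices: %s",
            paste(head(dg, 5), collapse = ", "))
    e <- mesh_edges(mesh)
    bad <- which(e[, 3] > 2L)
    if (length(bad))
      stopf("non-manifold edges (more than 2 incident faces): %s",
            paste(apply(e[head(bad, 5), 1:2, drop = FALSE], 1,
                        paste, collapse = "-"), collapse = ", "))
    if (any(e[, 3] < 2L))
      warnf("mesh '%s' is not closed (%d boundary edges); genus undefined",
            mesh$subject_id, sum(e[, 3] < 2L))
  }
  invisible(mesh)
}

#' @rdname mesh_genus
#' @export
mesh_is_closed <- function(mesh) {
  if (!nrow(mesh$faces)) return(FALSE)
  all(mesh_edges(mesh)[, 3] == 2L)
}

#' Euler characteristic and genus
#'
#' `mesh_euler()` returns chi = V - E + F; `mesh_genus()` returns
#' `(2 - chi) / 2` for closed meshes and `NA` (with a warning) otherwise.
#'
#' @param mesh a [triangle_mesh].
#' @return integer Euler characteristic, or genus.
#' @export
mesh_euler <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' @rdname mesh_genus
#' @export
mesh_genus <- function(mesh) {
  if (!mesh_is_closed(mesh)) {
    warnf("mesh '%s' is not closed; genus undefined", mesh$subject_id)
    return(NA_integer_)
  }
  chi <- mesh_euler(mesh)
  if (chi %% 2L != 0L) stopf("odd Euler characteristic %d on a closed mesh", chi)
  as.integer((2L - chi) / 2L)
}

#' Bounding box diagonal length
#'
#' Euclidean length of the diagonal of the axis-aligned bounding box; this is
#' the length scale used to express the metric blending weight as
#' omega = alpha * ell^2.
#'
#' @param mesh a [triangle_mesh].
#' @return positive scalar (0 for a single vertex).
#' @export
bounding_box_diagonal <- function(mesh) {
  if (nrow(mesh$vertices) == 0L) stopf("empty mesh")
  rng <- apply(mesh$vertices, 2, range)
  sqrt(sum((rng[2, ] - rng[1, ])^2))
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("off", "ply", "obj"))
    stopf("cannot infer mesh format from extension '%s'", ext)
  ext
}

#' Read a triangle mesh from OFF, PLY or OBJ
#'
#' Supports ASCII OFF, ASCII and binary little-endian PLY (float or double
#' vertex properties), and OBJ geometry (`v`/`f` records; materials, normals
#' and texture indices are ignored). Vertex order is preserved.
#'
#' @param path file path.
#' @param format `"off"`, `"ply"`, `"obj"`, or `"auto"` (from extension).
#' @param subject_id,side metadata attached to the mesh; `subject_id`
#'   defaults to the file base name.
#' @return a validated [triangle_mesh].
#' @export
read_mesh <- function(path, format = c("auto", "off", "ply", "obj"),
                      subject_id = NULL, side = "none") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") format <- guess_format(path)
  if (is.null(subject_id)) subject_id <- tools::file_path_sans_ext(basename(path))
  m <- switch(format,
              off = read_off(path),
              ply = read_ply(path),
              obj = read_obj(path))
  triangle_mesh(m$vertices, m$faces, subject_id = subject_id, side = side)
}

strip_tokens <- function(lines) {
  lines <- sub("#.*", "", lines)
  lines[nzchar(trimws(lines))]
}

read_off <- function(path) {
  lines <- strip_tokens(readLines(path, warn = FALSE))
  if (!length(lines) || toupper(trimws(lines[1])) != "OFF")
    stopf("%s: not an OFF file (missing header)", path)
  counts <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]]))
  if (length(counts) < 2L || anyNA(counts[1:2]))
    stopf("%s: malformed OFF count line (line 2)", path)
  nv <- counts[1]; nf <- counts[2]
  body <- lines[-(1:2)]
  if (length(body) < nv + nf)
    stopf("%s: OFF file truncated (%d records, need %d)", path, length(body), nv + nf)
  vtx <- do.call(rbind, lapply(seq_len(nv), function(i) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]][1:3]))
    if (anyNA(x)) stopf("%s: bad vertex record at line %d", path, i + 2L)
    x
  }))
  fac <- do.call(rbind, lapply(seq_len(nf), function(i) {
    x <- suppressWarnings(as.integer(strsplit(trimws(body[nv + i]), "\\s+")[[1]]))
    if (anyNA(x[1]) || x[1] != 3L || length(x) < 4L)
      stopf("%s: non-triangular or bad face record at line %d", path, nv + i + 2L)
    x[2:4] + 1L
  }))
  list(vertices = vtx, faces = fac)
}

read_obj <- function(path) {
  lines <- strip_tokens(readLines(path, warn = FALSE))
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl)) stopf("%s: no vertex records in OBJ", path)
  vtx <- do.call(rbind, lapply(vl, function(s) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(s), "\\s+")[[1]][2:4]))
    if (anyNA(x)) stopf("%s: bad OBJ vertex record: %s", path, s)
    x
  }))
  fac <- do.call(rbind, lapply(fl, function(s) {
    tok <- strsplit(trimws(s), "\\s+")[[1]][-1]
    idx <- suppressWarnings(as.integer(sub("/.*", "", tok)))
    if (anyNA(idx) || length(idx) != 3L)
      stopf("%s: non-triangular or bad OBJ face record: %s", path, s)
    idx
  }))
  list(vertices = vtx, faces = fac)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stopf("%s: PLY header not terminated", path)
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  if (!length(header) || trimws(header[1]) != "ply") stopf("%s: not a PLY file", path)
  fmt_line <- grep("^format", trimws(header), value = TRUE)
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stopf("%s: unsupported PLY format '%s'", path, fmt)

  elems <- list(); cur <- NULL
  for (ln in trimws(header)) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(n = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props[[length(elems[[cur]]$props) + 1L]] <- tok[-1]
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stopf("%s: PLY lacks vertex or face element", path)
  nv <- elems$vertex$n; nf <- elems$face$n
  vprops <- elems$vertex$props
  vtypes <- vapply(vprops, `[`, "", 1L)
  vnames <- vapply(vprops, function(p) p[length(p)], "")
  xyz <- match(c("x", "y", "z"), vnames)
  if (anyNA(xyz)) stopf("%s: PLY vertex element lacks x/y/z", path)

  ply_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  read_scalar <- function(type, n = 1L) {
    sz <- ply_size[[type]]
    if (is.null(sz)) stopf("%s: unknown PLY type '%s'", path, type)
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", n = n, size = sz, endian = "little")
    else
      readBin(con, "integer", n = n, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }

  if (fmt == "ascii") {
    body <- strip_tokens(readLines(con, warn = FALSE))
    if (length(body) < nv + nf) stopf("%s: PLY body truncated", path)
    vtx <- do.call(rbind, lapply(seq_len(nv), function(i) {
      x <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
      if (anyNA(x[xyz])) stopf("%s: bad PLY vertex at record %d", path, i)
      x[xyz]
    }))
    fac <- do.call(rbind, lapply(seq_len(nf), function(i) {
      x <- suppressWarnings(as.integer(strsplit(trimws(body[nv + i]), "\\s+")[[1]]))
      if (x[1] != 3L) stopf("%s: non-triangular PLY face at record %d", path, i)
      x[2:4] + 1L
    }))
  } else {
    vtx <- matrix(0, nv, 3)
    for (i in seq_len(nv)) {
      row <- numeric(length(vtypes))
      for (j in seq_along(vtypes)) row[j] <- read_scalar(vtypes[j])
      vtx[i, ] <- row[xyz]
    }
    fp <- elems$face$props[[1]]
    if (fp[1] != "list") stopf("%s: PLY face property is not a list", path)
    fac <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- read_scalar(fp[2])
      if (cnt != 3L) stopf("%s: non-triangular PLY face at record %d", path, i)
      fac[i, ] <- read_scalar(fp[3], 3L) + 1L
    }
  }
  list(vertices = vtx, faces = fac)
}

#' Write a triangle mesh
#'
#' @param mesh a [triangle_mesh].
#' @param path output file path.
#' @param format `"off"`, `"ply"`, `"obj"`, or `"auto"` (from extension).
#' @param binary for PLY: write binary little-endian with `float64` vertex
#'   coordinates (lossless round trip); ignored otherwise.
#' @param digits significant digits for ASCII output (default 17, lossless
#'   for doubles).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "off", "ply", "obj"),
                       binary = FALSE, digits = 17) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (nrow(mesh$vertices) == 0L) stopf("refusing to write an empty mesh")
  V <- mesh$vertices; f <- mesh$faces
  num <- function(M) apply(M, 1, function(r) paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  ok <- tryCatch({
    if (format == "off") {
      writeLines(c("OFF", sprintf("%d %d 0", nrow(V), nrow(f)), num(V),
                   sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)), path)
    } else if (format == "obj") {
      writeLines(c(sprintf("v %s", num(V)),
                   sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
    } else {
      hdr <- c("ply",
               sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
               sprintf("element vertex %d", nrow(V)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header")
      if (binary) {
        con <- file(path, "wb")
        on.exit(close(con), add = TRUE)
        writeLines(hdr, con)
        for (i in seq_len(nrow(V)))
          writeBin(as.double(V[i, ]), con, size = 8, endian = "little")
        for (i in seq_len(nrow(f))) {
          writeBin(as.raw(3L), con)
          writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
        }
      } else {
        writeLines(c(hdr, num(V),
                     sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)), path)
      }
    }
    TRUE
  }, error = function(e) stopf("cannot write %s: %s", path, conditionMessage(e)))
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with header `subject_id,side,sex,apoe,label`; `sex` in F/M, `apoe` in
#' E2/E3/E4, `label` in CN/AD (extensible: other label levels are kept).
#'
#' @param path CSV file path.
#' @return data.frame with character columns.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("subject_id", "side", "sex", "apoe", "label")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stopf("phenotype table lacks columns: %s", paste(miss, collapse = ", "))
  bad <- setdiff(unique(ph$sex), c("F", "M"))
  if (length(bad)) stopf("unknown sex levels: %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(ph$apoe), c("E2", "E3", "E4"))
  if (length(bad)) stopf("unknown ApoE levels: %s", paste(bad, collapse = ", "))
  ph
}
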