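#' Read a triangle mesh from STL, PLY or OBJ
#'
#' STL (both binary and ASCII dialects), ASCII PLY and Wavefront OBJ are
#' supported; format is inferred from the extension (or content, for the
#' two STL dialects) unless given. STL files carry no shared-vertex
#' topology, so duplicate vertices are merged by exact coordinate match
#' (no tolerance welding, for determinism); face winding is preserved
#' from the file.
#'
#' @param path file path.
#' @param format `"auto"`, `"stl"`, `"ply"` or `"obj"`.
#' @param name mesh label; defaults to the file name.
#' @return A [trimesh()].
#' @export
load_mesh <- function(path, format = c("auto", "stl", "ply", "obj"),
                      name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read mesh file '%s'", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", ply = "ply", obj = "obj",
                     stop(sprintf("cannot infer mesh format from '%s'", path)))
  }
  name <- name %||% basename(path)
  mesh <- switch(format,
                 stl = read_stl(path, name),
                 ply = read_ply(path, name),
                 obj = read_obj(path, name))
  if (nrow(mesh$faces) == 0) stop(sprintf("empty mesh in '%s'", path))
  mesh
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' Binary STL stores float32 coordinates; ASCII PLY and OBJ are written at
#' full double precision (17 significant digits), so PLY round-trips are
#' exact.
#'
#' @param mesh a [trimesh()].
#' @param path output path.
#' @param format one of `"stl_binary"`, `"stl_ascii"`, `"ply"`, `"obj"`;
#'   inferred from the extension when `"auto"` (STL defaults to binary).
#' @param scalar optional per-vertex numeric attached to PLY output as a
#'   `quality` property (used to export distance maps).
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path,
                      format = c("auto", "stl_binary", "stl_ascii",
                                 "ply", "obj"),
                      scalar = NULL) {
  stopifnot(inherits(mesh, "trimesh"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl_binary", ply = "ply", obj = "obj",
                     stop(sprintf("cannot infer mesh format from '%s'", path)))
  }
  switch(format,
         stl_binary = write_stl_binary(mesh, path),
         stl_ascii = write_stl_ascii(mesh, path),
         ply = write_ply(mesh, path, scalar),
         obj = write_obj(mesh, path))
  invisible(path)
}

# ---- STL ----

# exact-match vertex merging (per-triangle soup -> indexed mesh)
soup_to_mesh <- function(tri_vertices, name) {
  key <- sprintf("%.17g|%.17g|%.17g",
                 tri_vertices[, 1], tri_vertices[, 2], tri_vertices[, 3])
  idx <- match(key, key)           # first occurrence per unique vertex
  uniq <- sort(unique(idx))
  remap <- integer(nrow(tri_vertices))
  remap[uniq] <- seq_along(uniq)
  v <- tri_vertices[uniq, , drop = FALSE]
  f <- matrix(remap[idx], ncol = 3, byrow = TRUE)
  trimesh(v, f, name)
}

is_binary_stl <- function(path) {
  size <- file.info(path)$size
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  identical(size, 84 + 50 * as.numeric(n))
}

read_stl <- function(path, name) {
  if (is_binary_stl(path)) read_stl_binary(path, name)
  else read_stl_ascii(path, name)
}

read_stl_binary <- function(path, name) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (n < 1) stop(sprintf("empty mesh in '%s'", path))
  raw <- readBin(con, "raw", 50 * n)
  rec <- matrix(raw, nrow = 50)
  fl <- matrix(readBin(as.vector(rec[1:48, ]), "numeric", size = 4,
                       n = 12L * n, endian = "little"),
               nrow = 12)
  # rows 4..12 of each record are the three vertices (1..3 the stored normal)
  tri <- t(fl[4:12, , drop = FALSE])
  tv <- matrix(NA_real_, 3 * n, 3)
  tv[seq(1, 3 * n, by = 3), ] <- tri[, 1:3, drop = FALSE]
  tv[seq(2, 3 * n, by = 3), ] <- tri[, 4:6, drop = FALSE]
  tv[seq(3, 3 * n, by = 3), ] <- tri[, 7:9, drop = FALSE]
  soup_to_mesh(tv, name)
}

read_stl_ascii <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop(sprintf("malformed ASCII STL '%s'", path))
  parts <- strsplit(trimws(vl), "\\s+")
  tv <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(tv))) stop(sprintf("non-numeric vertex in '%s'", path))
  soup_to_mesh(tv, name)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  n <- nrow(mesh$faces)
  writeBin(as.integer(n), con, size = 4, endian = "little")
  nrm <- face_normals(mesh)
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  block <- t(cbind(nrm, v1, v2, v3))  # 12 floats per face
  fraw <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
  fm <- matrix(fraw, nrow = 48)
  out <- rbind(fm, matrix(as.raw(0), 2, n))  # attribute byte count = 0
  writeBin(as.vector(out), con)
}

write_stl_ascii <- function(mesh, path) {
  nrm <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  fmt <- paste0(
    " facet normal %.9g %.9g %.9g\n  outer loop\n",
    "   vertex %.9g %.9g %.9g\n   vertex %.9g %.9g %.9g\n",
    "   vertex %.9g %.9g %.9g\n  endloop\n endfacet")
  body <- sprintf(fmt, nrm[, 1], nrm[, 2], nrm[, 3],
                  v[f[, 1], 1], v[f[, 1], 2], v[f[, 1], 3],
                  v[f[, 2], 1], v[f[, 2], 2], v[f[, 2], 3],
                  v[f[, 3], 1], v[f[, 3], 2], v[f[, 3], 3])
  writeLines(c(sprintf("solid %s", mesh$name), body,
               sprintf("endsolid %s", mesh$name)), path)
}

# ---- PLY (ASCII) ----

read_ply <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop(sprintf("not a PLY file: '%s'", path))
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop(sprintf("PLY header not terminated in '%s'", path))
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", header)))
    stop(sprintf("only ASCII PLY is supported: '%s'", path))
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop(sprintf("bad PLY header in '%s'", path))
  vlines <- lines[endh + seq_len(nv)]
  flines <- lines[endh + nv + seq_len(nf)]
  vp <- strsplit(trimws(vlines), "\\s+")
  v <- t(vapply(vp, function(p) as.numeric(p[1:3]), numeric(3)))
  fp <- strsplit(trimws(flines), "\\s+")
  f <- t(vapply(fp, function(p) {
    k <- as.integer(p[1])
    if (k != 3) stop("only triangle PLY faces are supported")
    as.integer(p[2:4])
  }, integer(3))) + 1L
  trimesh(v, f, name)
}

write_ply <- function(mesh, path, scalar = NULL) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  if (!is.null(scalar) && length(scalar) != nv)
    stop("scalar must have one value per vertex")
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nv),
              "property double x", "property double y", "property double z",
              if (!is.null(scalar)) "property double quality",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  v <- mesh$vertices
  vtxt <- if (is.null(scalar))
    sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
  else
    sprintf("%.17g %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3], scalar)
  f0 <- mesh$faces - 1L
  ftxt <- sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3])
  writeLines(c(header, vtxt, ftxt), path)
}

# ---- OBJ ----

read_obj <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0)
    stop(sprintf("no geometry in OBJ '%s'", path))
  vp <- strsplit(trimws(vl), "\\s+")
  v <- t(vapply(vp, function(p) as.numeric(p[2:4]), numeric(3)))
  fp <- strsplit(trimws(fl), "\\s+")
  f <- t(vapply(fp, function(p) {
    if (length(p) != 4) stop("only triangle OBJ faces are supported")
    as.integer(sub("/.*$", "", p[2:4]))
  }, integer(3)))
  trimesh(v, f, name)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(sprintf("o %s", mesh$name),
               sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
}
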