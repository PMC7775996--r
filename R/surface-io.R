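#' Surface mesh objects
#'
#' A `surface_mesh` is a triangulated cortical sheet: an `n x 3` matrix of
#' vertex coordinates in world millimetres (RAS frame) and an `m x 3` matrix
#' of 1-based triangle vertex indices, plus a free-text hemisphere label.
#' White and pial surfaces of one subject (and of all subjects in a
#' template-based analysis) share the triangulation, so vertices correspond
#' across surfaces by index.
#'
#' @param vertices numeric matrix, `n x 3`, world coordinates in mm.
#' @param faces integer matrix, `m x 3`, 1-based vertex indices.
#' @param hemisphere text tag, e.g. `"lh"`, `"rh"` or `"synthetic"`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, hemisphere = "unknown") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop_fmt("geometry_error", "vertices must be n x 3")
  if (ncol(faces) != 3L) stop_fmt("geometry_error", "faces must be m x 3")
  n <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > n)
      stop_fmt("geometry_error",
               "face indices out of range [1, %d]", n)
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
      faces[, 2] == faces[, 3]
    if (any(degen))
      stop_fmt("geometry_error", "%d degenerate triangle(s)", sum(degen))
  }
  structure(list(vertices = vertices, faces = faces,
                 hemisphere = hemisphere),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, hemisphere '%s'\n",
              nrow(x$vertices), nrow(x$faces), x$hemisphere))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Vertex adjacency of a surface mesh
#'
#' Undirected vertex adjacency derived from the triangle edges, as a list of
#' integer neighbour vectors (1-based). Isolated vertices get an empty
#' vector.
#'
#' @param mesh a `surface_mesh`.
#' @return list of integer vectors, one per vertex.
#' @export
mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  adj <- split(e[, 2], factor(e[, 1], levels = seq_len(n_vertices(mesh))))
  lapply(adj, function(v) sort(unique(v)))
}

# Sparse symmetric edge incidence (i, j, one row per undirected edge, i < j)
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# FreeSurfer binary triangle-surface magic: 0xFF 0xFF 0xFE
FS_TRIANGLE_MAGIC <- as.raw(c(0xff, 0xff, 0xfe))

#' Read a FreeSurfer binary surface
#'
#' Reads the FreeSurfer big-endian binary triangle-surface format (the
#' format of `lh.white`, `lh.pial`, ...). Face indices are converted to
#' 1-based.
#'
#' @param path file path.
#' @param hemisphere hemisphere tag stored on the mesh; guessed from the
#'   file name (`lh.`/`rh.` prefix) when `NULL`.
#' @return a [surface_mesh()].
#' @export
read_surface <- function(path, hemisphere = NULL) {
  if (!file.exists(path))
    stop_fmt("io_error", "surface file does not exist: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3L)
  if (length(magic) < 3L || !identical(magic, FS_TRIANGLE_MAGIC))
    stop_fmt("format_error",
             "unsupported surface format (magic %s at offset 0): %s",
             paste(as.character(magic), collapse = " "), path)
  # comment line terminated by "\n\n"
  cmt <- raw(0)
  prev_nl <- FALSE
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L)
      stop_fmt("format_error",
               "truncated surface header (EOF at offset %d): %s",
               3L + length(cmt), path)
    if (b == as.raw(0x0a)) {
      if (prev_nl) break
      prev_nl <- TRUE
    } else prev_nl <- FALSE
    cmt <- c(cmt, b)
  }
  counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  if (length(counts) < 2L || any(counts < 0L))
    stop_fmt("format_error", "truncated surface counts: %s", path)
  nv <- counts[1]; nf <- counts[2]
  xyz <- readBin(con, "numeric", n = 3L * nv, size = 4L, endian = "big")
  if (length(xyz) < 3L * nv)
    stop_fmt("format_error",
             "truncated vertex block (got %d of %d floats): %s",
             length(xyz), 3L * nv, path)
  tri <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(tri) < 3L * nf)
    stop_fmt("format_error",
             "truncated face block (got %d of %d ints): %s",
             length(tri), 3L * nf, path)
  if (is.null(hemisphere)) {
    bn <- basename(path)
    hemisphere <- if (grepl("^lh\\.", bn)) "lh"
    else if (grepl("^rh\\.", bn)) "rh" else "unknown"
  }
  surface_mesh(matrix(xyz, ncol = 3L, byrow = TRUE),
               matrix(tri, ncol = 3L, byrow = TRUE) + 1L,
               hemisphere = hemisphere)
}

#' Write a FreeSurfer binary surface
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param comment header comment line.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path,
                          comment = "created by boundaryprofile") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FS_TRIANGLE_MAGIC, con)
  writeBin(c(charToRaw(comment), as.raw(c(0x0a, 0x0a))), con)
  writeBin(as.integer(c(nrow(mesh$vertices), nrow(mesh$faces))), con,
           size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}
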