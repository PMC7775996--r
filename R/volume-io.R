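#' Volume image objects
#'
#' A `volume_image` is a 3D scalar grid plus an invertible 4x4 voxel-to-world
#' affine (mm, RAS). Voxel indices are 0-based in the affine convention:
#' world = affine %*% c(i, j, k, 1) for 0-based (i, j, k).
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, affine = diag(4)) {
  data <- as.array(data)
  if (length(dim(data)) == 4L && dim(data)[4] == 1L)
    data <- array(data, dim(data)[1:3])
  if (length(dim(data)) != 3L)
    stop_fmt("format_error", "volume data must be a 3D array")
  if (any(dim(data) < 2L))
    stop_fmt("geometry_error",
             "volume must have >= 2 voxels along every axis (got %s)",
             paste(dim(data), collapse = "x"))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop_fmt("geometry_error", "affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop_fmt("geometry_error", "affine is not invertible")
  structure(list(data = data, affine = affine), class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("volume_image: %s voxels, spacing ~%s mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(sqrt(colSums(x$affine[1:3, 1:3]^2)), 3),
                    collapse = " x ")))
  invisible(x)
}

#' Map world coordinates to (0-based) voxel coordinates
#'
#' @param volume a [volume_image()].
#' @param points `n x 3` matrix of world mm coordinates.
#' @return `n x 3` matrix of continuous 0-based voxel coordinates.
#' @export
world_to_voxel <- function(volume, points) {
  points <- rbind_points(points)
  inv <- solve(volume$affine)
  p1 <- cbind(points, 1)
  out <- p1 %*% t(inv)
  out[, 1:3, drop = FALSE]
}

#' Map (0-based) voxel coordinates to world coordinates
#'
#' @inheritParams world_to_voxel
#' @param voxels `n x 3` matrix of 0-based voxel coordinates.
#' @export
voxel_to_world <- function(volume, voxels) {
  voxels <- rbind_points(voxels)
  out <- cbind(voxels, 1) %*% t(volume$affine)
  out[, 1:3, drop = FALSE]
}

rbind_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  as.matrix(points)
}

MGH_HEADER_BYTES <- 284L

#' Read an MGH/MGZ or NIfTI volume
#'
#' Dispatches on the file extension: `.mgh`/`.mgz` are read with the
#' built-in big-endian MGH reader, `.nii`/`.nii.gz` through RNifti. The
#' returned affine maps 0-based voxel indices to world RAS mm.
#'
#' @param path file path.
#' @return a [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop_fmt("io_error", "volume file does not exist: %s", path)
  if (grepl("\\.mgh$|\\.mgz$", path)) {
    read_mgh(path)
  } else if (grepl("\\.nii$|\\.nii\\.gz$", path)) {
    img <- RNifti::readNifti(path)
    aff <- structure(RNifti::xform(img), dimnames = NULL)
    volume_image(as.array(img), matrix(aff, 4, 4))
  } else {
    stop_fmt("format_error", "unsupported volume format: %s", path)
  }
}

read_mgh <- function(path) {
  con <- if (grepl("\\.mgz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 7L, size = 4L, endian = "big")
  if (length(hdr) < 7L)
    stop_fmt("format_error", "truncated MGH header (offset 0): %s", path)
  version <- hdr[1]
  if (version != 1L)
    stop_fmt("format_error", "unsupported MGH version %d: %s", version, path)
  dims <- hdr[2:4]; nframes <- hdr[5]; dtype <- hdr[6]
  good_ras <- readBin(con, "integer", n = 1L, size = 2L, endian = "big")
  affine <- diag(4)
  if (isTRUE(good_ras == 1L)) {
    geom <- readBin(con, "numeric", n = 15L, size = 4L, endian = "big")
    spacing <- geom[1:3]
    mdc <- matrix(geom[4:12], nrow = 3L)  # columns: x_ras, y_ras, z_ras
    c_ras <- geom[13:15]
    rot <- mdc %*% diag(spacing)
    affine[1:3, 1:3] <- rot
    affine[1:3, 4] <- c_ras - rot %*% (dims / 2)
  }
  # skip remaining header padding
  consumed <- 7L * 4L + 2L + if (isTRUE(good_ras == 1L)) 60L else 0L
  readBin(con, "raw", n = MGH_HEADER_BYTES - consumed)
  nvox <- prod(dims) * max(nframes, 1L)
  vals <- switch(as.character(dtype),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1L,
                             signed = FALSE)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 4L,
                             endian = "big")),
    "3" = readBin(con, "numeric", n = nvox, size = 4L, endian = "big"),
    "4" = as.numeric(readBin(con, "integer", n = nvox, size = 2L,
                             endian = "big")),
    stop_fmt("format_error", "unsupported MGH datatype %d: %s", dtype, path))
  if (length(vals) < nvox)
    stop_fmt("format_error",
             "truncated MGH data (got %d of %d values): %s",
             length(vals), nvox, path)
  volume_image(array(vals[seq_len(prod(dims))], dim = dims), affine)
}

#' Write a volume as MGH/MGZ (float32)
#'
#' @param volume a [volume_image()].
#' @param path output path ending in `.mgh` or `.mgz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (grepl("\\.nii$|\\.nii\\.gz$", path)) {
    img <- RNifti::asNifti(volume$data)
    img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (!grepl("\\.mgh$|\\.mgz$", path))
    stop_fmt("format_error", "unsupported output volume format: %s", path)
  con <- if (grepl("\\.mgz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  dims <- dim(volume$data)
  writeBin(as.integer(c(1L, dims, 1L, 3L, 0L)), con, size = 4L,
           endian = "big")
  writeBin(1L, con, size = 2L, endian = "big")
  rot <- volume$affine[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  mdc <- rot %*% diag(1 / spacing)
  c_ras <- volume$affine[1:3, 4] + rot %*% (dims / 2)
  writeBin(as.numeric(c(spacing, mdc, c_ras)), con, size = 4L,
           endian = "big")
  writeBin(raw(MGH_HEADER_BYTES - (7L * 4L + 2L + 60L)), con)
  writeBin(as.numeric(volume$data), con, size = 4L, endian = "big")
  invisible(path)
}

#' Vertex map objects
#'
#' One scalar per mesh vertex with a validity mask; the unit of all
#' surface-based statistics. Invalid vertices carry `NA` and are excluded
#' from every statistic.
#'
#' @param values numeric vector, one value per vertex.
#' @param valid logical vector; defaults to `!is.na(values)`.
#' @param mesh_id identifier of the template mesh.
#' @param modality one of `"FA"`, `"MD"`, `"T1I"`, `"GWC"`, `"t"`, `"F"`,
#'   `"binary"`, or another tag.
#' @return An object of class `vertex_map`.
#' @export
vertex_map <- function(values, valid = NULL, mesh_id = "template",
                       modality = "unknown") {
  values <- as.numeric(values)
  if (is.null(valid)) valid <- !is.na(values)
  valid <- as.logical(valid) & !is.na(values)
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid, mesh_id = mesh_id,
                 modality = modality), class = "vertex_map")
}

#' @export
print.vertex_map <- function(x, ...) {
  cat(sprintf(
    "vertex_map [%s]: %d vertices (%d valid), range [%.4g, %.4g]\n",
    x$modality, length(x$values), sum(x$valid),
    suppressWarnings(min(x$values, na.rm = TRUE)),
    suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Write a vertex map as an MGH overlay and/or TSV
#'
#' The overlay is an `n x 1 x 1` float MGH volume (the FreeSurfer overlay
#' convention); the TSV has columns `vertex_id` (1-based) and `value`.
#' Invalid vertices are written as NaN in the overlay and `NA` in the TSV.
#'
#' @param map a [vertex_map()].
#' @param path output path; `.mgh`/`.mgz` writes an overlay, `.tsv` a table.
#' @return `path`, invisibly.
#' @export
write_vertex_map <- function(map, path) {
  if (grepl("\\.tsv$", path)) {
    df <- data.frame(vertex_id = seq_along(map$values), value = map$values)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  vals <- map$values
  vals[!map$valid] <- NaN
  write_overlay_mgh(vals, path)
  invisible(path)
}

write_overlay_mgh <- function(vals, path) {
  con <- if (grepl("\\.mgz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(1L, length(vals), 1L, 1L, 1L, 3L, 0L)), con,
           size = 4L, endian = "big")
  writeBin(0L, con, size = 2L, endian = "big")
  writeBin(raw(MGH_HEADER_BYTES - (7L * 4L + 2L)), con)
  writeBin(as.numeric(vals), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read a per-vertex MGH overlay
#'
#' @param path `.mgh`/`.mgz` overlay written by [write_vertex_map()] (or any
#'   MGH file whose trailing axes are 1).
#' @param modality modality tag for the returned map.
#' @return a [vertex_map()].
#' @export
read_vertex_map <- function(path, modality = "unknown") {
  con <- if (grepl("\\.mgz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 7L, size = 4L, endian = "big")
  if (length(hdr) < 7L || hdr[1] != 1L)
    stop_fmt("format_error", "not an MGH overlay: %s", path)
  dims <- hdr[2:4]; dtype <- hdr[6]
  good_ras <- readBin(con, "integer", n = 1L, size = 2L, endian = "big")
  consumed <- 7L * 4L + 2L
  readBin(con, "raw", n = MGH_HEADER_BYTES - consumed)
  if (dtype != 3L)
    stop_fmt("format_error", "overlay datatype %d unsupported: %s",
             dtype, path)
  vals <- readBin(con, "numeric", n = prod(dims), size = 4L, endian = "big")
  vertex_map(ifelse(is.nan(vals), NA_real_, vals), modality = modality)
}
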