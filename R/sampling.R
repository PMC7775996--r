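#' Per-vertex outward unit normals
#'
#' Area-weighted average of incident-triangle normals, normalized to unit
#' length. Orientation follows the triangle winding; for geometry produced
#' by [make_template_geometry()] (and FreeSurfer surfaces) this points
#' outward, i.e. from white matter toward the pial surface. Vertices with
#' no incident face are returned as `NA` rows.
#'
#' @param mesh a [surface_mesh()].
#' @return `n x 3` matrix of unit normals (NA rows for isolated vertices).
#' @export
compute_vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  # cross product rows; magnitude = 2 * triangle area (area weighting)
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(v), 3)
  for (corner in 1:3) {
    for (ax in 1:3) {
      n[, ax] <- n[, ax] +
        rowsum_safe(fn[, ax], f[, corner], nrow(v))
    }
  }
  len <- sqrt(rowSums(n^2))
  incident <- tabulate(f, nbins = nrow(v)) > 0
  bad <- !incident | len < 1e-300
  len[bad] <- NA_real_
  out <- n / len
  out[bad, ] <- NA_real_
  out
}

#' Trilinear sampling of a volume at world coordinates
#'
#' Interpolates trilinearly in the volume's own voxel space (points are
#' mapped through the inverse affine; no prior resampling). Points outside
#' the voxel-centre hull are flagged invalid, never extrapolated or
#' clamped.
#'
#' @param volume a [volume_image()].
#' @param points `n x 3` matrix of world mm coordinates.
#' @return list with `values` (numeric, `NA` where invalid) and `valid`
#'   (logical).
#' @export
trilinear_sample <- function(volume, points) {
  vox <- world_to_voxel(volume, points)
  d <- dim(volume$data)
  eps <- 1e-9
  valid <- vox[, 1] >= -eps & vox[, 1] <= d[1] - 1 + eps &
    vox[, 2] >= -eps & vox[, 2] <= d[2] - 1 + eps &
    vox[, 3] >= -eps & vox[, 3] <= d[3] - 1 + eps
  valid[!is.finite(rowSums(vox))] <- FALSE
  vals <- rep(NA_real_, nrow(vox))
  if (any(valid)) {
    p <- vox[valid, , drop = FALSE]
    i0 <- pmin(pmax(floor(p[, 1]), 0), d[1] - 2)
    j0 <- pmin(pmax(floor(p[, 2]), 0), d[2] - 2)
    k0 <- pmin(pmax(floor(p[, 3]), 0), d[3] - 2)
    fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
    at <- function(di, dj, dk)
      volume$data[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
    vals[valid] <-
      at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
      at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
      at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
      at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
      at(1, 1, 0) * fx * fy * (1 - fz) +
      at(1, 0, 1) * fx * (1 - fy) * fz +
      at(0, 1, 1) * (1 - fx) * fy * fz +
      at(1, 1, 1) * fx * fy * fz
    valid[is.na(vals) & valid] <- FALSE
  }
  list(values = vals, valid = valid)
}

#' Sample a volume at a cortical-thickness projection fraction
#'
#' The sample point at vertex v is `white + fraction * (pial - white)`:
#' fraction 0 is the gray-white boundary, 1 the pial surface. Fractions
#' 0.3 and 0.6 target the deeper (more myelinated) and more superficial
#' gray matter.
#'
#' @param white,pial vertex-corresponding [surface_mesh()]es.
#' @param volume a [volume_image()].
#' @param fraction proportion of cortical thickness in `[0, 1]`.
#' @param modality modality tag for the result.
#' @return a [vertex_map()].
#' @export
sample_projection_fraction <- function(white, pial, volume, fraction,
                                       modality = "unknown") {
  if (n_vertices(white) != n_vertices(pial))
    stop_fmt("geometry_error",
             "white (%d) and pial (%d) vertex counts differ",
             n_vertices(white), n_vertices(pial))
  if (fraction < 0 || fraction > 1)
    stop_fmt("parameter_error", "fraction must be in [0, 1]")
  pts <- white$vertices + fraction * (pial$vertices - white$vertices)
  s <- trilinear_sample(volume, pts)
  vertex_map(s$values, s$valid, modality = modality)
}

#' Sample a volume at an absolute depth along the vertex normal
#'
#' The sample point is `white + depth_mm * normal` with outward unit
#' normals, so negative depths sample below the gray-white boundary into
#' the superficial white matter (-1 mm targets short-range U-fibres,
#' -2 mm the terminations of long-range fibres).
#'
#' @param white white [surface_mesh()].
#' @param normals `n x 3` outward unit normals
#'   (from [compute_vertex_normals()]).
#' @param volume a [volume_image()].
#' @param depth_mm signed depth in mm (negative = into white matter).
#' @param modality modality tag for the result.
#' @return a [vertex_map()]; vertices sampling outside the volume (or with
#'   undefined normals) are masked invalid.
#' @export
sample_absolute_depth <- function(white, normals, volume, depth_mm,
                                  modality = "unknown") {
  if (nrow(normals) != n_vertices(white))
    stop_fmt("geometry_error", "normals do not match the mesh")
  pts <- white$vertices + depth_mm * normals
  s <- trilinear_sample(volume, pts)
  s$valid[!is.finite(rowSums(normals))] <- FALSE
  s$values[!s$valid] <- NA_real_
  vertex_map(s$values, s$valid, modality = modality)
}

#' Sampling scheme
#'
#' Ordered set of sampling depths. Each depth is either an absolute signed
#' distance in mm along the vertex normal (<= 0, below the boundary) or a
#' projection fraction of cortical thickness in `[0, 1]`. The default is
#' the five-depth scheme: -2 mm, -1 mm, boundary, 30% CT, 60% CT.
#'
#' @param labels character vector of unique depth labels.
#' @param type `"absolute"` or `"fraction"` per label.
#' @param value numeric depth (mm) or fraction per label.
#' @return data.frame of class `sampling_scheme`.
#' @export
sampling_scheme <- function(labels = c("-2mm", "-1mm", "boundary",
                                       "30%CT", "60%CT"),
                            type = c("absolute", "absolute", "fraction",
                                     "fraction", "fraction"),
                            value = c(-2, -1, 0, 0.3, 0.6)) {
  if (anyDuplicated(labels))
    stop_fmt("parameter_error", "depth labels must be unique")
  if (length(labels) != length(type) || length(labels) != length(value))
    stop_fmt("parameter_error", "labels/type/value lengths differ")
  if (any(type == "fraction" & (value < 0 | value > 1)))
    stop_fmt("parameter_error", "fractions must be in [0, 1]")
  if (any(type == "absolute" & value > 0))
    stop_fmt("parameter_error",
             "absolute depths must be <= 0 (below the boundary)")
  structure(data.frame(label = labels, type = type, value = value,
                       stringsAsFactors = FALSE),
            class = c("sampling_scheme", "data.frame"))
}

#' Build the depth profile of one subject
#'
#' Samples every modality volume at every depth of the scheme and computes
#' the shared validity mask (a vertex is dropped everywhere once any of
#' its samples falls outside a volume).
#'
#' @param white,pial vertex-corresponding [surface_mesh()]es.
#' @param volumes named list of [volume_image()]s (e.g. `FA`, `MD`, `T1I`).
#' @param scheme a [sampling_scheme()].
#' @param normals optional precomputed normals.
#' @return object of class `depth_profile`: `maps[[modality]][[label]]`
#'   [vertex_map()]s plus the `shared_valid` mask.
#' @export
build_depth_profile <- function(white, pial, volumes,
                                scheme = sampling_scheme(),
                                normals = NULL) {
  if (is.null(names(volumes)) || any(names(volumes) == ""))
    stop_fmt("input_error", "volumes must be a named list")
  if (is.null(normals)) normals <- compute_vertex_normals(white)
  maps <- lapply(names(volumes), function(mod) {
    vol <- volumes[[mod]]
    per_depth <- lapply(seq_len(nrow(scheme)), function(k) {
      if (scheme$type[k] == "fraction") {
        sample_projection_fraction(white, pial, vol, scheme$value[k],
                                   modality = mod)
      } else {
        sample_absolute_depth(white, normals, vol, scheme$value[k],
                              modality = mod)
      }
    })
    names(per_depth) <- scheme$label
    per_depth
  })
  names(maps) <- names(volumes)
  shared <- Reduce(`&`, lapply(unlist(maps, recursive = FALSE),
                               function(m) m$valid))
  structure(list(maps = maps, scheme = scheme, shared_valid = shared),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile: %s at depths {%s}; %d/%d vertices valid\n",
              paste(names(x$maps), collapse = ", "),
              paste(x$scheme$label, collapse = ", "),
              sum(x$shared_valid), length(x$shared_valid)))
  invisible(x)
}
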