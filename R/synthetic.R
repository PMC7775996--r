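#' Specification of a synthetic cortical cohort
#'
#' Bundles every knob of the synthetic data generator: template geometry,
#' tissue profiles across the gray-white boundary, planted regional effects,
#' the noise model, and the clinical-score model. Defaults emulate a
#' two-group (ASD/TD), two-sex, two-site adult cohort: 23 subjects per
#' group x sex x site cell (184 total), ages uniform on 18-52 years, FSIQ
#' normal with mean 115 and SD 11, mean cortical thickness 2.67 mm.
#'
#' Tissue profiles are sigmoidal across the boundary between a white-matter
#' and a gray-matter plateau: T1 intensity and FA are higher in white
#' matter, MD is higher in gray matter. Planted effects are disc-shaped
#' regions where a modality is shifted for the subjects of a group (main
#' effect) or with a group-by-sex pattern; magnitudes are in the modality's
#' own units.
#'
#' @param n_per_cell subjects per group x sex x site cell (>= 2).
#' @param mesh_kind `"slab"` (flat sheet, the default test world) or
#'   `"sphere"`.
#' @param mesh_extent_mm slab edge length in mm (slab) or sphere radius.
#' @param vertex_spacing_mm target vertex spacing in mm.
#' @param thickness_mean,thickness_sd cortical thickness distribution
#'   across vertices, mm.
#' @param tissue_profile named list per modality with entries `wm`, `gm`
#'   (plateau values) and `width` (transition width, mm).
#' @param effect_list list of planted effects; each a list with `center`
#'   (xy mm for slab, unit direction for sphere), `radius_mm`, `modality`,
#'   `depth_range` (signed mm relative to the boundary, negative = into
#'   white matter), `magnitude` (modality units), and `pattern` (`"group"`:
#'   added for ASD subjects only; `"group_x_sex"`: added with sign
#'   group x sex under +/-1 coding).
#' @param noise_sd named per-modality SD of spatially correlated voxel
#'   noise.
#' @param noise_fwhm_mm spatial FWHM of the volume noise, mm.
#' @param subject_offset_sd named per-modality SD of a global per-subject
#'   intensity offset.
#' @param dose_sd SD of the per-subject effect-magnitude scaling factor
#'   (mean 1).
#' @param clinical_r target correlation between the AQ-like score and the
#'   per-subject effect dose within the ASD group.
#' @param volume_spacing_mm voxel size of the generated volumes, mm.
#' @param diffusion_spacing_mm voxel size of FA/MD volumes; defaults to
#'   `volume_spacing_mm`, set to 2.4 to emulate a coarser diffusion grid.
#' @param seed master seed; every stochastic output is a deterministic
#'   function of it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_cell = 23L,
                           mesh_kind = c("slab", "sphere"),
                           mesh_extent_mm = 20,
                           vertex_spacing_mm = 1,
                           thickness_mean = 2.67,
                           thickness_sd = 0.1,
                           tissue_profile = list(
                             T1I = list(wm = 110, gm = 90, width = 0.5),
                             FA  = list(wm = 0.45, gm = 0.15, width = 0.5),
                             MD  = list(wm = 7.5e-4, gm = 8.5e-4,
                                        width = 0.5)),
                           effect_list = default_effect_list(),
                           noise_sd = c(T1I = 2, FA = 0.03, MD = 4e-5),
                           noise_fwhm_mm = 6,
                           subject_offset_sd = c(T1I = 1, FA = 0.01,
                                                 MD = 1e-5),
                           dose_sd = 0.3,
                           clinical_r = 0.6,
                           volume_spacing_mm = 1,
                           diffusion_spacing_mm = NULL,
                           seed = 1L) {
  mesh_kind <- match.arg(mesh_kind)
  if (vertex_spacing_mm <= 0)
    stop_fmt("parameter_error", "vertex_spacing_mm must be > 0")
  if (n_per_cell < 2L)
    stop_fmt("parameter_error",
             "n_per_cell must be >= 2 (variance inestimable)")
  for (ef in effect_list) {
    if (!is.finite(ef$magnitude))
      stop_fmt("parameter_error", "effect magnitude must be finite")
    if (ef$radius_mm >= mesh_extent_mm)
      stop_fmt("parameter_error",
               "effect radius %.1f mm exceeds mesh extent", ef$radius_mm)
  }
  structure(list(
    n_per_cell = as.integer(n_per_cell), mesh_kind = mesh_kind,
    mesh_extent_mm = mesh_extent_mm, vertex_spacing_mm = vertex_spacing_mm,
    thickness_mean = thickness_mean, thickness_sd = thickness_sd,
    tissue_profile = tissue_profile, effect_list = effect_list,
    noise_sd = noise_sd, noise_fwhm_mm = noise_fwhm_mm,
    subject_offset_sd = subject_offset_sd, dose_sd = dose_sd,
    clinical_r = clinical_r, volume_spacing_mm = volume_spacing_mm,
    diffusion_spacing_mm = diffusion_spacing_mm %||% volume_spacing_mm,
    seed = as.integer(seed)), class = "synthetic_spec")
}

#' Default planted effects
#'
#' Three disc effects on the default 20 mm slab: an FA reduction and a T1
#' gray-matter intensity increase (lowering GWC) whose discs partly
#' overlap, plus a group-by-sex MD effect in a separate disc.
#' @export
default_effect_list <- function() {
  list(
    list(center = c(7, 7), radius_mm = 5, modality = "FA",
         depth_range = c(-3, 1), magnitude = -0.05, pattern = "group"),
    list(center = c(11, 7), radius_mm = 5, modality = "T1I",
         depth_range = c(0, 3), magnitude = 4, pattern = "group"),
    list(center = c(7, 14), radius_mm = 4, modality = "MD",
         depth_range = c(-3, 0.5), magnitude = 4e-5,
         pattern = "group_x_sex"))
}

#' Template white/pial geometry for a synthetic cohort
#'
#' Slab: a regular grid in the z = 0 plane (white surface) with the pial
#' surface displaced to z = thickness(v). Sphere: a subdivided icosahedron
#' of the requested radius with the pial surface displaced radially. Both
#' surfaces share the triangulation, so vertices correspond by index.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `white`, `pial` ([surface_mesh()]s) and
#'   `thickness` (per-vertex mm).
#' @export
make_template_geometry <- function(spec) {
  kind <- spec$mesh_kind
  if (kind == "slab") {
    s <- spec$vertex_spacing_mm
    xs <- seq(0, spec$mesh_extent_mm, by = s)
    n1 <- length(xs)
    grid <- expand.grid(x = xs, y = xs)
    verts <- cbind(grid$x, grid$y, 0)
    idx <- function(i, j) (j - 1L) * n1 + i
    i <- rep(seq_len(n1 - 1L), n1 - 1L)
    j <- rep(seq_len(n1 - 1L), each = n1 - 1L)
    # two CCW triangles per grid quad (normals toward +z = pial side)
    faces <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                   cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
    white <- surface_mesh(verts, faces, hemisphere = "synthetic-slab")
    outward <- matrix(rep(c(0, 0, 1), each = nrow(verts)), ncol = 3)
  } else {
    R <- spec$mesh_extent_mm
    # icosahedron edge ~ 1.05 R; halves per subdivision
    n_sub <- max(0L, round(log2(R * 1.0515 / spec$vertex_spacing_mm)))
    ico <- icosphere(n_sub)
    white <- surface_mesh(ico$vertices * R, ico$faces,
                          hemisphere = "synthetic-sphere")
    outward <- ico$vertices
  }
  thickness <- with_seed(substream_seed(spec$seed, "thickness"), {
    pmax(0.5, rnorm(nrow(white$vertices), spec$thickness_mean,
                    spec$thickness_sd))
  })
  pial <- surface_mesh(white$vertices + outward * thickness,
                       white$faces, hemisphere = white$hemisphere)
  list(white = white, pial = pial, thickness = thickness)
}

# Subdivided icosahedron on the unit sphere. Midpoint subdivision with a
# shared-edge cache, then radial projection.
icosphere <- function(n_subdiv = 2L) {
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
  for (lvl in seq_len(n_subdiv)) {
    cache <- new.env(hash = TRUE)
    vlist <- lapply(seq_len(nrow(v)), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (vlist[[a]] + vlist[[b]]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1L]] <<- m
      cache[[key]] <- length(vlist)
      length(vlist)
    }
    newf <- vector("list", nrow(f))
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[[k]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                         c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- do.call(rbind, newf)
  }
  list(vertices = v, faces = f)
}

# Signed depth relative to the white surface for world points: z for the
# slab, radius - R for the sphere. Negative = into white matter.
synthetic_depth <- function(spec, pts) {
  if (spec$mesh_kind == "slab") pts[, 3]
  else sqrt(rowSums(pts^2)) - spec$mesh_extent_mm
}

# In-region indicator for a planted effect at world points.
effect_region <- function(spec, effect, pts) {
  d <- synthetic_depth(spec, pts)
  if (spec$mesh_kind == "slab") {
    lat <- sqrt((pts[, 1] - effect$center[1])^2 +
                  (pts[, 2] - effect$center[2])^2)
  } else {
    u <- effect$center / sqrt(sum(effect$center^2))
    r <- pmax(sqrt(rowSums(pts^2)), 1e-9)
    ang <- acos(pmin(1, pmax(-1, (pts %*% u) / r)))
    lat <- as.numeric(ang) * spec$mesh_extent_mm
  }
  lat <= effect$radius_mm & d >= effect$depth_range[1] &
    d <= effect$depth_range[2]
}

# Sign with which an effect enters a subject's volumes (0 = not applied).
effect_cell_sign <- function(effect, group, sex) {
  g <- if (group == "ASD") 1 else -1
  s <- if (sex == "male") 1 else -1
  switch(effect$pattern,
         group = if (group == "ASD") 1 else 0,
         group_x_sex = g * s,
         stop_fmt("parameter_error", "unknown effect pattern '%s'",
                  effect$pattern))
}

volume_grid <- function(spec, spacing, margin = 4) {
  if (spec$mesh_kind == "slab") {
    lo <- c(-margin, -margin, -(margin + 2))
    hi <- c(spec$mesh_extent_mm + margin, spec$mesh_extent_mm + margin,
            spec$thickness_mean + margin + 2)
  } else {
    R <- spec$mesh_extent_mm + spec$thickness_mean + margin
    lo <- c(-R, -R, -R); hi <- c(R, R, R)
  }
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  affine <- diag(c(spacing, spacing, spacing, 1))
  affine[1:3, 4] <- lo
  list(dims = dims, affine = affine)
}

# Gaussian smoothing of a 3D array, separable along each axis, with exact
# variance bookkeeping (interior weights); returns the field rescaled to
# unit marginal SD assuming unit-SD white-noise input.
smooth_noise_array <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  shrink <- sqrt(sum(k^2))
  d <- dim(arr)
  smooth_axis <- function(a, axis) {
    m <- aperm(a, c(axis, setdiff(1:3, axis)))
    dm <- dim(m)
    mm <- matrix(m, nrow = dm[1])
    n <- dm[1]
    band <- Matrix::bandSparse(n, n, k = -r:r,
                               diagonals = lapply(-r:r, function(off)
                                 rep(k[off + r + 1], n - abs(off))))
    mm <- as.matrix(band %*% mm)
    out <- array(mm, dm)
    aperm(out, order(c(axis, setdiff(1:3, axis))))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr / shrink^3
}

#' Simulate the volumes of one synthetic subject
#'
#' Each modality volume is a sigmoidal profile across the boundary between
#' its white- and gray-matter plateau values, plus the planted effects that
#' apply to the subject's group/sex cell (scaled by the subject's dose),
#' plus spatially correlated Gaussian noise and a global subject offset.
#' Deterministic given `seed`.
#'
#' @param geometry output of [make_template_geometry()].
#' @param spec a [synthetic_spec()].
#' @param subject_cell list with `group` (`"ASD"`/`"TD"`) and `sex`
#'   (`"male"`/`"female"`).
#' @param seed integer seed for this subject's noise.
#' @param dose per-subject effect scaling (default 1).
#' @param noise logical; set `FALSE` for noise-free volumes.
#' @return named list of [volume_image()]s (`T1I`, `FA`, `MD`).
#' @export
simulate_subject_volumes <- function(geometry, spec, subject_cell, seed,
                                     dose = 1, noise = TRUE) {
  mods <- names(spec$tissue_profile)
  out <- vector("list", length(mods))
  names(out) <- mods
  for (mod in mods) {
    spacing <- if (mod %in% c("FA", "MD")) spec$diffusion_spacing_mm
    else spec$volume_spacing_mm
    grid <- volume_grid(spec, spacing)
    dims <- grid$dims
    ijk <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1L,
                                 j = seq_len(dims[2]) - 1L,
                                 k = seq_len(dims[3]) - 1L))
    pts <- cbind(ijk, 1) %*% t(grid$affine)
    pts <- pts[, 1:3, drop = FALSE]
    prof <- spec$tissue_profile[[mod]]
    depth <- synthetic_depth(spec, pts)
    vals <- prof$gm + (prof$wm - prof$gm) *
      stats::plogis(-depth / (prof$width / 4))
    for (ef in spec$effect_list) {
      if (ef$modality != mod) next
      sgn <- effect_cell_sign(ef, subject_cell$group, subject_cell$sex)
      if (sgn == 0) next
      inr <- effect_region(spec, ef, pts)
      vals[inr] <- vals[inr] + sgn * dose * ef$magnitude
    }
    arr <- array(vals, dims)
    if (noise) {
      arr <- arr + with_seed(substream_seed(seed, paste0("noise-", mod)), {
        sigma_vox <- (spec$noise_fwhm_mm / 2.3548) / spacing
        field <- smooth_noise_array(array(rnorm(prod(dims)), dims),
                                    sigma_vox)
        offset <- rnorm(1, 0, spec$subject_offset_sd[[mod]])
        field * spec$noise_sd[[mod]] + offset
      })
    }
    out[[mod]] <- volume_image(arr, grid$affine)
  }
  out
}

#' Simulate a synthetic cohort table and its ground truth
#'
#' Fills every group x sex x site cell with `n_per_cell` subjects. Ages are
#' uniform on 18-52 years, FSIQ normal (115, 11). Each subject carries an
#' effect dose (mean 1), and the AQ-like score of ASD subjects is a linear
#' function of the dose plus noise calibrated to the spec's target
#' correlation; BDI/BAI comorbidity scores are generated as correlated
#' nuisance scores.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `cohort` (a `cohort_table` including a `dose` column)
#'   and `truth` (per planted effect: affected white-surface vertex set,
#'   modality, magnitude, pattern, depth range).
#' @export
simulate_cohort <- function(spec) {
  cells <- expand.grid(group = c("ASD", "TD"), sex = c("male", "female"),
                       site = c("A", "B"), stringsAsFactors = FALSE)
  n <- nrow(cells) * spec$n_per_cell
  df <- cells[rep(seq_len(nrow(cells)), each = spec$n_per_cell), ]
  rownames(df) <- NULL
  df$id <- sprintf("S%03d", seq_len(n))
  cohort <- with_seed(substream_seed(spec$seed, "cohort"), {
    df$age <- runif(n, 18, 52)
    df$fsiq <- rnorm(n, 115, 11)
    df$dose <- rnorm(n, 1, spec$dose_sd)
    z <- (df$dose - 1) / max(spec$dose_sd, 1e-12)
    r <- spec$clinical_r
    eps <- rnorm(n)
    is_asd <- df$group == "ASD"
    df$aq <- ifelse(is_asd,
                    round(35 + 8 * (r * z + sqrt(max(0, 1 - r^2)) * eps)),
                    round(15 + 6 * rnorm(n)))
    df$bdi <- pmax(0, round(ifelse(is_asd, 12 + 8 * rnorm(n),
                                   4 + 4 * rnorm(n))))
    df$bai <- pmax(0, round(ifelse(is_asd, 10 + 7 * rnorm(n),
                                   4 + 4 * rnorm(n))))
    df
  })
  cohort <- cohort[, c("id", "group", "sex", "site", "age", "fsiq",
                       "aq", "bdi", "bai", "dose")]
  geometry <- make_template_geometry(spec)
  truth <- lapply(spec$effect_list, function(ef) {
    verts <- which(effect_region(spec, ef, geometry$white$vertices +
                                   1e-9))
    list(vertices = verts, modality = ef$modality,
         magnitude = ef$magnitude, pattern = ef$pattern,
         depth_range = ef$depth_range, radius_mm = ef$radius_mm)
  })
  list(cohort = validate_cohort(cohort), truth = truth,
       geometry = geometry)
}

#' Write a complete synthetic data set to disk
#'
#' Writes the template surfaces (FreeSurfer binary format), one MGH volume
#' per subject and modality, the cohort TSV (with `path_*` columns), and a
#' truth JSON.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return the cohort table, invisibly.
#' @export
simulate_to_dir <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(spec)
  write_surface(sim$geometry$white, file.path(dir, "white.surf"))
  write_surface(sim$geometry$pial, file.path(dir, "pial.surf"))
  cohort <- sim$cohort
  for (mod in names(spec$tissue_profile))
    cohort[[paste0("path_", mod)]] <- NA_character_
  for (s in seq_len(nrow(cohort))) {
    vols <- simulate_subject_volumes(
      sim$geometry, spec,
      list(group = cohort$group[s], sex = cohort$sex[s]),
      seed = substream_seed(spec$seed, paste0("subject-", cohort$id[s])),
      dose = cohort$dose[s])
    for (mod in names(vols)) {
      p <- file.path(dir, sprintf("%s_%s.mgz", cohort$id[s], mod))
      write_volume(vols[[mod]], p)
      cohort[[paste0("path_", mod)]][s] <- basename(p)
    }
  }
  write_cohort(cohort, file.path(dir, "cohort.tsv"))
  jsonlite::write_json(
    lapply(sim$truth, function(tr)
      list(vertices = tr$vertices, modality = tr$modality,
           magnitude = tr$magnitude, pattern = tr$pattern,
           depth_range = tr$depth_range)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}
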