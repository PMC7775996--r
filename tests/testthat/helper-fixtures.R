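# Shared fixtures: small synthetic worlds and independent oracles.

# Slab spec with no planted effects (null world).
null_spec <- function(extent = 20, n_per_cell = 3L, seed = 1L, ...) {
  synthetic_spec(n_per_cell = n_per_cell, mesh_extent_mm = extent,
                 effect_list = list(), seed = seed, ...)
}

# A small cohort + design shared by statistical tests.
make_cohort_design <- function(n_per_cell = 3L, seed = 1L, extent = 20) {
  spec <- null_spec(extent = extent, n_per_cell = n_per_cell, seed = seed)
  sim <- simulate_cohort(spec)
  list(spec = spec, cohort = sim$cohort, geometry = sim$geometry,
       X = build_design(sim$cohort))
}

# Volume whose value is an affine function of world coordinates, on the
# synthetic slab's grid (trilinear interpolation must reproduce it
# exactly).
affine_volume <- function(spec, coef = c(2, -1, 3), intercept = 0.5,
                          spacing = 1) {
  grid <- boundaryprofile:::volume_grid(spec, spacing)
  ijk <- as.matrix(expand.grid(i = seq_len(grid$dims[1]) - 1,
                               j = seq_len(grid$dims[2]) - 1,
                               k = seq_len(grid$dims[3]) - 1))
  pts <- cbind(ijk, 1) %*% t(grid$affine)
  vals <- intercept + pts[, 1:3] %*% coef
  volume_image(array(vals, grid$dims), grid$affine)
}

affine_field_at <- function(pts, coef = c(2, -1, 3), intercept = 0.5) {
  as.numeric(intercept + pts %*% coef)
}

# Smooth unit-SD noise maps on the mesh, subjects x vertices.
smooth_noise_maps <- function(mesh, n_subjects, fwhm = 6) {
  nv <- nrow(mesh$vertices)
  Y <- boundaryprofile:::smooth_matrix(
    mesh, matrix(rnorm(n_subjects * nv), n_subjects, nv), fwhm,
    rep(TRUE, nv))
  Y / sd(as.numeric(Y))
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Breadth-first-search connected components: independent oracle for the
# cluster labeling.
bfs_components <- function(idx, adjacency) {
  lab <- integer(length(idx))
  names(lab) <- idx
  inset <- logical(max(c(idx, 1L)))
  inset[idx] <- TRUE
  comp <- 0L
  for (start in idx) {
    if (lab[as.character(start)] > 0L) next
    comp <- comp + 1L
    queue <- start
    lab[as.character(start)] <- comp
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (nb in adjacency[[v]]) {
        if (nb <= length(inset) && inset[nb] &&
            lab[as.character(nb)] == 0L) {
          lab[as.character(nb)] <- comp
          queue <- c(queue, nb)
        }
      }
    }
  }
  unname(lab)
}

# Canonical partition signature for comparing two component labelings.
partition_signature <- function(idx, membership) {
  groups <- split(idx, membership)
  sorted <- lapply(groups, sort)
  paste(sort(vapply(sorted, paste, character(1), collapse = ",")),
        collapse = ";")
}
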