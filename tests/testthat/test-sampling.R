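test_that("vertex normals: planar, spherical, and brute-force agreement", {
  geo <- make_template_geometry(null_spec(extent = 10))
  nrm <- compute_vertex_normals(geo$white)
  expect_lt(max(abs(sweep(nrm, 2, c(0, 0, 1)))), 1e-12)

  # brute-force oracle: loop over faces, accumulate cross products
  set.seed(42)
  pts <- cbind(runif(40), runif(40), runif(40) * 0.1)
  tri <- t(utils::combn(40, 3))[sample(9880, 60), ]
  keep <- apply(tri, 1, function(f) {
    a <- pts[f[2], ] - pts[f[1], ]; b <- pts[f[3], ] - pts[f[1], ]
    sqrt(sum(crossprod_vec(a, b)^2)) > 1e-6
  })
  mesh <- surface_mesh(pts, tri[keep, ])
  oracle <- matrix(0, 40, 3)
  for (k in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[k, ]
    fn <- crossprod_vec(pts[f[2], ] - pts[f[1], ],
                        pts[f[3], ] - pts[f[1], ])
    for (v in f) oracle[v, ] <- oracle[v, ] + fn
  }
  len <- sqrt(rowSums(oracle^2))
  oracle <- oracle / ifelse(len > 0, len, NA)
  mine <- compute_vertex_normals(mesh)
  ok <- is.finite(len) & len > 1e-12
  expect_lt(max(abs(mine[ok, ] - oracle[ok, ])), 1e-9)
  # isolated vertices are flagged, not silently zero
  iso <- setdiff(seq_len(40), unique(as.integer(mesh$faces)))
  if (length(iso)) expect_true(all(is.na(mine[iso, ])))
})

test_that("trilinear interpolation: voxel centres, midpoints, affine fields", {
  vol <- volume_image(array(rnorm(5 * 5 * 5), c(5, 5, 5)))
  s <- trilinear_sample(vol, rbind(c(2, 3, 1)))
  expect_equal(s$values, vol$data[3, 4, 2])
  mid <- trilinear_sample(vol, rbind(c(2.5, 3, 1)))
  expect_equal(mid$values, (vol$data[3, 4, 2] + vol$data[4, 4, 2]) / 2)

  spec <- null_spec(extent = 10)
  avol <- affine_volume(spec)
  set.seed(7)
  pts <- cbind(runif(50, 0, 10), runif(50, 0, 10), runif(50, -2, 3))
  got <- trilinear_sample(avol, pts)
  expect_true(all(got$valid))
  expect_lt(max(abs(got$values - affine_field_at(pts))), 1e-9)

  # outside the grid hull: flagged, not extrapolated
  out <- trilinear_sample(vol, rbind(c(-1, 0, 0), c(0, 0, 10)))
  expect_identical(out$valid, c(FALSE, FALSE))
  expect_true(all(is.na(out$values)))
})

test_that("projection-fraction sampling follows the white-pial axis", {
  spec <- synthetic_spec(thickness_mean = 2.5, thickness_sd = 0,
                         effect_list = list())
  geo <- make_template_geometry(spec)
  fvol <- affine_volume(spec, coef = c(0, 0, 1), intercept = 0)  # f = z
  for (fr in c(0.3, 0.6)) {
    m <- sample_projection_fraction(geo$white, geo$pial, fvol, fr)
    expect_equal(m$values, rep(fr * 2.5, length(m$values)),
                 tolerance = 1e-9)
  }
  m0 <- sample_projection_fraction(geo$white, geo$pial, fvol, 0)
  expect_equal(m0$values, rep(0, length(m0$values)), tolerance = 1e-12)
  cvol <- affine_volume(spec, coef = c(0, 0, 0), intercept = 3.25)
  mc <- sample_projection_fraction(geo$white, geo$pial, cvol, 0.42)
  expect_equal(unique(mc$values), 3.25)
  expect_error(sample_projection_fraction(geo$white, geo$pial, fvol, 1.2),
               "fraction")
  small <- surface_mesh(geo$pial$vertices[1:10, ],
                        matrix(c(1, 2, 3), 1))
  expect_error(sample_projection_fraction(geo$white, small, fvol, 0.3),
               "vertex counts")
})

test_that("absolute-depth sampling follows the normal and masks out-of-volume", {
  spec <- synthetic_spec(thickness_mean = 2.5, thickness_sd = 0,
                         effect_list = list())
  geo <- make_template_geometry(spec)
  nrm <- compute_vertex_normals(geo$white)
  fvol <- affine_volume(spec, coef = c(0, 0, 1), intercept = 0)
  m1 <- sample_absolute_depth(geo$white, nrm, fvol, -1)
  expect_equal(m1$values, rep(-1, length(m1$values)), tolerance = 1e-9)
  m0 <- sample_absolute_depth(geo$white, nrm, fvol, 0)
  f0 <- sample_projection_fraction(geo$white, geo$pial, fvol, 0)
  expect_equal(m0$values, f0$values, tolerance = 1e-12)

  # thin volume: deep samples leave the grid and are masked, never clamped
  thin <- volume_image(array(1, c(25, 25, 2)),
                       {
                         a <- diag(4); a[1:3, 4] <- c(-2, -2, -1); a
                       })
  deep <- sample_absolute_depth(geo$white, nrm, thin, -2)
  expect_true(all(!deep$valid))
  shallow <- sample_absolute_depth(geo$white, nrm, thin, -0.5)
  # mask monotonicity: deeper sampling never unmasks a vertex
  expect_true(all(deep$valid <= shallow$valid))
})

test_that("depth profiles assemble, stay order-invariant and monotone", {
  spec <- synthetic_spec(effect_list = list(), thickness_sd = 0)
  geo <- make_template_geometry(spec)
  vols <- simulate_subject_volumes(geo, spec,
                                   list(group = "TD", sex = "female"),
                                   seed = 3, noise = FALSE)
  sch <- sampling_scheme()
  prof <- build_depth_profile(geo$white, geo$pial, vols, sch)
  expect_equal(length(prof$maps), 3L)
  expect_equal(names(prof$maps$FA), sch$label)

  # noise-free FA: white plateau at -1 mm, gray plateau at 60% CT
  expect_lt(max(abs(prof$maps$FA[["-1mm"]]$values - 0.45)) / 0.45, 0.01)
  expect_lt(max(abs(prof$maps$FA[["60%CT"]]$values - 0.15)) / 0.15, 0.01)

  # monotone non-increasing T1 profile from deep white into gray matter
  M <- vapply(sch$label, function(l) prof$maps$T1I[[l]]$values,
              numeric(n_vertices(geo$white)))
  expect_true(all(apply(M, 1, function(r) all(diff(r) <= 1e-9))))

  # permuting the scheme permutes, never changes, the values
  perm <- sch[c(3, 1, 5, 2, 4), ]
  prof2 <- build_depth_profile(geo$white, geo$pial, vols, perm)
  expect_equal(prof2$maps$MD[["30%CT"]]$values,
               prof$maps$MD[["30%CT"]]$values)

  only_boundary <- sampling_scheme("boundary", "fraction", 0)
  prof3 <- build_depth_profile(geo$white, geo$pial, vols, only_boundary)
  expect_equal(length(unlist(prof3$maps, recursive = FALSE)), 3L)
  expect_error(build_depth_profile(geo$white, geo$pial,
                                   unname(vols), sch), "named")
  expect_error(sampling_scheme(c("a", "a"), c("absolute", "absolute"),
                               c(-1, -2)), "unique")
})
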