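# Uniform-smoothness stand-in for tests that construct t-maps directly.
uniform_smoothness <- function(mesh, fwhm) {
  f <- mesh$faces
  v <- mesh$vertices
  cr <- boundaryprofile:::cross3(v[f[, 2], ] - v[f[, 1], ],
                                 v[f[, 3], ] - v[f[, 1], ])
  area_tri <- 0.5 * sqrt(rowSums(cr^2))
  nv <- nrow(v)
  vertex_area <- numeric(nv)
  for (corner in 1:3)
    vertex_area <- vertex_area +
      boundaryprofile:::rowsum_safe(area_tri / 3, f[, corner], nv)
  structure(list(vertex_fwhm = rep(fwhm, nv),
                 vertex_resel = vertex_area / fwhm^2,
                 vertex_area = vertex_area,
                 total_resels = sum(vertex_area) / fwhm^2,
                 total_area = sum(vertex_area),
                 global_fwhm = fwhm, resels1 = 0, resels0 = 1),
            class = "smoothness_estimate")
}

as_t_map <- function(values, df) {
  structure(list(map = vertex_map(values, modality = "t"), df = df,
                 contrast = "synthetic", stat = "t"),
            class = "stat_map")
}

test_that("residual smoothness: white noise, smoothed noise, equivariance", {
  cd <- make_cohort_design(n_per_cell = 3L, seed = 1, extent = 25)
  mesh <- cd$geometry$white
  nv <- n_vertices(mesh)
  n <- nrow(cd$X)
  set.seed(12)
  Yw <- matrix(rnorm(n * nv), n, nv)
  fit_w <- fit_vertex_glm(Yw, cd$X)
  sm_w <- estimate_smoothness(fit_w, mesh)
  # discrete white noise on a unit-edge grid: FWHM = h * sqrt(2 log 2)
  expect_lt(abs(sm_w$global_fwhm - sqrt(2 * log(2))) / sqrt(2 * log(2)),
            0.15)

  Ys <- smooth_noise_maps(mesh, n, fwhm = 6)
  fit_s <- fit_vertex_glm(Ys, cd$X)
  sm_s <- estimate_smoothness(fit_s, mesh)
  expect_gt(sm_s$global_fwhm, 6 * 0.85)
  expect_lt(sm_s$global_fwhm, 6 * 1.15)

  # resels of the whole mesh ~ area / FWHM^2 under uniform smoothness
  expect_lt(abs(sm_s$total_resels - sm_s$total_area / 6^2) /
              (sm_s$total_area / 6^2), 0.35)

  # doubling the mesh scale doubles the FWHM in mm
  mesh2 <- surface_mesh(mesh$vertices * 2, mesh$faces)
  sm2 <- estimate_smoothness(fit_s, mesh2)
  expect_equal(sm2$global_fwhm, 2 * sm_s$global_fwhm, tolerance = 1e-9)
})

test_that("cluster definition: empty maps, planted discs, partition", {
  cd <- make_cohort_design(n_per_cell = 3L, seed = 2, extent = 25)
  mesh <- cd$geometry$white
  nv <- n_vertices(mesh)
  sm <- uniform_smoothness(mesh, 6)
  df <- 30

  zero <- define_clusters(as_t_map(rep(0, nv), df), mesh, sm)
  expect_equal(nrow(zero), 0L)

  v <- mesh$vertices
  t_cdt <- qt(1 - 0.001 / 2, df)
  disc1 <- which(sqrt((v[, 1] - 6)^2 + (v[, 2] - 6)^2) <= 3)
  disc2 <- which(sqrt((v[, 1] - 18)^2 + (v[, 2] - 18)^2) <= 3)
  tv <- rep(0, nv)
  tv[disc1] <- t_cdt + 1
  tv[disc2] <- -(t_cdt + 2)
  cl <- define_clusters(as_t_map(tv, df), mesh, sm)
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$sign, c("positive", "negative"))
  got1 <- cl$vertices[[which(cl$sign == "positive")]]
  expect_setequal(got1, disc1)
  expect_setequal(cl$vertices[[which(cl$sign == "negative")]], disc2)
  # suprathreshold partition: disjoint, union equals the excursion set
  expect_length(intersect(cl$vertices[[1]], cl$vertices[[2]]), 0)
  expect_setequal(unlist(cl$vertices), c(disc1, disc2))
})

test_that("component labeling agrees with a BFS oracle on random maps", {
  cd <- make_cohort_design(n_per_cell = 2L, seed = 3, extent = 15)
  mesh <- cd$geometry$white
  nv <- n_vertices(mesh)
  adj <- mesh_adjacency(mesh)
  edges <- boundaryprofile:::mesh_edges(mesh)
  set.seed(13)
  for (rep in 1:100) {
    idx <- which(runif(nv) < 0.25)
    if (!length(idx)) next
    mine <- boundaryprofile:::component_membership(idx, edges)
    oracle <- bfs_components(idx, adj)
    expect_identical(partition_signature(idx, mine),
                     partition_signature(idx, oracle))
  }
})

test_that("RFT cluster p: limits, monotonicity, df guard", {
  p0 <- rft_cluster_p(1e-9, total_resels = 20, cdt_p = 0.001, df = 30)
  pbig <- rft_cluster_p(10, 20, 0.001, 30)
  expect_gt(p0, pbig)
  ext <- seq(0.01, 8, length.out = 40)
  ps <- rft_cluster_p(ext, 20, 0.001, 30)
  expect_true(all(diff(ps) < 0))
  # extent -> 0 approaches the probability of any suprathreshold cluster
  expect_equal(p0, rft_cluster_p(0, 20, 0.001, 30), tolerance = 1e-6)
  expect_error(rft_cluster_p(1, 20, 0.001, df = 2), "df > 2")
})

test_that("null FWER is controlled for both RFT and permutation", {
  cd <- make_cohort_design(n_per_cell = 3L, seed = 5, extent = 25)
  mesh <- cd$geometry$white
  n <- nrow(cd$X)
  set.seed(21)
  n_data <- 200
  any_rft <- 0L
  any_perm <- 0L
  pairs <- list()
  for (d in seq_len(n_data)) {
    Y <- smooth_noise_maps(mesh, n, fwhm = 6)
    pt <- permutation_cluster_test(Y, cd$X, "group", mesh,
                                   cdt_p = 0.001, n_perm = 150, seed = d)
    cl <- rft_correct_clusters(pt$clusters, pt$smoothness)
    if (nrow(cl)) {
      if (any(cl$p_rft < 0.05)) any_rft <- any_rft + 1L
      if (any(cl$p_perm <= 0.05)) any_perm <- any_perm + 1L
      pairs[[length(pairs) + 1L]] <- cl[, c("p_rft", "p_perm")]
    }
  }
  expect_gte(any_rft / n_data, 0.01)
  expect_lte(any_rft / n_data, 0.10)
  expect_gte(any_perm / n_data, 0.01)
  expect_lte(any_perm / n_data, 0.10)

  # RFT and permutation corrected p agree within a factor of 3 in the
  # informative range
  pr <- do.call(rbind, pairs)
  mid <- pr[pr$p_rft >= 0.01 & pr$p_rft <= 0.2 & pr$p_perm > 0, ,
            drop = FALSE]
  expect_gt(nrow(mid), 5)
  ratio <- mid$p_rft / mid$p_perm
  expect_gt(median(ratio), 1 / 3)
  expect_lt(median(ratio), 3)
  expect_gt(mean(ratio > 1 / 3 & ratio < 3), 0.8)
})

test_that("permutation test is seed-reproducible and detects planted effects", {
  cd <- make_cohort_design(n_per_cell = 5L, seed = 6, extent = 20)
  mesh <- cd$geometry$white
  nv <- n_vertices(mesh)
  v <- mesh$vertices
  disc <- which(sqrt((v[, 1] - 10)^2 + (v[, 2] - 10)^2) <= 5)
  asd <- cd$cohort$group == "ASD"
  set.seed(30)
  Y <- smooth_noise_maps(mesh, nrow(cd$X), fwhm = 6)
  Y[asd, disc] <- Y[asd, disc] + 2
  r1 <- permutation_cluster_test(Y, cd$X, "group", mesh, n_perm = 120,
                                 seed = 99)
  r2 <- permutation_cluster_test(Y, cd$X, "group", mesh, n_perm = 120,
                                 seed = 99)
  expect_identical(r1$clusters$p_perm, r2$clusters$p_perm)
  expect_identical(r1$max_null, r2$max_null)
  expect_true(any(r1$clusters$p_perm <= 0.05))
  expect_gt(min(r1$clusters$p_perm), 0)
  expect_warning(
    permutation_cluster_test(Y, cd$X, "group", mesh, n_perm = 50,
                             seed = 1), "n_perm")
})
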