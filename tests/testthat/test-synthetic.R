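test_that("slab template geometry matches its construction", {
  spec <- synthetic_spec(mesh_extent_mm = 20, vertex_spacing_mm = 1,
                         thickness_mean = 2.5, thickness_sd = 0,
                         effect_list = list())
  geo <- make_template_geometry(spec)
  expect_equal(nrow(geo$white$vertices), 441L)
  expect_true(all(geo$white$vertices[, 3] == 0))
  d <- sqrt(rowSums((geo$pial$vertices - geo$white$vertices)^2))
  expect_equal(d, rep(2.5, 441))
  expect_error(synthetic_spec(vertex_spacing_mm = 0), "> 0")
  expect_error(synthetic_spec(n_per_cell = 1), ">= 2")
})

test_that("sphere template normals are radial and thickness is honored", {
  spec <- synthetic_spec(mesh_kind = "sphere", mesh_extent_mm = 50,
                         vertex_spacing_mm = 26, thickness_mean = 2.5,
                         thickness_sd = 0, effect_list = list())
  geo <- make_template_geometry(spec)
  nrm <- compute_vertex_normals(geo$white)
  radial <- geo$white$vertices /
    sqrt(rowSums(geo$white$vertices^2))
  expect_lt(max(abs(nrm - radial)), 1e-6)
  d <- sqrt(rowSums((geo$pial$vertices - geo$white$vertices)^2))
  expect_equal(d, rep(2.5, nrow(radial)), tolerance = 1e-12)
})

test_that("per-vertex thickness reproduces the requested distribution", {
  spec <- synthetic_spec(mesh_extent_mm = 40, thickness_mean = 2.67,
                         thickness_sd = 0.1, effect_list = list(),
                         seed = 5)
  geo <- make_template_geometry(spec)
  d <- sqrt(rowSums((geo$pial$vertices - geo$white$vertices)^2))
  sem <- 0.1 / sqrt(length(d))
  expect_lt(abs(mean(d) - 2.67), 3 * sem)
  expect_gt(sd(d), 0.05)
})

test_that("noise-free volumes hit the tissue plateaus at the sampled depths", {
  spec <- synthetic_spec(effect_list = list(), thickness_sd = 0)
  geo <- make_template_geometry(spec)
  vols <- simulate_subject_volumes(geo, spec,
                                   list(group = "TD", sex = "male"),
                                   seed = 1, noise = FALSE)
  nrm <- compute_vertex_normals(geo$white)
  wm <- sample_absolute_depth(geo$white, nrm, vols$T1I, -1)
  gm <- sample_projection_fraction(geo$white, geo$pial, vols$T1I, 0.6)
  expect_lt(max(abs(wm$values - 110)) / 110, 0.01)
  expect_lt(max(abs(gm$values - 90)) / 90, 0.01)
})

test_that("same cell and seed give identical volumes (determinism)", {
  spec <- null_spec(extent = 10, seed = 2)
  geo <- make_template_geometry(spec)
  v1 <- simulate_subject_volumes(geo, spec,
                                 list(group = "ASD", sex = "female"),
                                 seed = 77)
  v2 <- simulate_subject_volumes(geo, spec,
                                 list(group = "ASD", sex = "female"),
                                 seed = 77)
  expect_identical(v1$FA$data, v2$FA$data)
  expect_identical(v1$MD$data, v2$MD$data)
  v3 <- simulate_subject_volumes(geo, spec,
                                 list(group = "ASD", sex = "female"),
                                 seed = 78)
  expect_false(identical(v1$FA$data, v3$FA$data))
})

test_that("planted FA group effect is recovered in the sample mean", {
  spec <- synthetic_spec(n_per_cell = 5L, dose_sd = 0, seed = 9)
  sim <- simulate_cohort(spec)
  geo <- sim$geometry
  nrm <- compute_vertex_normals(geo$white)
  disc <- sim$truth[[1]]$vertices
  expect_gt(length(disc), 0)
  disc_means <- vapply(seq_len(nrow(sim$cohort)), function(s) {
    vols <- simulate_subject_volumes(
      geo, spec,
      list(group = sim$cohort$group[s], sex = sim$cohort$sex[s]),
      seed = boundaryprofile:::substream_seed(
        spec$seed, paste0("subject-", sim$cohort$id[s])),
      dose = 1)
    m <- sample_absolute_depth(geo$white, nrm, vols$FA, 0)
    mean(m$values[disc])
  }, numeric(1))
  td <- sim$cohort$group == "TD"
  diff_obs <- mean(disc_means[td]) - mean(disc_means[!td])
  sem <- sqrt(var(disc_means[td]) / sum(td) +
                var(disc_means[!td]) / sum(!td))
  expect_lt(abs(diff_obs - 0.05), 3 * sem)
})

test_that("cohort structure, ages, FSIQ and clinical correlation", {
  spec <- synthetic_spec(n_per_cell = 20L, clinical_r = 0.6, seed = 4)
  sim <- simulate_cohort(spec)
  co <- sim$cohort
  expect_equal(nrow(co), 160L)
  expect_equal(as.integer(table(co$group)), c(80L, 80L))
  expect_true(all(co$age >= 18 & co$age <= 52))
  expect_lt(abs(mean(co$fsiq) - 115), 3 * 11 / sqrt(160))
  asd <- co$group == "ASD"
  r_hat <- cor(co$aq[asd], co$dose[asd])
  expect_gt(r_hat, 0.4)
  expect_lt(r_hat, 0.75)

  spec0 <- synthetic_spec(n_per_cell = 20L, clinical_r = 0, seed = 4)
  co0 <- simulate_cohort(spec0)$cohort
  asd0 <- co0$group == "ASD"
  expect_lt(abs(cor(co0$aq[asd0], co0$dose[asd0])), 0.3)
})

test_that("balanced cohorts give null demographic group tests", {
  n_ok <- 0L
  for (s in 1:100) {
    co <- simulate_cohort(null_spec(n_per_cell = 5L, seed = s))$cohort
    tt <- demographics_tests(co)
    if (abs(tt$statistic[tt$variable == "age"]) < 2) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 95L)
})

test_that("simulated data set writes and reloads consistently", {
  spec <- synthetic_spec(n_per_cell = 2L, mesh_extent_mm = 8,
                         effect_list = list(), seed = 6)
  dir <- withr::local_tempdir()
  cohort <- simulate_to_dir(spec, dir)
  expect_true(file.exists(file.path(dir, "white.surf")))
  rt <- read_cohort(file.path(dir, "cohort.tsv"))
  expect_equal(rt$id, cohort$id)
  expect_equal(rt$age, cohort$age, tolerance = 1e-6)
  vol <- read_volume(file.path(dir, rt$path_FA[1]))
  geo <- make_template_geometry(spec)
  ref <- simulate_subject_volumes(
    geo, spec, list(group = rt$group[1], sex = rt$sex[1]),
    seed = boundaryprofile:::substream_seed(
      spec$seed, paste0("subject-", rt$id[1])),
    dose = rt$dose[1])
  expect_lt(max(abs(vol$data - ref$FA$data)), 1e-5)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(length(truth), 0L)  # null spec has no planted effects
})
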