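test_that("design matrix: coding, centering, orthogonality, rank", {
  # balanced 2x2x2 toy cohort
  co <- expand.grid(group = c("ASD", "TD"), sex = c("male", "female"),
                    site = c("A", "B"), stringsAsFactors = FALSE)
  co$id <- sprintf("S%d", 1:8)
  co$age <- c(20, 30, 25, 35, 22, 28, 41, 19)
  co$fsiq <- c(100, 110, 120, 105, 95, 115, 108, 111)
  X <- build_design(validate_cohort(co))
  expect_identical(colnames(X),
                   c("(Intercept)", "group", "sex", "group_x_sex",
                     "site", "age", "age2", "fsiq"))
  expect_equal(sum(X[, "group"] * X[, "sex"]), 0)      # balance
  expect_lt(abs(sum(X[, "age"])), 1e-9)                # centering
  expect_lt(abs(sum(X[, "age2"])), 1e-9)
  expect_lt(abs(sum(X[, "fsiq"])), 1e-9)
  expect_equal(qr(X)$rank, 8L)

  # the study's cell counts: 53/39 ASD, 51/41 TD males/females
  cells <- data.frame(
    group = rep(c("ASD", "TD"), times = c(92, 92)),
    sex = c(rep("male", 53), rep("female", 39),
            rep("male", 51), rep("female", 41)))
  cells$site <- rep(c("A", "B"), length.out = 184)
  cells$id <- sprintf("P%03d", 1:184)
  set.seed(10)
  cells$age <- runif(184, 18, 52)
  cells$fsiq <- rnorm(184, 115, 11)
  Xp <- build_design(validate_cohort(cells))
  expect_lt(kappa(scale(Xp, center = FALSE), exact = TRUE), 100)

  single_sex <- co[co$sex == "male", ]
  expect_error(build_design(single_sex), "single level")
})

test_that("OLS fit: exact recovery, residual orthogonality, brute-force match", {
  cd <- make_cohort_design(n_per_cell = 3L, seed = 2)
  X <- cd$X
  n <- nrow(X)
  set.seed(4)
  beta_true <- matrix(rnorm(ncol(X) * 30), ncol(X), 30)
  Y <- X %*% beta_true
  fit <- fit_vertex_glm(Y, X)
  expect_lt(max(abs(fit$coefficients - beta_true)), 1e-9)

  Yn <- Y + matrix(rnorm(n * 30), n, 30)
  fitn <- fit_vertex_glm(Yn, X)
  expect_lt(max(abs(crossprod(X, fitn$residuals))), 1e-8)

  # brute-force normal equations, vertex by vertex
  for (v in sample(30, 5)) {
    bf <- solve(t(X) %*% X, t(X) %*% Yn[, v])
    expect_lt(max(abs(fitn$coefficients[, v] - bf)), 1e-8)
  }

  # a vertex with NaN data is masked, not a global failure
  Yn[3, 7] <- NaN
  fit2 <- fit_vertex_glm(Yn, X)
  expect_false(fit2$valid[7])
  expect_true(all(fit2$valid[-7]))
})

test_that("null group t-map follows Student t and holds its size", {
  cd <- make_cohort_design(n_per_cell = 5L, seed = 3)
  n <- nrow(cd$X)
  set.seed(5)
  Y <- matrix(rnorm(n * 20000), n, 20000)
  fit <- fit_vertex_glm(Y, cd$X)
  tm <- contrast_t(fit, "group")
  ks <- suppressWarnings(
    stats::ks.test(tm$map$values, function(q) pt(q, tm$df)))
  expect_gt(ks$p.value, 0.01)
  alpha_hat <- mean(abs(tm$map$values) > qt(0.975, tm$df))
  expect_gt(alpha_hat, 0.04)
  expect_lt(alpha_hat, 0.06)
})

test_that("contrast t: sign equivariance and a hand-computed example", {
  # 6-point regression, hand-computable via normal equations
  x <- c(-1, -1, 0, 0, 1, 1)
  X <- cbind(`(Intercept)` = 1, slope = x)
  y <- c(1.2, 0.8, 2.1, 1.9, 3.2, 2.8)
  fit <- fit_vertex_glm(matrix(y), X)
  bf_beta <- solve(t(X) %*% X, t(X) %*% y)
  bf_res <- y - X %*% bf_beta
  bf_s2 <- sum(bf_res^2) / (6 - 2)
  bf_t <- bf_beta[2] / sqrt(bf_s2 * solve(t(X) %*% X)[2, 2])
  tm <- contrast_t(fit, "slope")
  expect_lt(abs(tm$map$values - bf_t), 1e-9)

  Xf <- X
  Xf[, 2] <- -Xf[, 2]
  tf <- contrast_t(fit_vertex_glm(matrix(y), Xf), "slope")
  expect_equal(tf$map$values, -tm$map$values, tolerance = 1e-12)
  expect_error(contrast_t(fit, "not_a_column"), "unknown")
  expect_error(contrast_t(fit, c(1, 0, 0)), "length")
})

test_that("planted group effect elevates |t| inside its region", {
  cd <- make_cohort_design(n_per_cell = 10L, seed = 6)   # 40/group
  mesh <- cd$geometry$white
  nv <- n_vertices(mesh)
  v <- mesh$vertices
  disc <- which(sqrt((v[, 1] - 10)^2 + (v[, 2] - 10)^2) <= 5)
  asd <- cd$cohort$group == "ASD"
  set.seed(7)
  Y <- matrix(rnorm(nrow(cd$X) * nv), nrow(cd$X), nv)
  Y[asd, disc] <- Y[asd, disc] + 1
  fit <- fit_vertex_glm(Y, cd$X)
  tm <- contrast_t(fit, "group")
  expect_gt(mean(abs(tm$map$values[disc])),
            mean(abs(tm$map$values[-disc])))
  # effect coding: beta_group = half the group difference
  recovered <- mean(fit$coefficients["group", disc])
  expect_lt(abs(recovered - 0.5) / 0.5, 0.2)
})

test_that("nested F: zero column, null distribution, t^2 identity, truth", {
  cd <- make_cohort_design(n_per_cell = 5L, seed = 8)
  X <- cd$X
  n <- nrow(X)
  set.seed(9)
  Y <- matrix(rnorm(n * 5000), n, 5000)

  # adding an all-zeros column changes nothing
  Xz <- cbind(X, zero = 0)
  Fz <- nested_f_test(Y[, 1:200], X, Xz)
  expect_lt(max(Fz$map$values, na.rm = TRUE), 1e-9)

  # irrelevant random column on null data: F(1, df)
  Xr <- cbind(X, rnd = rnorm(n))
  Fr <- nested_f_test(Y, X, Xr)
  ks <- suppressWarnings(
    stats::ks.test(Fr$map$values, function(q) pf(q, 1, Fr$df)))
  expect_gt(ks$p.value, 0.01)

  # t^2 for a single added column equals the nested F
  X0 <- X[, setdiff(colnames(X), "group_x_sex")]
  Fnest <- nested_f_test(Y[, 1:500], X0, X)
  tint <- contrast_t(fit_vertex_glm(Y[, 1:500], X), "group_x_sex")
  expect_lt(max(abs(tint$map$values^2 - Fnest$map$values)), 1e-9)

  # planted interaction: median F in the region beats the null 95th pct
  cd2 <- make_cohort_design(n_per_cell = 10L, seed = 10)
  mesh <- cd2$geometry$white
  v <- mesh$vertices
  disc <- which(sqrt((v[, 1] - 10)^2 + (v[, 2] - 10)^2) <= 5)
  gs <- ifelse(cd2$cohort$group == "ASD", 1, -1) *
    ifelse(cd2$cohort$sex == "male", 1, -1)
  set.seed(11)
  Y2 <- matrix(rnorm(nrow(cd2$X) * n_vertices(mesh)), nrow(cd2$X),
               n_vertices(mesh))
  Y2[, disc] <- Y2[, disc] + gs
  X0b <- cd2$X[, setdiff(colnames(cd2$X), "group_x_sex")]
  Fb <- nested_f_test(Y2, X0b, cd2$X)
  expect_gt(median(Fb$map$values[disc]), qf(0.95, 1, Fb$df))

  expect_error(nested_f_test(Y, Xr, X), "not nested")
})
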