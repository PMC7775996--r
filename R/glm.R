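DESIGN_COLUMNS <- c("(Intercept)", "group", "sex", "group_x_sex", "site",
                    "age", "age2", "fsiq")

#' Build the vertex-wise design matrix
#'
#' Implements the cohort model
#' `Y = b0 + b1 Group + b2 Sex + b3 Group:Sex + b4 Site + b5 Age +
#'  b6 Age^2 + b7 FSIQ + e`
#' with effect (-1/+1) codes for the categorical factors (ASD/male/site-A
#' coded +1), so the group coefficient is half the adjusted group
#' difference and the interaction coefficient is directly interpretable in
#' the presence of main effects. All continuous covariates are mean
#' centered across the full sample; the quadratic age term is the square
#' of centered age, itself centered, to limit collinearity. Centering
#' constants are recorded as the `"centers"` attribute.
#'
#' @param cohort a `cohort_table`.
#' @param extra_covariates names of additional numeric cohort columns to
#'   append (mean centered), e.g. `"bdi"` for the depression-covaried
#'   robustness model.
#' @return design matrix with a `"centers"` attribute, full column rank.
#' @export
build_design <- function(cohort, extra_covariates = NULL) {
  cohort <- validate_cohort(as.data.frame(cohort))
  code2 <- function(x, pos) ifelse(x == pos, 1, -1)
  grp <- code2(cohort$group, "ASD")
  sex <- code2(cohort$sex, "male")
  site <- code2(cohort$site, sort(unique(cohort$site))[1])
  age_c <- cohort$age - mean(cohort$age)
  age2 <- age_c^2 - mean(age_c^2)
  fsiq_c <- cohort$fsiq - mean(cohort$fsiq)
  X <- cbind(1, grp, sex, grp * sex, site, age_c, age2, fsiq_c)
  colnames(X) <- DESIGN_COLUMNS
  centers <- c(age = mean(cohort$age), age2 = mean(age_c^2),
               fsiq = mean(cohort$fsiq))
  for (cv in extra_covariates) {
    v <- cohort[[cv]]
    if (is.null(v) || !is.numeric(v))
      stop_fmt("design_error", "covariate '%s' missing or non-numeric", cv)
    X <- cbind(X, v - mean(v))
    colnames(X)[ncol(X)] <- cv
    centers[cv] <- mean(v)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_fmt("design_error", "design is rank deficient; collinear: %s",
             paste(dropped, collapse = ", "))
  }
  attr(X, "centers") <- centers
  X
}

#' Fit the vertex-wise general linear model
#'
#' Ordinary least squares at every vertex of a subject-by-vertex data
#' matrix, sharing one design across vertices. Vertices with any
#' non-finite observation (or zero residual variance) are masked, not a
#' global failure. Residuals are retained for smoothness estimation.
#'
#' @param Y numeric matrix, subjects x vertices, rows in cohort order.
#' @param X design matrix from [build_design()].
#' @return an object of class `vertex_glm`: coefficients (p x V),
#'   `sigma2`, residual `df`, residual matrix, the design, and the vertex
#'   validity mask.
#' @export
fit_vertex_glm <- function(Y, X) {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X))
    stop_fmt("design_error", "Y rows (%d) do not match design rows (%d)",
             nrow(Y), nrow(X))
  p <- ncol(X)
  qrX <- qr(X)
  df <- nrow(X) - qrX$rank
  if (df <= 0) stop_fmt("design_error", "no residual degrees of freedom")
  valid <- colSums(!is.finite(Y)) == 0L
  # Moore-Penrose pseudo-inverse of X'X, so aliased columns (rank-deficient
  # designs, e.g. inside nested comparisons) yield minimum-norm solutions
  # instead of a hard failure.
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-12
  XtXinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$v[, pos, drop = FALSE]) / sv$d[pos]^2)
  beta <- matrix(NA_real_, p, ncol(Y),
                 dimnames = list(colnames(X), colnames(Y)))
  resid <- matrix(NA_real_, nrow(Y), ncol(Y))
  if (any(valid)) {
    B <- XtXinv %*% crossprod(X, Y[, valid, drop = FALSE])
    beta[, valid] <- B
    resid[, valid] <- Y[, valid, drop = FALSE] - X %*% B
  }
  sigma2 <- colSums(resid^2) / df
  structure(list(coefficients = beta, sigma2 = sigma2, df = df,
                 residuals = resid, X = X, XtXinv = XtXinv,
                 valid = valid, n = nrow(Y)),
            class = "vertex_glm")
}

#' @export
print.vertex_glm <- function(x, ...) {
  cat(sprintf(
    "vertex_glm: %d subjects, %d vertices (%d valid), %d terms, df = %d\n",
    x$n, length(x$valid), sum(x$valid), nrow(x$coefficients), x$df))
  cat("terms:", paste(rownames(x$coefficients), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.vertex_glm <- function(object, ...) object$coefficients

#' @export
residuals.vertex_glm <- function(object, ...) object$residuals

#' @export
summary.vertex_glm <- function(object, ...) {
  s2 <- object$sigma2[object$valid]
  out <- list(
    n = object$n, df = object$df,
    n_vertices = length(object$valid), n_valid = sum(object$valid),
    mean_coef = rowMeans(object$coefficients[, object$valid,
                                             drop = FALSE]),
    sigma = sqrt(c(min = min(s2), median = median(s2), max = max(s2))))
  class(out) <- "summary.vertex_glm"
  out
}

#' @export
print.summary.vertex_glm <- function(x, ...) {
  cat(sprintf("vertex GLM: n = %d subjects, residual df = %d, %d/%d vertices\n",
              x$n, x$df, x$n_valid, x$n_vertices))
  cat("mean coefficient across valid vertices:\n")
  print(signif(x$mean_coef, 4))
  cat("residual SD (min/median/max):",
      paste(signif(x$sigma, 4), collapse = " / "), "\n")
  invisible(x)
}

#' Contrast t-map
#'
#' `t = c'beta / se(c'beta)` per vertex, with the fit's residual degrees of
#' freedom. The group difference map is the `"group"` contrast; the
#' group-by-sex interaction map is `"group_x_sex"`.
#'
#' @param fit a [fit_vertex_glm()] object.
#' @param contrast a design column name or a numeric contrast vector of
#'   length `ncol(X)`.
#' @return object of class `stat_map`: a t-valued [vertex_map()] plus `df`
#'   and the contrast description.
#' @export
contrast_t <- function(fit, contrast) {
  X <- fit$X
  if (is.character(contrast)) {
    if (!contrast %in% colnames(X))
      stop_fmt("usage_error", "unknown design column '%s'", contrast)
    cv <- as.numeric(colnames(X) == contrast)
    label <- contrast
  } else {
    cv <- as.numeric(contrast)
    if (length(cv) != ncol(X))
      stop_fmt("usage_error", "contrast length %d != %d design columns",
               length(cv), ncol(X))
    label <- paste(cv, collapse = ",")
  }
  var_scale <- as.numeric(t(cv) %*% fit$XtXinv %*% cv)
  se <- sqrt(var_scale * fit$sigma2)
  tval <- as.numeric(crossprod(cv, fit$coefficients)) / se
  valid <- fit$valid & is.finite(tval) & fit$sigma2 > 0
  structure(list(map = vertex_map(ifelse(valid, tval, NA_real_), valid,
                                  modality = "t"),
                 df = fit$df, contrast = label, stat = "t"),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  if (x$stat == "t") {
    cat(sprintf("stat_map: t(%d), contrast '%s'\n", x$df, x$contrast))
  } else {
    cat(sprintf("stat_map: F(%d, %d), '%s'\n", x$df1, x$df, x$contrast))
  }
  print(x$map)
  invisible(x)
}

#' Vertex-wise F-test for nested model comparison
#'
#' Step-up comparison of a reduced against a full design containing it:
#' `F = ((RSS_r - RSS_f) / q) / (RSS_f / df_f)` per vertex, with q the
#' number of added columns. Used to decide whether adding a term (the
#' group-by-sex interaction, BDI, ...) improves the vertex-wise fit.
#'
#' @param Y subjects x vertices data matrix.
#' @param X_reduced,X_full design matrices; the reduced columns must be a
#'   subset of the full columns (by name).
#' @return object of class `stat_map` with `stat = "F"`, df pair
#'   `(df1, df)`.
#' @export
nested_f_test <- function(Y, X_reduced, X_full) {
  if (is.null(colnames(X_reduced)) || is.null(colnames(X_full)) ||
      !all(colnames(X_reduced) %in% colnames(X_full)))
    stop_fmt("usage_error",
             "designs are not nested (reduced columns not in full)")
  fit_r <- fit_vertex_glm(Y, X_reduced)
  fit_f <- fit_vertex_glm(Y, X_full)
  q <- ncol(X_full) - ncol(X_reduced)
  if (q < 1L)
    stop_fmt("usage_error", "full design adds no columns")
  rss_r <- colSums(fit_r$residuals^2)
  rss_f <- colSums(fit_f$residuals^2)
  df_f <- fit_f$df
  Fval <- pmax(0, (rss_r - rss_f) / q) / (rss_f / df_f)
  valid <- fit_f$valid & is.finite(Fval)
  structure(list(map = vertex_map(ifelse(valid, Fval, NA_real_), valid,
                                  modality = "F"),
                 df1 = q, df = df_f,
                 contrast = paste(setdiff(colnames(X_full),
                                          colnames(X_reduced)),
                                  collapse = "+"),
                 stat = "F"),
            class = "stat_map")
}
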