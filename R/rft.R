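#' Estimate residual smoothness (local FWHM, resels)
#'
#' Nonisotropic smoothness estimation from normalized GLM residuals: for
#' every mesh edge the squared gradient of the normalized residual field
#' is `sum_subj (u_i - u_j)^2 / |e|^2`, and the local FWHM follows the
#' Gaussian-field relation `FWHM = sqrt(4 log 2 / grad^2)`. Resels
#' (resolution elements) per triangle are `area / FWHM^2`; each vertex is
#' assigned a third of every incident triangle's resels and area, so
#' cluster extents can be accumulated vertex-wise in resel units (this is
#' what makes the cluster correction valid under spatially varying
#' smoothness).
#'
#' @param fit a [fit_vertex_glm()] object (residuals retained).
#' @param mesh the template [surface_mesh()].
#' @return object of class `smoothness_estimate`: per-vertex FWHM (mm),
#'   per-vertex resel and area shares, `total_resels`, `total_area`,
#'   `global_fwhm`, boundary resel counts `resels1`, `resels0`.
#' @export
estimate_smoothness <- function(fit, mesh) {
  if (fit$df <= 1) stop_fmt("inference_error", "need residual df > 1")
  n <- n_vertices(mesh)
  R <- fit$residuals
  norms <- sqrt(colSums(R^2))
  valid <- fit$valid & norms > 0
  u <- sweep(R, 2, pmax(norms, 1e-300), "/")
  e <- mesh_edges(mesh)
  keep <- valid[e[, 1]] & valid[e[, 2]]
  dot <- rep(NA_real_, nrow(e))
  dot[keep] <- colSums(u[, e[keep, 1], drop = FALSE] *
                         u[, e[keep, 2], drop = FALSE])
  dv <- mesh$vertices[e[, 1], , drop = FALSE] -
    mesh$vertices[e[, 2], , drop = FALSE]
  len2 <- rowSums(dv^2)
  # squared gradient of the unit-variance field along each edge
  g_edge <- pmax(2 * (1 - dot), 1e-12) / len2
  # per-vertex mean squared gradient over incident valid edges
  gv_sum <- rowsum_safe(c(g_edge[keep], g_edge[keep]),
                        c(e[keep, 1], e[keep, 2]), n)
  gv_cnt <- rowsum_safe(rep(1, 2 * sum(keep)),
                        c(e[keep, 1], e[keep, 2]), n)
  g_vertex <- ifelse(gv_cnt > 0, gv_sum / pmax(gv_cnt, 1), NA_real_)
  vertex_fwhm <- sqrt(4 * log(2) / g_vertex)
  # per-triangle resels from its three edges
  f <- mesh$faces
  ekey <- (pmin(e[, 1], e[, 2]) - 1) * n + pmax(e[, 1], e[, 2])
  g_lookup <- g_edge
  names(g_lookup) <- as.character(ekey)
  tri_edge_key <- function(a, b)
    as.character((pmin(a, b) - 1) * n + pmax(a, b))
  g_tri <- (g_lookup[tri_edge_key(f[, 1], f[, 2])] +
              g_lookup[tri_edge_key(f[, 2], f[, 3])] +
              g_lookup[tri_edge_key(f[, 3], f[, 1])]) / 3
  v <- mesh$vertices
  cr <- cross3(v[f[, 2], ] - v[f[, 1], ], v[f[, 3], ] - v[f[, 1], ])
  area_tri <- 0.5 * sqrt(rowSums(cr^2))
  tri_valid <- valid[f[, 1]] & valid[f[, 2]] & valid[f[, 3]] &
    is.finite(g_tri)
  resel_tri <- ifelse(tri_valid, area_tri * g_tri / (4 * log(2)), 0)
  area_tri_v <- ifelse(tri_valid, area_tri, 0)
  vertex_resel <- numeric(n)
  vertex_area <- numeric(n)
  for (corner in 1:3) {
    vertex_resel <- vertex_resel +
      rowsum_safe(resel_tri / 3, f[, corner], n)
    vertex_area <- vertex_area +
      rowsum_safe(area_tri_v / 3, f[, corner], n)
  }
  total_resels <- sum(resel_tri)
  total_area <- sum(area_tri_v)
  if (total_resels <= 0)
    stop_fmt("inference_error", "no valid triangles for smoothness")
  global_fwhm <- sqrt(total_area / total_resels)
  # boundary (perimeter) resels for the unified expected-EC formula
  edge_face_count <- table(c(tri_edge_key(f[, 1], f[, 2]),
                             tri_edge_key(f[, 2], f[, 3]),
                             tri_edge_key(f[, 3], f[, 1])))
  bkey <- names(edge_face_count)[edge_face_count == 1]
  blen <- sqrt(len2[match(bkey, as.character(ekey))])
  perimeter <- sum(blen, na.rm = TRUE)
  structure(list(vertex_fwhm = vertex_fwhm, vertex_resel = vertex_resel,
                 vertex_area = vertex_area, total_resels = total_resels,
                 total_area = total_area, global_fwhm = global_fwhm,
                 resels1 = 0.5 * perimeter / global_fwhm,
                 resels0 = if (perimeter > 0) 1 else 2),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf(
    "smoothness_estimate: global FWHM %.2f mm, %.2f resels over %.1f mm^2\n",
    x$global_fwhm, x$total_resels, x$total_area))
  invisible(x)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Connected components of a vertex subset in mesh adjacency (igraph).
# Returns an integer membership vector over `idx`.
component_membership <- function(idx, edges) {
  if (length(idx) == 0L) return(integer(0))
  pos <- integer(max(idx))
  pos[idx] <- seq_along(idx)
  keep <- edges[, 1] %in% idx & edges[, 2] %in% idx
  es <- edges[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(es) > 0)
    g <- igraph::add_edges(g, rbind(pos[es[, 1]], pos[es[, 2]]))
  igraph::components(g)$membership
}

#' Suprathreshold clusters of a statistic map
#'
#' Thresholds a t-map at the cluster-defining threshold (CDT), two-tailed:
#' vertices with `t >= t_cdt` and `t <= -t_cdt` form separate positive and
#' negative excursion sets, each decomposed into connected components in
#' mesh adjacency. Extents are reported in vertices, mm^2 and resels
#' (local-FWHM-normalized, which is how nonisotropy is handled).
#'
#' @param stat a `stat_map` from [contrast_t()].
#' @param mesh the template [surface_mesh()].
#' @param smoothness a [estimate_smoothness()] result.
#' @param cdt_p cluster-defining threshold as a two-tailed p-value
#'   (default 0.001).
#' @return a `cluster_table` data.frame: `cluster_id`, `sign`,
#'   `n_vertices`, `area_mm2`, `resels`, `peak_t`, `peak_vertex`,
#'   `p_rft` (filled by [rft_cluster_p()]), and a `vertices` list column.
#' @export
define_clusters <- function(stat, mesh, smoothness, cdt_p = 0.001) {
  if (cdt_p <= 0 || cdt_p >= 1)
    stop_fmt("parameter_error", "cdt_p must be in (0, 1)")
  if (stat$stat != "t")
    stop_fmt("usage_error",
             "cluster definition expects a t map (q = 1 F-tests are t^2)")
  t_cdt <- stats::qt(1 - cdt_p / 2, stat$df)
  vals <- stat$map$values
  edges <- mesh_edges(mesh)
  rows <- list()
  for (sgn in c(1, -1)) {
    idx <- which(stat$map$valid & sgn * vals >= t_cdt)
    if (!length(idx)) next
    memb <- component_membership(idx, edges)
    for (m in sort(unique(memb))) {
      vs <- idx[memb == m]
      pk <- vs[which.max(sgn * vals[vs])]
      rows[[length(rows) + 1L]] <- data.frame(
        sign = if (sgn > 0) "positive" else "negative",
        n_vertices = length(vs),
        area_mm2 = sum(smoothness$vertex_area[vs]),
        resels = sum(smoothness$vertex_resel[vs]),
        peak_t = vals[pk], peak_vertex = pk, p_rft = NA_real_)
      rows[[length(rows)]]$vertices <- I(list(vs))
    }
  }
  if (!length(rows)) {
    out <- empty_cluster_table()
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(-out$resels), , drop = FALSE]
    out <- cbind(cluster_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
  }
  attr(out, "cdt_p") <- cdt_p
  attr(out, "df") <- stat$df
  class(out) <- c("cluster_table", "data.frame")
  out
}

empty_cluster_table <- function() {
  out <- data.frame(cluster_id = integer(0), sign = character(0),
                    n_vertices = integer(0), area_mm2 = numeric(0),
                    resels = numeric(0), peak_t = numeric(0),
                    peak_vertex = integer(0), p_rft = numeric(0))
  out$vertices <- I(list())
  out
}

# Expected-EC densities of a t field at threshold t0 (2D search space).
ec_density_t <- function(t0, df) {
  f1 <- (1 + t0^2 / df)^(-(df - 1) / 2)
  rho0 <- stats::pt(t0, df, lower.tail = FALSE)
  rho1 <- sqrt(4 * log(2)) / (2 * pi) * f1
  rho2 <- 4 * log(2) / (2 * pi)^(3 / 2) *
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2) * t0 * f1
  c(rho0 = rho0, rho1 = rho1, rho2 = rho2)
}

#' RFT cluster-level corrected p-value
#'
#' Corrected p for a cluster of a given resel extent on a 2D random
#' t-field: the expected number of clusters per tail comes from the
#' expected Euler characteristic at the cluster-defining threshold
#' (including the boundary terms of the search region), cluster extents
#' are taken exponential with mean = expected suprathreshold resel mass /
#' expected cluster count, and the family-wise p is the Poisson-clumping
#' probability of at least one cluster this large across both tails.
#'
#' @param extent_resels cluster extent in resels.
#' @param total_resels 2D resels of the search region.
#' @param cdt_p two-tailed cluster-defining threshold p.
#' @param df residual degrees of freedom (> 2).
#' @param resels1,resels0 boundary / topological resel counts of the
#'   search region (defaults: no boundary term).
#' @param two_tailed count clusters of both signs (default `TRUE`).
#' @return corrected p-value in (0, 1].
#' @export
rft_cluster_p <- function(extent_resels, total_resels, cdt_p, df,
                          resels1 = 0, resels0 = 1, two_tailed = TRUE) {
  if (df <= 2) stop_fmt("inference_error", "need df > 2 for cluster RFT")
  if (any(extent_resels < 0) || total_resels <= 0 ||
      cdt_p <= 0 || cdt_p >= 1)
    stop_fmt("parameter_error", "invalid RFT inputs")
  t0 <- stats::qt(1 - cdt_p / 2, df)
  rho <- ec_density_t(t0, df)
  Em <- max(resels0 * rho["rho0"] + resels1 * rho["rho1"] +
              total_resels * rho["rho2"], 1e-12)
  En <- total_resels * rho["rho0"]
  mean_extent <- En / Em
  tails <- if (two_tailed) 2 else 1
  p <- -expm1(-tails * Em * exp(-extent_resels / mean_extent))
  unname(pmin(1, pmax(p, 0)))
}

#' Apply the RFT correction to a cluster table
#'
#' @param clusters a `cluster_table` from [define_clusters()].
#' @param smoothness the matching [estimate_smoothness()].
#' @return the table with `p_rft` filled in.
#' @export
rft_correct_clusters <- function(clusters, smoothness) {
  if (nrow(clusters) == 0L) return(clusters)
  clusters$p_rft <- rft_cluster_p(
    clusters$resels, smoothness$total_resels,
    attr(clusters, "cdt_p"), attr(clusters, "df"),
    resels1 = smoothness$resels1, resels0 = smoothness$resels0)
  clusters
}

#' Permutation (Freedman-Lane) cluster test
#'
#' Nonparametric oracle for the RFT correction: residuals of the reduced
#' model (the design without the tested column, so site/age/FSIQ structure
#' is respected) are permuted across subjects, the full model is refitted,
#' and the null distribution of the maximum suprathreshold cluster resel
#' extent (both tails) yields empirical family-wise corrected p-values.
#'
#' @param Y subjects x vertices data matrix.
#' @param X design from [build_design()].
#' @param contrast tested design column name.
#' @param mesh the template [surface_mesh()].
#' @param cdt_p two-tailed cluster-defining threshold p.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; results are seed-reproducible.
#' @return list with `clusters` (observed `cluster_table` with `p_perm`),
#'   `max_null` (permutation null of the max extent), `smoothness`.
#' @export
permutation_cluster_test <- function(Y, X, contrast, mesh,
                                     cdt_p = 0.001, n_perm = 500,
                                     seed = 1L) {
  if (n_perm < 100)
    warning("n_perm < 100: permutation p resolution is coarse")
  fit <- fit_vertex_glm(Y, X)
  sm <- estimate_smoothness(fit, mesh)
  tobs <- contrast_t(fit, contrast)
  clusters <- define_clusters(tobs, mesh, sm, cdt_p)
  X0 <- X[, setdiff(colnames(X), contrast), drop = FALSE]
  fit0 <- fit_vertex_glm(Y, X0)
  fitted0 <- Y - fit0$residuals
  t_cdt <- stats::qt(1 - cdt_p / 2, fit$df)
  edges <- mesh_edges(mesh)
  cv <- as.numeric(colnames(X) == contrast)
  var_scale <- as.numeric(t(cv) %*% fit$XtXinv %*% cv)
  XtXinvXt <- fit$XtXinv %*% t(X)
  max_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      Ystar <- fitted0 + fit0$residuals[sample.int(nrow(Y)), ,
                                        drop = FALSE]
      B <- XtXinvXt %*% Ystar
      res <- Ystar - X %*% B
      s2 <- colSums(res^2) / fit$df
      tv <- as.numeric(crossprod(cv, B)) / sqrt(var_scale * s2)
      tv[!fit$valid | !is.finite(tv)] <- 0
      mx <- 0
      for (sgn in c(1, -1)) {
        idx <- which(sgn * tv >= t_cdt)
        if (!length(idx)) next
        memb <- component_membership(idx, edges)
        ext <- rowsum_safe(sm$vertex_resel[idx], memb, max(memb))
        mx <- max(mx, ext)
      }
      mx
    }, numeric(1))
  })
  if (nrow(clusters) > 0L) {
    clusters$p_perm <- vapply(clusters$resels, function(s)
      (1 + sum(max_null >= s)) / (n_perm + 1), numeric(1))
  } else clusters$p_perm <- numeric(0)
  list(clusters = clusters, max_null = max_null, smoothness = sm)
}
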