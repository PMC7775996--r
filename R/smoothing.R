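#' Smooth a vertex map on the mesh to a target FWHM
#'
#' Iterated discrete heat diffusion on the mesh graph: per iteration every
#' vertex exchanges a fraction of its difference with each neighbour,
#' `x <- x + alpha * sum_j (x_j - x_i)`. The pair (iteration count, alpha)
#' is chosen from the mesh's edge lengths so that the accumulated kernel
#' variance matches the requested Gaussian FWHM (variance
#' `(fwhm / 2.3548)^2` per tangent axis); by the central limit theorem the
#' effective kernel is Gaussian after a few tens of iterations. The update
#' is symmetric, so the mean over valid vertices is conserved exactly and
#' the kernel is non-negative (`alpha <= 1/max degree`). Masked vertices
#' are excluded from the graph entirely, so no weight bleeds across the
#' mask (the remaining weights are implicitly renormalized).
#'
#' @param mesh the template [surface_mesh()].
#' @param map a [vertex_map()].
#' @param fwhm_mm target full width at half maximum in mm (0 = identity).
#' @return the smoothed [vertex_map()] (same mask).
#' @export
smooth_vertex_map <- function(mesh, map, fwhm_mm) {
  if (fwhm_mm < 0)
    stop_fmt("parameter_error", "fwhm_mm must be >= 0")
  if (length(map$values) != n_vertices(mesh))
    stop_fmt("geometry_error", "map does not match the mesh")
  if (fwhm_mm == 0) return(map)
  op <- smoothing_operator(mesh, fwhm_mm, valid = map$valid)
  x <- map$values
  x[!map$valid] <- 0
  for (it in seq_len(op$n_iter)) x <- as.numeric(op$S %*% x)
  x[!map$valid] <- NA_real_
  vertex_map(x, map$valid, mesh_id = map$mesh_id, modality = map$modality)
}

# One-step diffusion operator S = I - alpha * L_cot on the valid submesh,
# plus the iteration count needed for the target FWHM. Cotangent edge
# weights (clamped at 0) approximate the Laplace-Beltrami operator, so the
# effective kernel is isotropic on the sheet; uniform weights would make
# the diagonal edges of a gridded triangulation smear one diagonal
# direction more than the other.
smoothing_operator <- function(mesh, fwhm_mm, valid = NULL) {
  n <- n_vertices(mesh)
  if (is.null(valid)) valid <- rep(TRUE, n)
  f <- mesh$faces
  v <- mesh$vertices
  ew <- new.env(hash = FALSE)
  ekeys <- function(a, b) (pmin(a, b) - 1) * n + pmax(a, b)
  cot_opposite <- function(opp, a, b) {
    u <- v[a, , drop = FALSE] - v[opp, , drop = FALSE]
    w <- v[b, , drop = FALSE] - v[opp, , drop = FALSE]
    dot <- rowSums(u * w)
    crs <- sqrt(rowSums(cross3(u, w)^2))
    dot / pmax(crs, 1e-300)
  }
  key_all <- c(ekeys(f[, 1], f[, 2]), ekeys(f[, 2], f[, 3]),
               ekeys(f[, 3], f[, 1]))
  cot_all <- c(cot_opposite(f[, 3], f[, 1], f[, 2]),
               cot_opposite(f[, 1], f[, 2], f[, 3]),
               cot_opposite(f[, 2], f[, 3], f[, 1]))
  agg <- rowsum(cot_all / 2, group = key_all, reorder = FALSE)
  key_u <- as.numeric(rownames(agg))
  w_edge <- pmax(agg[, 1], 0)   # clamp obtuse-angle weights
  i_e <- floor((key_u - 1) / n) + 1
  j_e <- key_u - (i_e - 1) * n
  keep <- valid[i_e] & valid[j_e] & w_edge > 0
  i_e <- i_e[keep]; j_e <- j_e[keep]; w_edge <- w_edge[keep]
  dv <- v[i_e, , drop = FALSE] - v[j_e, , drop = FALSE]
  wlen2 <- w_edge * rowSums(dv^2)
  wdeg <- rowsum_safe(c(w_edge, w_edge), c(i_e, j_e), n)
  # per-iteration kernel variance per tangent axis (2D sheet):
  # alpha * mean_i sum_{j ~ i} w_ij |p_j - p_i|^2 / 2
  sum_wlen2 <- rowsum_safe(c(wlen2, wlen2), c(i_e, j_e), n)
  inner <- valid & wdeg > 0
  mean_wlen2 <- mean(sum_wlen2[inner]) / 2
  alpha0 <- 0.9 / max(wdeg)
  target_var <- (fwhm_mm / (2 * sqrt(2 * log(2))))^2
  v1_max <- alpha0 * mean_wlen2
  n_iter <- max(1L, ceiling(target_var / v1_max))
  alpha <- target_var / (n_iter * mean_wlen2)
  S <- Matrix::sparseMatrix(
    i = c(i_e, j_e, seq_len(n)),
    j = c(j_e, i_e, seq_len(n)),
    x = c(alpha * w_edge, alpha * w_edge, 1 - alpha * wdeg),
    dims = c(n, n))
  list(S = S, n_iter = n_iter, alpha = alpha)
}

rowsum_safe <- function(x, group, n) {
  out <- numeric(n)
  acc <- rowsum(x, group = group, reorder = FALSE)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Smooth every map of a depth profile (plus any extra maps)
#'
#' Convenience wrapper applying [smooth_vertex_map()] with one FWHM to all
#' maps of a [build_depth_profile()] result.
#'
#' @param mesh template [surface_mesh()].
#' @param profile a `depth_profile`.
#' @param fwhm_mm smoothing FWHM in mm.
#' @return the profile with smoothed maps (raw maps kept under `$raw`).
#' @export
smooth_depth_profile <- function(mesh, profile, fwhm_mm) {
  raw <- profile$maps
  profile$maps <- lapply(profile$maps, function(per_depth)
    lapply(per_depth, function(m) smooth_vertex_map(mesh, m, fwhm_mm)))
  profile$raw <- raw
  profile$fwhm_mm <- fwhm_mm
  profile
}
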