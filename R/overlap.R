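#' Binarize significant clusters into a vertex map
#'
#' 1 at every vertex belonging to a cluster whose corrected p is below
#' `alpha`, 0 elsewhere.
#'
#' @param clusters a `cluster_table` with `p_rft` (or `p_perm`) filled.
#' @param n_vertices template vertex count.
#' @param alpha cluster-corrected significance level (default 0.05).
#' @param p_column which corrected p column to use.
#' @return a [vertex_map()] with modality `"binary"`.
#' @export
binarize_significant <- function(clusters, n_vertices, alpha = 0.05,
                                 p_column = "p_rft") {
  vals <- numeric(n_vertices)
  if (nrow(clusters) > 0L) {
    sig <- which(!is.na(clusters[[p_column]]) &
                   clusters[[p_column]] < alpha)
    for (k in sig) vals[clusters$vertices[[k]]] <- 1
  }
  vertex_map(vals, rep(TRUE, n_vertices), modality = "binary")
}

#' Overlap of two binary vertex maps
#'
#' Counts and the overlap percentage
#' `100 * |A intersect B| / |denominator map|`. In the boundary analysis
#' the denominator is the diffusion-measure map (FA or MD), i.e. "out of
#' all vertices with a significant difference in FA, what share also shows
#' a GWC alteration".
#'
#' @param map_a,map_b binary [vertex_map()]s on the same mesh (or plain
#'   0/1 vectors).
#' @param denominator `"A"` or `"B"`: which map's count is the percentage
#'   denominator.
#' @return list: `n_vertices`, `count_a`, `count_b`, `count_intersection`,
#'   `percent_overlap`, `denominator`.
#' @export
overlap_summary <- function(map_a, map_b, denominator = c("B", "A")) {
  denominator <- match.arg(denominator)
  a <- binary_values(map_a)
  b <- binary_values(map_b)
  if (length(a) != length(b))
    stop_fmt("geometry_error", "maps are on different meshes (%d vs %d)",
             length(a), length(b))
  inter <- sum(a & b)
  denom_count <- if (denominator == "A") sum(a) else sum(b)
  if (denom_count == 0)
    stop_fmt("usage_error", "denominator map has no suprathreshold vertices")
  list(n_vertices = length(a), count_a = sum(a), count_b = sum(b),
       count_intersection = inter,
       percent_overlap = 100 * inter / denom_count,
       denominator = denominator)
}

binary_values <- function(m) {
  v <- if (inherits(m, "vertex_map")) m$values else as.numeric(m)
  v[is.na(v)] <- 0
  v != 0
}

#' Pairwise prevalence chi-square test
#'
#' Tests whether two measures' significant differences are equally
#' prevalent across the surface: a 2x2 table of (suprathreshold, not)
#' counts for the two maps, continuity-corrected (Yates) chi-square with
#' df = 1.
#'
#' @param count_a,count_b suprathreshold vertex counts of the two maps.
#' @param n_vertices total vertices per map.
#' @param correct apply the Yates continuity correction (default `TRUE`).
#' @return list: `chi2`, `df`, `p`.
#' @export
prevalence_chi2 <- function(count_a, count_b, n_vertices,
                            correct = TRUE) {
  if (count_a > n_vertices || count_b > n_vertices)
    stop_fmt("usage_error", "counts exceed the number of vertices")
  tab <- rbind(c(count_a, n_vertices - count_a),
               c(count_b, n_vertices - count_b))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    stop_fmt("usage_error", "chi-square undefined: zero marginal")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Simulation null for the overlap percentage
#'
#' Generates pairs of random vertex-wise difference maps, thresholds each,
#' and computes the percent overlap, yielding the null distribution under
#' spatial independence. Two modes:
#' \describe{
#'   \item{iid}{each vertex carries an independent standard-normal random
#'     "t-value", thresholded two-tailed at `threshold_p` (default 0.05).}
#'   \item{prevalence_matched}{each simulated map is a uniformly random
#'     vertex set of exactly the observed suprathreshold count, so only
#'     the spatial arrangement is randomized.}
#' }
#' The empirical exceedance probability is
#' `(1 + #\{sims >= observed\}) / (n_sims + 1)`.
#'
#' @param n_vertices vertices per map.
#' @param observed_percent observed overlap percentage to test (optional;
#'   without it only the null distribution is returned).
#' @param n_sims number of simulated map pairs (default 5000).
#' @param seed integer seed.
#' @param mode `"iid"` or `"prevalence_matched"`.
#' @param threshold_p two-tailed threshold for iid mode (default 0.05).
#' @param counts length-2 vector of observed suprathreshold counts
#'   (required for `prevalence_matched`; `counts[1]` is the GWC-like map,
#'   `counts[2]` the denominator/diffusion map).
#' @param denominator `"A"` or `"B"`: which simulated map's count divides
#'   the intersection (default `"B"`, matching [overlap_summary()]).
#' @return list: `sim_percent` (length `n_sims`), `sim_p` (if an observed
#'   percentage was given), `mode`, `seed`, `n_sims`.
#' @export
simulate_overlap_null <- function(n_vertices, observed_percent = NULL,
                                  n_sims = 5000, seed = 1L,
                                  mode = c("iid", "prevalence_matched"),
                                  threshold_p = 0.05, counts = NULL,
                                  denominator = "B") {
  mode <- match.arg(mode)
  if (n_sims < 1) stop_fmt("parameter_error", "n_sims must be >= 1")
  if (mode == "prevalence_matched" &&
      (is.null(counts) || length(counts) != 2))
    stop_fmt("usage_error",
             "prevalence_matched mode needs the two observed counts")
  zcrit <- qnorm(1 - threshold_p / 2)
  sim_percent <- with_seed(seed, {
    vapply(seq_len(n_sims), function(s) {
      if (mode == "iid") {
        a <- abs(rnorm(n_vertices)) >= zcrit
        b <- abs(rnorm(n_vertices)) >= zcrit
      } else {
        a <- logical(n_vertices)
        a[sample.int(n_vertices, counts[1])] <- TRUE
        b <- logical(n_vertices)
        b[sample.int(n_vertices, counts[2])] <- TRUE
      }
      denom <- if (denominator == "A") sum(a) else sum(b)
      if (denom == 0) 0 else 100 * sum(a & b) / denom
    }, numeric(1))
  })
  out <- list(sim_percent = sim_percent, mode = mode, seed = seed,
              n_sims = n_sims)
  if (!is.null(observed_percent)) {
    out$observed_percent <- observed_percent
    out$sim_p <- (1 + sum(sim_percent >= observed_percent)) / (n_sims + 1)
  }
  out
}

#' Full overlap analysis of two thresholded maps
#'
#' Combines [overlap_summary()], [prevalence_chi2()] and
#' [simulate_overlap_null()] into one record.
#'
#' @inheritParams overlap_summary
#' @param n_sims simulated map pairs for the null (default 5000).
#' @param seed integer seed for the simulation.
#' @param mode simulation mode, see [simulate_overlap_null()].
#' @return an `overlap_result` list with counts, percentage, chi-square
#'   and simulation p-value.
#' @export
overlap_analysis <- function(map_a, map_b, denominator = "B",
                             n_sims = 5000, seed = 1L, mode = "iid") {
  ov <- overlap_summary(map_a, map_b, denominator)
  chi <- prevalence_chi2(ov$count_a, ov$count_b, ov$n_vertices)
  sim <- simulate_overlap_null(
    ov$n_vertices, observed_percent = ov$percent_overlap,
    n_sims = n_sims, seed = seed, mode = mode,
    counts = c(ov$count_a, ov$count_b), denominator = denominator)
  structure(c(ov, list(chi2_value = chi$chi2, chi2_df = chi$df,
                       chi2_p = chi$p, sim_n = n_sims,
                       sim_p = sim$sim_p, sim_mode = mode, seed = seed)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: |A|=%d, |B|=%d, |A&B|=%d of %d vertices -> %.2f%% (den. %s)\n",
    x$count_a, x$count_b, x$count_intersection, x$n_vertices,
    x$percent_overlap, x$denominator))
  cat(sprintf("prevalence chi2(df=%d) = %.1f, p = %.3g; sim p (%s, N=%d) = %.4g\n",
              x$chi2_df, x$chi2_value, x$chi2_p, x$sim_mode, x$sim_n,
              x$sim_p))
  invisible(x)
}
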