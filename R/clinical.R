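#' Welch two-sample t-test from group summaries
#'
#' `t = (m_A - m_B) / sqrt(s_A^2/n_A + s_B^2/n_B)` with the
#' Welch-Satterthwaite fractional degrees of freedom and a two-tailed p;
#' the form used for the demographic group comparisons (age, FSIQ, global
#' brain measures).
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries.
#' @return list: `t`, `df`, `p`.
#' @export
welch_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2)
    stop_fmt("usage_error", "need n >= 2 per group")
  if (sd_a <= 0 || sd_b <= 0)
    stop_fmt("usage_error", "need positive SDs")
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  tval <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
}

#' Continuity-corrected 2x2 chi-square
#'
#' Yates-corrected chi-square with df = 1, as used for the categorical
#' demographic comparisons (sex by group, site by group).
#'
#' @param counts 2x2 table of counts.
#' @param correct apply the continuity correction (default `TRUE`).
#' @return list: `chi2`, `df`, `p`.
#' @export
chi2_2x2 <- function(counts, correct = TRUE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    stop_fmt("usage_error", "need a 2x2 table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop_fmt("usage_error", "chi-square undefined: zero marginal")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Demographic group comparison table
#'
#' Welch t-tests for the continuous covariates and Yates-corrected
#' chi-square tests for sex and site composition, ASD vs TD.
#'
#' @param cohort a `cohort_table`.
#' @return data.frame with one row per comparison (`variable`, `test`,
#'   `statistic`, `df`, `p`).
#' @export
demographics_tests <- function(cohort) {
  cohort <- validate_cohort(as.data.frame(cohort))
  a <- cohort[cohort$group == "ASD", ]
  b <- cohort[cohort$group == "TD", ]
  rows <- list()
  for (v in c("age", "fsiq")) {
    w <- welch_t(mean(a[[v]]), sd(a[[v]]), nrow(a),
                 mean(b[[v]]), sd(b[[v]]), nrow(b))
    rows[[v]] <- data.frame(variable = v, test = "welch_t",
                            statistic = w$t, df = w$df, p = w$p)
  }
  for (v in c("sex", "site")) {
    lv <- sort(unique(cohort[[v]]))
    tab <- rbind(table(factor(a[[v]], levels = lv)),
                 table(factor(b[[v]], levels = lv)))
    ch <- chi2_2x2(tab)
    rows[[v]] <- data.frame(variable = v, test = "chi2_yates",
                            statistic = ch$chi2, df = ch$df, p = ch$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster-mean vs clinical-score Pearson correlations
#'
#' For every (cluster, score) pair, the Pearson correlation between the
#' per-subject mean of a measure over the cluster's vertices and a
#' clinical questionnaire score, with pairwise deletion of missing scores
#' and a two-tailed p. Run within the ASD group by default (scores such as
#' ADI-R/AQ are condition-specific); set `group = NULL` to pool. P-values
#' are uncorrected (exploratory associations); an optional
#' Benjamini-Hochberg column can be added.
#'
#' @param Y subjects x vertices measure matrix (cohort row order).
#' @param cohort the matching `cohort_table`.
#' @param clusters a `cluster_table` (its `vertices` lists are used).
#' @param scores character vector of cohort score column names.
#' @param group restrict to this group (default `"ASD"`).
#' @param bh add a Benjamini-Hochberg adjusted column (default `TRUE`).
#' @param measure label stored in the output.
#' @return data.frame: `cluster_id`, `measure`, `score`, `n`, `r`, `p`
#'   (and `p_bh`); undefined pairs (zero variance, n < 3) carry `NA`.
#' @export
cluster_clinical_correlations <- function(Y, cohort, clusters, scores,
                                          group = "ASD", bh = TRUE,
                                          measure = "measure") {
  cohort <- as.data.frame(cohort)
  keep <- if (is.null(group)) rep(TRUE, nrow(cohort))
  else cohort$group == group
  rows <- list()
  for (k in seq_len(nrow(clusters))) {
    vs <- clusters$vertices[[k]]
    cm <- rowMeans(Y[, vs, drop = FALSE])
    for (sc in scores) {
      x <- cm[keep]
      y <- cohort[[sc]][keep]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x[ok], y[ok])
        r <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = clusters$cluster_id[k], measure = measure,
        score = sc, n = n, r = r, p = p)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(cluster_id = integer(0), measure = character(0),
                  score = character(0), n = integer(0), r = numeric(0),
                  p = numeric(0))
  if (bh && nrow(out)) out$p_bh <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
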