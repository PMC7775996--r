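#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis. Defaults follow the
#' study settings where stated: 15 mm FWHM surface smoothing, cluster
#' significance alpha = 0.05 two-tailed, N = 5000 simulated random
#' difference maps; the cluster-defining threshold defaults to two-tailed
#' p = 0.001.
#'
#' @param spec a [synthetic_spec()] describing the cohort to simulate, or
#'   `NULL` when `data_dir` points at a directory written by
#'   [simulate_to_dir()].
#' @param data_dir optional input directory (surfaces, volumes,
#'   cohort.tsv).
#' @param out output run directory.
#' @param fwhm_mm surface smoothing FWHM (mm).
#' @param scheme a [sampling_scheme()].
#' @param cdt_p cluster-defining threshold (two-tailed p).
#' @param alpha cluster-corrected significance level.
#' @param n_sims simulated map pairs for the overlap null.
#' @param n_perm permutations for the permutation oracle (0 = RFT only).
#' @param extra_covariates additional design covariates (e.g. `"bdi"`).
#' @param exclude_ids subject ids to drop (robustness reruns).
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(spec = synthetic_spec(), data_dir = NULL,
                            out = tempfile("bp_run_"), fwhm_mm = 15,
                            scheme = sampling_scheme(), cdt_p = 0.001,
                            alpha = 0.05, n_sims = 5000, n_perm = 0,
                            extra_covariates = NULL, exclude_ids = NULL,
                            seed = 1L) {
  structure(list(spec = spec, data_dir = data_dir, out = out,
                 fwhm_mm = fwhm_mm, scheme = scheme, cdt_p = cdt_p,
                 alpha = alpha, n_sims = n_sims, n_perm = n_perm,
                 extra_covariates = extra_covariates,
                 exclude_ids = exclude_ids, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Smooth the columns of a subjects x vertices matrix in one pass.
smooth_matrix <- function(mesh, M, fwhm_mm, valid) {
  if (fwhm_mm == 0) return(M)
  op <- smoothing_operator(mesh, fwhm_mm, valid = valid)
  Z <- t(M)
  Z[!valid, ] <- 0
  for (it in seq_len(op$n_iter)) Z <- as.matrix(op$S %*% Z)
  Z[!valid, ] <- NA_real_
  t(Z)
}

load_run_inputs <- function(config) {
  if (!is.null(config$data_dir)) {
    dir <- config$data_dir
    white <- read_surface(file.path(dir, "white.surf"))
    pial <- read_surface(file.path(dir, "pial.surf"))
    cohort <- read_cohort(file.path(dir, "cohort.tsv"))
    mods <- sub("^path_", "", grep("^path_", names(cohort), value = TRUE))
    get_volumes <- function(s) {
      vols <- lapply(mods, function(m)
        read_volume(file.path(dir, cohort[[paste0("path_", m)]][s])))
      names(vols) <- mods
      vols
    }
    list(white = white, pial = pial, cohort = cohort,
         get_volumes = get_volumes, truth = NULL)
  } else {
    spec <- config$spec
    sim <- simulate_cohort(spec)
    cohort <- sim$cohort
    get_volumes <- function(s) simulate_subject_volumes(
      sim$geometry, spec,
      list(group = cohort$group[s], sex = cohort$sex[s]),
      seed = substream_seed(spec$seed, paste0("subject-", cohort$id[s])),
      dose = cohort$dose[s])
    list(white = sim$geometry$white, pial = sim$geometry$pial,
         cohort = cohort, get_volumes = get_volumes, truth = sim$truth)
  }
}

#' Run the full boundary-profile analysis
#'
#' simulate/load -> depth sampling -> GWC -> smoothing -> vertex GLM
#' (group and group-by-sex contrasts) -> RFT cluster correction ->
#' binarized overlap analysis with chi-square and simulation null ->
#' demographics and clinical correlations -> report. All stage outputs are
#' written under `config$out`; a rerun with the same config and seed
#' reproduces them bitwise.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a `pipeline_run` list with all in-memory results
#'   and the run directory.
#' @export
run_pipeline <- function(config) {
  t_start <- Sys.time()
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_add <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop_fmt("pipeline_error", "stage '%s' failed: %s", name,
               conditionMessage(e)))
    log_add("stage %-12s %6.2f s", name,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  inputs <- stage("inputs", load_run_inputs(config))
  cohort <- inputs$cohort
  if (!is.null(config$exclude_ids)) {
    cohort <- cohort[!cohort$id %in% config$exclude_ids, , drop = FALSE]
    cohort <- validate_cohort(as.data.frame(cohort))
  }
  n_sub <- nrow(cohort)
  white <- inputs$white
  pial <- inputs$pial
  nv <- n_vertices(white)
  normals <- compute_vertex_normals(white)
  scheme <- config$scheme

  sampled <- stage("sampling", {
    # subjects x vertices matrix per (modality, depth) + GWC inputs
    mats <- list()
    gwc_raw <- matrix(NA_real_, n_sub, nv)
    shared_valid <- rep(TRUE, nv)
    for (s in seq_len(n_sub)) {
      vols <- inputs$get_volumes(which(inputs$cohort$id == cohort$id[s]))
      prof <- build_depth_profile(white, pial, vols, scheme,
                                  normals = normals)
      shared_valid <- shared_valid & prof$shared_valid
      for (mod in setdiff(names(prof$maps), "T1I")) {
        for (lab in scheme$label) {
          key <- paste(mod, lab, sep = "@")
          if (is.null(mats[[key]]))
            mats[[key]] <- matrix(NA_real_, n_sub, nv)
          mats[[key]][s, ] <- prof$maps[[mod]][[lab]]$values
        }
      }
      if ("T1I" %in% names(vols)) {
        wmi <- sample_absolute_depth(white, normals, vols$T1I, -1,
                                     modality = "T1I")
        gmi <- sample_projection_fraction(white, pial, vols$T1I, 0.3,
                                          modality = "T1I")
        g <- compute_gwc(wmi, gmi)
        gwc_raw[s, ] <- g$values
        shared_valid <- shared_valid & g$valid
      }
    }
    if (any(is.finite(gwc_raw))) mats[["GWC@boundary"]] <- gwc_raw
    list(mats = mats, valid = shared_valid)
  })

  smoothed <- stage("smoothing", {
    lapply(sampled$mats, function(M)
      smooth_matrix(white, M, config$fwhm_mm, sampled$valid))
  })

  X <- build_design(cohort, extra_covariates = config$extra_covariates)
  stats_out <- stage("glm", {
    lapply(smoothed, function(M) {
      fit <- fit_vertex_glm(M, X)
      # noise-free inputs have constant (zero) residuals: no smoothness,
      # no cluster inference, but coefficients remain available
      sm <- tryCatch(estimate_smoothness(fit, white),
                     error = function(e) NULL)
      res <- list(fit = fit, smoothness = sm)
      for (ctr in c("group", "group_x_sex")) {
        tmap <- contrast_t(fit, ctr)
        cl <- if (is.null(sm)) empty_cluster_table()
        else define_clusters(tmap, white, sm, config$cdt_p)
        if (!is.null(sm)) cl <- rft_correct_clusters(cl, sm)
        if (config$n_perm > 0) {
          pm <- permutation_cluster_test(
            M, X, ctr, white, cdt_p = config$cdt_p,
            n_perm = config$n_perm,
            seed = substream_seed(config$seed, paste0("perm-", ctr)))
          if (nrow(cl) > 0) cl$p_perm <- pm$clusters$p_perm
        }
        res[[ctr]] <- list(tmap = tmap, clusters = cl)
      }
      res
    })
  })

  overlaps <- stage("overlap", {
    sig_map <- function(key, ctr = "group") {
      st <- stats_out[[key]]
      if (is.null(st)) return(NULL)
      binarize_significant(st[[ctr]]$clusters, nv, alpha = config$alpha)
    }
    boundary_lab <- scheme$label[which(
      (scheme$type == "fraction" & scheme$value == 0) |
        (scheme$type == "absolute" & scheme$value == 0))][1]
    maps <- list(GWC = sig_map("GWC@boundary"),
                 FA = sig_map(paste0("FA@", boundary_lab)),
                 MD = sig_map(paste0("MD@", boundary_lab)))
    pairs <- list(c("GWC", "FA"), c("GWC", "MD"), c("MD", "FA"))
    out <- list()
    for (pr in pairs) {
      a <- maps[[pr[1]]]; b <- maps[[pr[2]]]
      if (is.null(a) || is.null(b)) next
      key <- paste(pr, collapse = "_vs_")
      out[[key]] <- tryCatch(
        overlap_analysis(a, b, denominator = "B",
                         n_sims = config$n_sims,
                         seed = substream_seed(config$seed,
                                               paste0("overlap-", key))),
        error = function(e) list(error = conditionMessage(e)))
    }
    out
  })

  demo <- stage("demographics", demographics_tests(cohort))
  clin <- stage("clincorr", {
    out <- list()
    for (key in names(smoothed)) {
      cl <- stats_out[[key]]$group$clusters
      sig <- cl[!is.na(cl$p_rft) & cl$p_rft < config$alpha, ,
                drop = FALSE]
      if (nrow(sig) == 0) next
      out[[key]] <- cluster_clinical_correlations(
        smoothed[[key]], cohort, sig,
        scores = intersect(c("aq", "bdi", "bai"),
                           clinical_score_names(cohort)),
        measure = key)
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(cluster_id = integer(0), measure = character(0),
                 score = character(0), n = integer(0), r = numeric(0),
                 p = numeric(0))
  })

  run <- list(config = config, cohort = cohort, white = white,
              pial = pial, valid = sampled$valid, maps = smoothed,
              stats = stats_out, overlaps = overlaps,
              demographics = demo, clinical = clin,
              truth = inputs$truth)
  class(run) <- "pipeline_run"

  stage("write", write_run_outputs(run, log_add))
  log_add("total %.2f s, seed %d",
          as.numeric(difftime(Sys.time(), t_start, units = "secs")),
          config$seed)
  writeLines(log_lines, file.path(config$out, "log.txt"))
  make_report(config$out)
  invisible(run)
}

write_run_outputs <- function(run, log_add = function(...) NULL) {
  out <- run$config$out
  cfg <- run$config
  yaml::write_yaml(list(
    fwhm_mm = cfg$fwhm_mm, cdt_p = cfg$cdt_p, alpha = cfg$alpha,
    n_sims = cfg$n_sims, n_perm = cfg$n_perm, seed = cfg$seed,
    scheme = as.data.frame(cfg$scheme),
    extra_covariates = cfg$extra_covariates,
    exclude_ids = cfg$exclude_ids,
    synthetic = !is.null(cfg$spec), data_dir = cfg$data_dir),
    file.path(out, "config.yaml"))
  write_cohort(run$cohort, file.path(out, "cohort_used.tsv"))
  write.table(run$demographics, file.path(out, "demographics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(run$clinical, file.path(out, "clincorr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dir.create(file.path(out, "maps"), showWarnings = FALSE)
  cluster_rows <- list()
  for (key in names(run$stats)) {
    for (ctr in c("group", "group_x_sex")) {
      st <- run$stats[[key]][[ctr]]
      write_vertex_map(st$tmap$map, file.path(
        out, "maps", paste0(gsub("[@%]", "_", key), "_", ctr, "_t.mgz")))
      cl <- st$clusters
      if (nrow(cl)) {
        cl_flat <- cl[, setdiff(names(cl), "vertices"), drop = FALSE]
        cl_flat$measure <- key
        cl_flat$contrast <- ctr
        cluster_rows[[paste(key, ctr)]] <- cl_flat
      }
    }
  }
  clusters_df <- if (length(cluster_rows)) do.call(rbind, cluster_rows)
  else data.frame(cluster_id = integer(0), sign = character(0),
                  n_vertices = integer(0), area_mm2 = numeric(0),
                  resels = numeric(0), peak_t = numeric(0),
                  peak_vertex = integer(0), p_rft = numeric(0),
                  measure = character(0), contrast = character(0))
  rownames(clusters_df) <- NULL
  write.table(clusters_df, file.path(out, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ov <- lapply(run$overlaps, unclass)
  jsonlite::write_json(ov, file.path(out, "overlap.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- list.files(out, recursive = TRUE)
  files <- setdiff(files, c("log.txt", "report.txt", "hashes.txt"))
  hashes <- tools::md5sum(file.path(out, files))
  writeLines(sprintf("%s  %s", hashes, files),
             file.path(out, "hashes.txt"))
  invisible(out)
}

#' Compose a human-readable run report
#'
#' Summarizes a completed run directory: demographics tests, per-depth
#' suprathreshold vertex counts per measure and contrast, significant
#' clusters, and the overlap analyses. Numbers are read back from the
#' run's TSV/JSON outputs, so the report always equals the persisted
#' values.
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @return the report text, invisibly; also written to `report.txt`.
#' @export
make_report <- function(run_dir) {
  need <- c("demographics.tsv", "clusters.tsv", "overlap.json",
            "config.yaml")
  missing_f <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing_f))
    stop_fmt("pipeline_error", "incomplete run; missing: %s",
             paste(missing_f, collapse = ", "))
  cfg <- yaml::read_yaml(file.path(run_dir, "config.yaml"))
  demo <- read.delim(file.path(run_dir, "demographics.tsv"))
  clusters <- read.delim(file.path(run_dir, "clusters.tsv"))
  ov <- jsonlite::read_json(file.path(run_dir, "overlap.json"),
                            simplifyVector = TRUE)
  txt <- c(
    "boundaryprofile run report",
    sprintf("seed %s | fwhm %s mm | cdt p %s | alpha %s",
            cfg$seed, cfg$fwhm_mm, cfg$cdt_p, cfg$alpha),
    "", "Demographics (ASD vs TD):",
    sprintf("  %-6s %-10s stat %8.3f  df %7.2f  p %.3f",
            demo$variable, demo$test, demo$statistic, demo$df, demo$p),
    "", "Significant clusters (corrected p < alpha):")
  if (nrow(clusters)) {
    sig <- clusters[!is.na(clusters$p_rft) & clusters$p_rft < cfg$alpha, ]
    counts <- stats::aggregate(n_vertices ~ measure + contrast,
                               data = clusters, FUN = sum)
    txt <- c(txt, "  suprathreshold vertex counts (all clusters):",
             sprintf("    %-14s %-12s %6d", counts$measure,
                     counts$contrast, counts$n_vertices))
    if (nrow(sig)) {
      txt <- c(txt, "  significant:",
               sprintf("    %-14s %-12s #%d %s n=%d peak t=%.2f p=%.4f",
                       sig$measure, sig$contrast, sig$cluster_id,
                       sig$sign, sig$n_vertices, sig$peak_t, sig$p_rft))
    } else txt <- c(txt, "  none")
  } else txt <- c(txt, "  no suprathreshold clusters (count 0)")
  txt <- c(txt, "", "Overlap of significant between-group differences:")
  if (length(ov)) {
    for (key in names(ov)) {
      o <- ov[[key]]
      if (!is.null(o$error)) {
        txt <- c(txt, sprintf("  %s: %s", key, o$error))
      } else {
        txt <- c(txt, sprintf(
          "  %s: |A|=%d |B|=%d inter=%d -> %.2f%% ; chi2=%.1f p=%.3g ; sim p=%.4g",
          key, o$count_a, o$count_b, o$count_intersection,
          o$percent_overlap, o$chi2_value, o$chi2_p, o$sim_p))
      }
    }
  } else txt <- c(txt, "  not computed (no eligible map pairs)")
  writeLines(txt, file.path(run_dir, "report.txt"))
  invisible(paste(txt, collapse = "\n"))
}
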