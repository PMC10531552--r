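# End-to-end cohort pipeline: phantom cohort (or supplied volumes) ->
# masked pairs -> outlier filter -> tissue groups -> 1000-voxel
# standardization -> pooled z-normalization -> mixture clustering ->
# cohort statistics and report files.

#' Cohort pipeline configuration
#'
#' The default cohort mirrors the study layout: 8 patients, 6 responding to
#' chemotherapy and 2 progressing, each with a baseline and a post-therapy
#' phantom.
#'
#' @param n_response,n_progression patients per therapy-course mode.
#' @param seed master seed; every per-patient and per-stage seed is derived
#'   from it.
#' @param n_standard standardized voxel count per tumor per timepoint.
#' @param thresholds A [tissue_thresholds].
#' @param phantom named list of [phantom_config] overrides applied to every
#'   patient (e.g. `grid_shape`, `compartment_params`).
#' @param cluster_mode `"2d"` (mixture on normalized ADC and SUV jointly) or
#'   `"1d"` (on normalized SUV, with intersection demarcation thresholds).
#' @param cluster_scope `"subset"` fits one mixture per display subset
#'   (baseline, post-response, post-progression); `"pooled"` fits once on
#'   everything.
#' @param dead_band unchanged-direction dead band for proportion deltas.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_response = 6L, n_progression = 2L, seed = 1L,
                          n_standard = 1000L,
                          thresholds = tissue_thresholds(),
                          phantom = list(),
                          cluster_mode = c("2d", "1d"),
                          cluster_scope = c("subset", "pooled"),
                          dead_band = 0) {
  if (n_response + n_progression < 1L) stop("cohort must have patients")
  structure(list(n_response = as.integer(n_response),
                 n_progression = as.integer(n_progression),
                 seed = as.integer(seed),
                 n_standard = as.integer(n_standard),
                 thresholds = thresholds, phantom = phantom,
                 cluster_mode = match.arg(cluster_mode),
                 cluster_scope = match.arg(cluster_scope),
                 dead_band = dead_band),
            class = "cohort_config")
}

#' Read a cohort configuration from YAML
#'
#' Scalar fields of [cohort_config] plus a `phantom:` mapping of generator
#' overrides and a `thresholds:` mapping (`suv_cut`, `adc_cut`,
#' `adc_outlier`).
#'
#' @param path YAML file.
#' @return A [cohort_config].
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- do.call(tissue_thresholds, y$thresholds %||% list())
  args <- y[setdiff(names(y), c("thresholds", "phantom"))]
  args$thresholds <- th
  args$phantom <- lapply(y$phantom %||% list(), unlist)
  do.call(cohort_config, args)
}

.patient_frame <- function(config) {
  modes <- c(rep("response", config$n_response),
             rep("progression", config$n_progression))
  data.frame(patient_id = sprintf("P%02d", seq_along(modes)),
             mode = modes, stringsAsFactors = FALSE)
}

.fit_subset <- function(table, rows, mode, seed) {
  sub <- vt_keep(table, rows)
  x <- if (mode == "2d") as.matrix(sub[, c("adc_norm", "suv_norm")])
       else sub$suv_norm
  fit_gmm(x, k = 3L, seed = seed)
}

#' Run the cohort pipeline
#'
#' Generates (or accepts) the cohort, executes every analysis stage in
#' order, and assembles the cohort result. With `out_dir` set, writes
#' `result.json`, `proportions.csv`, `clusters.csv` and `report.md`.
#' Reruns with the same configuration are byte-identical.
#'
#' @param config A [cohort_config].
#' @param out_dir optional output directory.
#' @return An object of class `cohort_result`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  patients <- .patient_frame(config)
  th <- config$thresholds

  summaries <- list()
  prop_rows <- list()
  std_tables <- list()
  for (p in seq_len(nrow(patients))) {
    pid <- patients$patient_id[p]
    ph_args <- config$phantom
    ph_args$seed <- derive_seed(config$seed, p)
    base <- generate_phantom(do.call(phantom_config, ph_args))
    post <- apply_therapy_course(base, patients$mode[p])
    for (ph in list(base, post)) {
      tab <- phantom_table(ph, use = "pipeline", patient_id = pid)
      tab <- suppressMessages(filter_outliers(tab, th$adc_outlier))
      tab <- classify_voxels(tab, th)
      key <- paste(pid, ph$timepoint, sep = ".")
      summaries[[key]] <- voxel_summary(tab)
      gp <- group_proportions(tab)
      prop_rows[[key]] <- data.frame(patient_id = pid,
                                     timepoint = ph$timepoint,
                                     mode = patients$mode[p],
                                     group = gp$group, n = gp$n,
                                     fraction = gp$fraction,
                                     volume_ml = gp$volume_ml)
      std_tables[[key]] <- standardize_size(
        tab, config$n_standard,
        seed = derive_seed(config$seed, 500L + 2L * p +
                             (ph$timepoint == "post")))
    }
  }
  proportions <- do.call(rbind, prop_rows)
  rownames(proportions) <- NULL

  pooled <- voxel_table(do.call(rbind, lapply(std_tables, as.data.frame)),
                        spacing = vt_spacing(std_tables[[1]]))
  rownames(pooled) <- NULL
  zn_adc <- znormalize(pooled$adc)
  zn_suv <- znormalize(pooled$suv)
  pooled$adc_norm <- zn_adc$values
  pooled$suv_norm <- zn_suv$values
  pooled$mode <- patients$mode[match(pooled$patient_id,
                                     patients$patient_id)]

  subsets <- if (config$cluster_scope == "pooled") {
    list(all = rep(TRUE, nrow(pooled)))
  } else {
    list(baseline = pooled$timepoint == "baseline",
         post_response = pooled$timepoint == "post" &
           pooled$mode == "response",
         post_progression = pooled$timepoint == "post" &
           pooled$mode == "progression")
  }
  subsets <- Filter(any, subsets)

  models <- list()
  correlations <- list()
  pooled$cluster <- factor(NA_character_, levels = TISSUE_LEVELS)
  for (s in seq_along(subsets)) {
    rows <- subsets[[s]]
    model <- .fit_subset(pooled, rows, config$cluster_mode,
                         derive_seed(config$seed, 900L + s))
    sub <- assign_clusters(model, vt_keep(pooled, rows),
                           var = if (config$cluster_mode == "2d") "both"
                                 else "suv")
    pooled$cluster[rows] <- sub$cluster
    models[[names(subsets)[s]]] <- model
    cw <- suppressWarnings(correlate_within_clusters(sub))
    cw$subset <- names(subsets)[s]
    correlations[[names(subsets)[s]]] <- cw
  }
  correlations <- do.call(rbind, correlations)
  rownames(correlations) <- NULL

  cluster_rows <- do.call(rbind, lapply(split(
    seq_len(nrow(pooled)),
    list(pooled$patient_id, pooled$timepoint), drop = TRUE),
    function(rows) {
      gp <- group_proportions(vt_keep(pooled, rows), column = "cluster")
      data.frame(patient_id = pooled$patient_id[rows[1]],
                 timepoint = pooled$timepoint[rows[1]],
                 cluster = gp$group, n = gp$n, fraction = gp$fraction)
    }))
  rownames(cluster_rows) <- NULL

  tests <- .cohort_tests(patients, summaries, proportions)

  result <- structure(list(
    patients = patients,
    summaries = summaries,
    proportions = proportions,
    cluster_proportions = cluster_rows,
    correlations = correlations,
    models = models,
    normalization = list(adc = list(mean = zn_adc$mean, sd = zn_adc$sd),
                         suv = list(mean = zn_suv$mean, sd = zn_suv$sd)),
    tests = tests,
    pooled = pooled,
    seed = config$seed), class = "cohort_result")

  if (!is.null(out_dir)) write_cohort_result(result, out_dir, config)
  result
}

# paired tests and subvolume-change associations at cohort level
.cohort_tests <- function(patients, summaries, proportions) {
  pick <- function(pid, tp, what, q)
    summaries[[paste(pid, tp, sep = ".")]][[q]][[what]]
  pids <- patients$patient_id
  mean_pre <- list(adc = vapply(pids, pick, numeric(1), tp = "baseline",
                                what = "mean", q = "adc"),
                   suv = vapply(pids, pick, numeric(1), tp = "baseline",
                                what = "mean", q = "suv"))
  mean_post <- list(adc = vapply(pids, pick, numeric(1), tp = "post",
                                 what = "mean", q = "adc"),
                    suv = vapply(pids, pick, numeric(1), tp = "post",
                                 what = "mean", q = "suv"))
  out <- list()
  for (q in c("adc", "suv")) {
    out[[paste0("wilcoxon_mean_", q)]] <-
      wilcoxon_signed_rank(mean_pre[[q]], mean_post[[q]])
    for (m in unique(patients$mode)) {
      sel <- patients$mode == m
      if (sum(sel) >= 1L)
        out[[paste0("wilcoxon_mean_", q, "_", m)]] <-
          wilcoxon_signed_rank(mean_pre[[q]][sel], mean_post[[q]][sel])
    }
  }
  frac <- function(pid, tp, g)
    proportions$fraction[proportions$patient_id == pid &
                         proportions$timepoint == tp &
                         proportions$group == g]
  response01 <- as.integer(patients$mode == "response")
  for (g in TISSUE_LEVELS) {
    pre <- vapply(pids, frac, numeric(1), tp = "baseline", g = g)
    post <- vapply(pids, frac, numeric(1), tp = "post", g = g)
    out[[paste0("wilcoxon_fraction_", g)]] <- wilcoxon_signed_rank(pre, post)
    delta <- post - pre
    if (length(unique(response01)) == 2L && length(delta) >= 3L) {
      out[[paste0("biserial_delta_", g)]] <-
        point_biserial(response01, delta)
      out[[paste0("regression_delta_", g)]] <-
        linear_regression(response01, delta)
    }
  }
  out
}

#' Write cohort result files
#'
#' @param result A [run_pipeline] result.
#' @param out_dir output directory (created if missing).
#' @param config the [cohort_config] used (echoed into the report).
#' @return Named vector of written paths, invisibly.
#' @export
write_cohort_result <- function(result, out_dir, config = NULL) {
  stopifnot(inherits(result, "cohort_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(json = file.path(out_dir, "result.json"),
             proportions = file.path(out_dir, "proportions.csv"),
             clusters = file.path(out_dir, "clusters.csv"),
             report = file.path(out_dir, "report.md"))
  ser <- list(
    seed = result$seed,
    patients = result$patients,
    proportions = result$proportions,
    cluster_proportions = result$cluster_proportions,
    correlations = result$correlations,
    normalization = result$normalization,
    tests = lapply(result$tests, function(t) t[setdiff(names(t), "")]),
    models = lapply(result$models, function(m) list(
      loglik = m$loglik, iterations = m$iterations,
      converged = m$converged,
      weights = vapply(m$components, `[[`, numeric(1), "weight"),
      means = lapply(m$components, `[[`, "mean"))))
  jsonlite::write_json(ser, paths[["json"]], auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$proportions, paths[["proportions"]],
                   row.names = FALSE)
  pooled <- as.data.frame(result$pooled)
  utils::write.csv(pooled, paths[["clusters"]], row.names = FALSE)
  writeLines(.render_report(result), paths[["report"]])
  invisible(paths)
}

.render_report <- function(result) {
  pr <- result$proportions
  col_of <- function(rows) {
    tot <- tapply(rows$volume_ml, rows$patient_id, sum)
    frac <- vapply(TISSUE_LEVELS, function(g)
      mean(rows$fraction[rows$group == g]), numeric(1))
    c(sprintf("%.0f", stats::median(tot)),
      sprintf("%.1f%%", 100 * frac))
  }
  cols <- list(
    Baseline = pr[pr$timepoint == "baseline", ],
    `Post (response)` = pr[pr$timepoint == "post" &
                             pr$mode == "response", ],
    `Post (progression)` = pr[pr$timepoint == "post" &
                                pr$mode == "progression", ])
  cols <- Filter(function(d) nrow(d) > 0, cols)
  body <- vapply(cols, col_of, character(4))
  rows <- c("Median volume (total) [mL]", "vital", "equivocal", "low vital")
  lines <- c("# Cohort report", "",
             paste0("| | ", paste(names(cols), collapse = " | "), " |"),
             paste0("|---|", paste(rep("---|", length(cols)),
                                   collapse = "")),
             vapply(seq_along(rows), function(i)
               paste0("| ", rows[i], " | ",
                      paste(body[i, ], collapse = " | "), " |"),
               character(1)),
             "", "## Cluster proportions (standardized voxels)", "")
  cp <- result$cluster_proportions
  agg <- stats::aggregate(fraction ~ timepoint + cluster, data = cp,
                          FUN = mean)
  lines <- c(lines, utils::capture.output(print(agg, row.names = FALSE)),
             "", "## Paired tests", "")
  for (nm in names(result$tests)) {
    t <- result$tests[[nm]]
    lines <- c(lines, sprintf("- %s: %s", nm,
      if (!is.null(t$p)) sprintf("p = %.4g", t$p)
      else sprintf("r/slope available (n = %d)", t$n)))
  }
  lines
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d patients (%d response, %d progression)\n",
              nrow(x$patients), sum(x$patients$mode == "response"),
              sum(x$patients$mode == "progression")))
  cat("tissue-group mean fractions by timepoint:\n")
  agg <- stats::aggregate(fraction ~ timepoint + group,
                          data = x$proportions, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
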