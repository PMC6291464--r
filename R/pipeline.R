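#' Build and validate a pipeline configuration
#'
#' Aggregates every fixed constant of the analysis: band set, sampling
#' rate, epoch and trim lengths, artifact threshold, surrogate count,
#' seeds, the clustering-denominator convention, the partial-correlation
#' method and the FDR level, plus the synthetic-cohort parameters.
#'
#' @param bands Character vector of band names (subset of
#'   `names(default_bands())`). Default `c("theta", "beta")` (demo scale).
#' @param fs Sampling rate in Hz (default 500).
#' @param epoch_len,trim Epoch length and edge trim in seconds (3.5 / 0.5).
#' @param artifact_threshold_uv Rejection threshold in muV (default 60).
#' @param n_surrogates Surrogates per small-world evaluation (default 50).
#' @param seed Master seed; every stochastic stage derives its own stream.
#' @param clustering_denominator `"degree"` or `"strength"`.
#' @param partial_method `"rank"` or `"linear"`.
#' @param fdr_q FDR level for node-level families (default 0.05).
#' @param metric_path `"per-segment"` or `"average"`, see
#'   [condition_metrics()].
#' @param conditions Conditions to simulate and analyze.
#' @param cohort Named list of overrides for [cohort_spec()].
#' @param out_dir Output directory.
#' @param write_recordings Also write the simulated recordings as TSV
#'   (default FALSE; they are reproducible from the seed).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(bands = c("theta", "beta"), fs = 500,
                            epoch_len = 3.5, trim = 0.5,
                            artifact_threshold_uv = 60, n_surrogates = 50,
                            seed = 1, clustering_denominator = "degree",
                            partial_method = "rank", fdr_q = 0.05,
                            metric_path = "per-segment",
                            conditions = c("rest", "0-back", "2-back"),
                            cohort = list(), out_dir = tempfile("plinet_run_"),
                            write_recordings = FALSE) {
  known <- names(default_bands())
  bad <- setdiff(bands, known)
  stop_if_not(length(bad) == 0,
              sprintf("unknown band name(s): %s (known: %s)",
                      paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  stop_if_not(epoch_len > 2 * trim, "epoch_len must exceed twice the trim")
  stop_if_not(artifact_threshold_uv > 0, "artifact threshold must be positive")
  stop_if_not(n_surrogates >= 1, "need at least one surrogate")
  stop_if_not(clustering_denominator %in% c("degree", "strength"),
              "clustering_denominator must be 'degree' or 'strength'")
  stop_if_not(partial_method %in% c("rank", "linear"),
              "partial_method must be 'rank' or 'linear'")
  stop_if_not(metric_path %in% c("per-segment", "average"),
              "metric_path must be 'per-segment' or 'average'")
  stop_if_not(all(conditions %in% c("rest", "0-back", "2-back")),
              "conditions must be among rest, 0-back, 2-back")
  structure(list(bands = bands, fs = fs, epoch_len = epoch_len, trim = trim,
                 artifact_threshold_uv = artifact_threshold_uv,
                 n_surrogates = n_surrogates, seed = as.integer(seed),
                 clustering_denominator = clustering_denominator,
                 partial_method = partial_method, fdr_q = fdr_q,
                 metric_path = metric_path, conditions = conditions,
                 cohort = cohort, out_dir = out_dir,
                 write_recordings = write_recordings),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  stop_if_not(file.exists(path), sprintf("config file not found: %s", path))
  args <- yaml::read_yaml(path)
  if (!is.null(args$bands)) args$bands <- unlist(args$bands)
  if (!is.null(args$conditions)) args$conditions <- unlist(args$conditions)
  do.call(pipeline_config, args)
}

# segments for one recording of one subject: broadband epochs -> amplitude
# rejection -> band filter -> edge trim
condition_segments <- function(recording, band, schedule, config) {
  onsets <- if (identical(recording$condition, "rest") || is.null(schedule))
    rest_onsets(recording, config$epoch_len) else schedule$onset_s
  eps <- extract_epochs(recording, onsets, config$epoch_len)
  eps <- reject_artifacts(eps, config$artifact_threshold_uv)
  report <- attr(eps, "report")
  filt <- bandpass_filter(eps, default_bands()[[band]])
  segs <- trim_to_segments(filt, config$trim)
  attr(segs, "rejection_report") <- report
  segs
}

metric_rows <- function(m, subject, group, condition, band, config) {
  glob <- data.frame(subject = subject, group = group, condition = condition,
                     band = band,
                     metric = c("avg_pli", "C", "L", "C_rand", "L_rand", "SW"),
                     node = "global",
                     value = c(m$avg_pli, m$C, m$L, m$C_rand, m$L_rand, m$SW))
  nod <- data.frame(subject = subject, group = group, condition = condition,
                    band = band, metric = "nodal_C", node = names(m$nodal_C),
                    value = unname(m$nodal_C))
  out <- rbind(glob, nod)
  out$n_surrogates <- config$n_surrogates
  out$seed <- config$seed
  out
}

#' Run the full pipeline: simulate, preprocess, connect, network, stats
#'
#' Executes every stage for every subject x condition x band, writing the
#' cohort table, per-subject condition-averaged PLI matrices, the tidy
#' metrics table, the statistics table and a run manifest with checksums
#' under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "pipeline_config"), "`config` must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cohort <- stage("simulate", {
    cs <- do.call(cohort_spec, c(config$cohort,
                                 if (is.null(config$cohort$fs)) list(fs = config$fs)))
    generate_cohort(cs, seed = derive_seed(config$seed, "cohort"),
                    conditions = config$conditions)
  })
  cohort_path <- file.path(config$out_dir, "cohort.tsv")
  write.table(cohort$table, cohort_path, sep = "\t", quote = FALSE, row.names = FALSE)
  for (task in names(cohort$schedules))
    write.table(cohort$schedules[[task]],
                file.path(config$out_dir, sprintf("schedule_%s.tsv", task)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (config$write_recordings) {
    rec_dir <- file.path(config$out_dir, "recordings")
    dir.create(rec_dir, showWarnings = FALSE)
    for (s in names(cohort$recordings)) for (cn in names(cohort$recordings[[s]]))
      write_eeg_tsv(cohort$recordings[[s]][[cn]],
                    file.path(rec_dir, sprintf("%s_%s.tsv", s, cn)))
  }
  pli_dir <- file.path(config$out_dir, "pli")
  dir.create(pli_dir, showWarnings = FALSE)
  rows <- list()
  reject_rows <- list()
  stage("connectivity/network", {
    for (si in seq_len(nrow(cohort$table))) {
      sub <- cohort$table$id[si]
      grp <- cohort$table$group[si]
      for (cn in config$conditions) {
        rec <- cohort$recordings[[sub]][[cn]]
        sched <- if (cn == "rest") NULL else cohort$schedules[[cn]]
        for (band in config$bands) {
          segs <- condition_segments(rec, band, sched, config)
          rep <- attr(segs, "rejection_report")
          if (nrow(rep) > 0) {
            rep$subject <- sub; rep$condition <- cn
            reject_rows[[length(reject_rows) + 1]] <- rep
          }
          mats <- segment_pli(segs)
          write_matrix_tsv(condition_average(mats),
                           file.path(pli_dir, sprintf("%s_%s_%s.tsv", sub, cn, band)))
          m <- condition_metrics(mats, config$n_surrogates,
                                 seed = derive_seed(config$seed,
                                                    paste(sub, cn, band)),
                                 path = config$metric_path,
                                 denominator = config$clustering_denominator)
          rows[[length(rows) + 1]] <- metric_rows(m, sub, grp, cn, band, config)
        }
      }
    }
  })
  metrics <- do.call(rbind, rows)
  metrics_path <- file.path(config$out_dir, "metrics.tsv")
  write.table(metrics, metrics_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(reject_rows) > 0)
    write.table(do.call(rbind, reject_rows),
                file.path(config$out_dir, "rejections.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  stats_df <- stage("stats", stats_battery(metrics, cohort$table, config))
  stats_path <- file.path(config$out_dir, "stats.tsv")
  write.table(stats_df, stats_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_tests = nrow(stats_df),
         n_significant_raw = sum(stats_df$p_raw < 0.05, na.rm = TRUE),
         n_significant_fdr = sum(stats_df$p_adjusted < config$fdr_q, na.rm = TRUE)),
    file.path(config$out_dir, "stats_summary.json"), auto_unbox = TRUE)
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("plinet")),
    config_hash = digest::digest(unclass(config)),
    seed = config$seed,
    checksums = stats::setNames(
      lapply(files, function(f) digest::digest(file = f)),
      sub(paste0(config$out_dir, "/"), "", files, fixed = TRUE)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Nonparametric statistics battery over a tidy metrics table
#'
#' Runs, per band: (1) rank partial correlation between age group and every
#' global EEG measure per condition, controlling education; (2) Friedman
#' tests across conditions per group with studentized-range-adjusted
#' Wilcoxon signed-rank post-hocs when significant; (3) Mann-Whitney U
#' group comparisons and paired Wilcoxon task comparisons of behavior;
#' (4) node-level partial correlations of nodal clustering with BH FDR
#' control within each band x condition family. Tests that are infeasible
#' at the current cohort size (e.g. too few complete cases) are reported
#' as rows with NA p-values and an explanatory note.
#'
#' @param metrics Tidy metrics data frame from [run_pipeline()]
#'   (columns subject, group, condition, band, metric, node, value).
#' @param cohort_table Cohort table with id, group, education and the
#'   behavioral columns.
#' @param config A [pipeline_config()].
#' @return Data frame of test results.
#' @export
stats_battery <- function(metrics, cohort_table, config) {
  out <- list()
  add <- function(test, band, condition, group, metric, node, r, family = NA,
                  note = NA_character_) {
    out[[length(out) + 1]] <<- data.frame(
      test = test, band = band, condition = condition, group = group,
      metric = metric, node = node,
      statistic = if (is.null(r)) NA_real_ else r$statistic,
      p_raw = if (is.null(r)) NA_real_ else r$p_raw,
      p_adjusted = if (is.null(r)) NA_real_ else r$p_adjusted,
      direction = if (is.null(r)) NA_real_ else r$direction,
      family = family, note = note, stringsAsFactors = FALSE)
  }
  safely <- function(expr) tryCatch(expr, error = function(e) e)
  educ <- cohort_table$education[match(unique(metrics$subject), cohort_table$id)]
  grp <- cohort_table$group[match(unique(metrics$subject), cohort_table$id)]
  subs <- unique(metrics$subject)
  value_of <- function(band, cond, metric, node = "global") {
    sel <- metrics$band == band & metrics$condition == cond &
      metrics$metric == metric & metrics$node == node
    v <- metrics$value[sel][match(subs, metrics$subject[sel])]
    v
  }
  for (band in config$bands) {
    for (cn in config$conditions) {
      for (metric in c("avg_pli", "C", "L", "SW")) {
        v <- value_of(band, cn, metric)
        r <- safely(partial_correlation(grp, v, educ, config$partial_method))
        if (inherits(r, "error"))
          add("partial_correlation_group", band, cn, "all", metric, "global",
              NULL, note = conditionMessage(r))
        else add("partial_correlation_group", band, cn, "all", metric, "global", r)
      }
      # node-level family with BH correction
      nodes <- unique(metrics$node[metrics$metric == "nodal_C"])
      fam <- sprintf("nodal_C.%s.%s.partial_correlation", band, cn)
      rs <- lapply(nodes, function(nd)
        safely(partial_correlation(grp, value_of(band, cn, "nodal_C", nd),
                                   educ, config$partial_method)))
      okmask <- !vapply(rs, inherits, logical(1), "error")
      if (any(okmask)) {
        padj <- rep(NA_real_, length(rs))
        padj[okmask] <- bh_fdr(vapply(rs[okmask], function(r) r$p_raw, numeric(1)),
                               config$fdr_q)$p_adjusted
        for (ii in seq_along(rs)) {
          if (okmask[ii]) {
            rs[[ii]]$p_adjusted <- padj[ii]
            add("partial_correlation_group", band, cn, "all", "nodal_C",
                nodes[ii], rs[[ii]], family = fam)
          } else
            add("partial_correlation_group", band, cn, "all", "nodal_C",
                nodes[ii], NULL, family = fam,
                note = conditionMessage(rs[[ii]]))
        }
      }
    }
    # task-evoked: Friedman across conditions, per group
    if (length(config$conditions) >= 2) {
      for (g in c(0, 1)) {
        gsubs <- subs[grp == g]
        for (metric in c("avg_pli", "C", "L", "SW")) {
          vals <- sapply(config$conditions, function(cn)
            value_of(band, cn, metric)[grp == g])
          r <- safely(friedman_test(vals))
          gname <- if (g == 0) "young" else "senior"
          if (inherits(r, "error")) {
            add("friedman_task", band, "all", gname, metric, "global", NULL,
                note = conditionMessage(r))
          } else {
            add("friedman_task", band, "all", gname, metric, "global", r)
            if (r$p_raw < 0.05) {
              ph <- posthoc_pairwise(vals)
              for (nm in names(ph))
                add("posthoc_wsr", band, nm, gname, metric, "global", ph[[nm]])
            }
          }
        }
      }
    }
  }
  # behavior
  for (task in c("0back", "2back")) {
    for (meas in c("accuracy", "rt")) {
      col <- paste0(ifelse(meas == "accuracy", "accuracy_", "rt_"), task)
      if (!col %in% names(cohort_table)) next
      y <- cohort_table[[col]][cohort_table$group == 0]
      s <- cohort_table[[col]][cohort_table$group == 1]
      add("mwu_group_behavior", NA, task, "all", meas, NA,
          mann_whitney_u(s, y))
    }
  }
  for (g in c(0, 1)) {
    gname <- if (g == 0) "young" else "senior"
    for (meas in c("accuracy", "rt")) {
      c0 <- paste0(ifelse(meas == "accuracy", "accuracy_", "rt_"), "0back")
      c2 <- paste0(ifelse(meas == "accuracy", "accuracy_", "rt_"), "2back")
      if (!all(c(c0, c2) %in% names(cohort_table))) next
      idx <- cohort_table$group == g
      add("wsr_task_behavior", NA, "0back vs 2back", gname, meas, NA,
          wilcoxon_signed_rank(cohort_table[[c2]][idx], cohort_table[[c0]][idx]))
    }
  }
  do.call(rbind, out)
}
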