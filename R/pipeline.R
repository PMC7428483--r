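#' Run configuration
#'
#' Assembles and validates all pipeline settings. Every analysis constant is
#' a named, defaulted key: nothing is hard-coded downstream.
#'
#' @param mode Input mode: `"simulate"` (generate a synthetic cohort) or
#'   `"roi-tsv"` (read ROI time-series TSVs from `input_dir`).
#' @param input_dir Directory of `<subject>_<condition>.tsv` time-series
#'   files plus `parcellation.tsv` and `scores.tsv` (roi-tsv mode).
#' @param output_dir Where report tables are written (`NULL`: don't write).
#' @param threshold_p Proportional threshold (default 0.25).
#' @param drop_k Leading volumes to drop (default 5).
#' @param cutoff_hz High-pass cutoff (default 0.01); `NA` disables filtering.
#' @param roi_radius_mm Sphere radius for NIfTI extraction (default 5).
#' @param networks Networks of interest (default `c("DMN", "FPN")`).
#' @param ranking Correlation ranking mode for thresholding.
#' @param alpha Significance threshold (default 0.05).
#' @param seed Integer seed driving all randomness.
#' @param sim Optional [sim_config()] for simulate mode (default:
#'   `sim_config()`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "roi-tsv"),
                       input_dir = NULL, output_dir = NULL,
                       threshold_p = 0.25, drop_k = 5L, cutoff_hz = 0.01,
                       roi_radius_mm = 5, networks = c("DMN", "FPN"),
                       ranking = "signed", alpha = 0.05, seed = 1L,
                       sim = NULL) {
  mode <- match.arg(mode)
  if (threshold_p <= 0 || threshold_p > 1) stop("threshold_p must lie in (0, 1]")
  if (mode == "roi-tsv") {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stop("roi-tsv mode requires an existing input_dir")
  }
  if (is.null(sim)) sim <- sim_config()
  structure(list(mode = mode, input_dir = input_dir, output_dir = output_dir,
                 threshold_p = threshold_p, drop_k = as.integer(drop_k),
                 cutoff_hz = cutoff_hz, roi_radius_mm = roi_radius_mm,
                 networks = networks, ranking = ranking, alpha = alpha,
                 seed = as.integer(seed), sim = sim),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; a `sim:` block (if present)
#' mirrors [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) {
    for (b in c("dmn_boost", "fpn_boost", "between_boost"))
      if (!is.null(y$sim[[b]])) y$sim[[b]] <- unlist(y$sim[[b]])
    do.call(sim_config, y$sim)
  } else NULL
  y$sim <- NULL
  do.call(run_config, c(y, list(sim = sim)))
}

#' Validate pipeline inputs
#'
#' Checks matrix shapes against the parcellation, per-node variance, and
#' design completeness (every subject must have every condition). Problems
#' are reported, not thrown; `fatal` entries make [run_pipeline()] abort.
#'
#' @param ts_list Nested list `ts_list[[subject]][[condition]]` of
#'   [roi_timeseries()].
#' @param parc A [parcellation()].
#' @param conditions Conditions the design requires.
#' @return Data frame with columns `level` (`"fatal"`/`"warning"`),
#'   `message`; zero rows when everything checks out.
#' @export
validate_inputs <- function(ts_list, parc, conditions = NULL) {
  probs <- list()
  add <- function(level, msg)
    probs[[length(probs) + 1L]] <<- data.frame(level = level, message = msg,
                                               stringsAsFactors = FALSE)
  if (is.null(conditions))
    conditions <- Reduce(union, lapply(ts_list, names))
  for (subj in names(ts_list)) {
    have <- names(ts_list[[subj]])
    missing <- setdiff(conditions, have)
    if (length(missing))
      add("fatal", sprintf("subject %s missing condition(s): %s",
                           subj, paste(missing, collapse = ", ")))
    extra <- setdiff(have, conditions)
    if (length(extra))
      add("warning", sprintf("subject %s has unused condition(s): %s",
                             subj, paste(extra, collapse = ", ")))
    for (cond in intersect(have, conditions)) {
      ts <- ts_list[[subj]][[cond]]
      if (ncol(ts) != nrow(parc)) {
        add("fatal", sprintf("%s/%s: %d nodes, parcellation has %d",
                             subj, cond, ncol(ts), nrow(parc)))
        next
      }
      sds <- apply(unclass(ts), 2, stats::sd)
      if (any(sds == 0))
        add("fatal", sprintf("%s/%s: zero-variance node(s): %s", subj, cond,
                             paste(colnames(ts)[sds == 0], collapse = ", ")))
    }
  }
  if (length(probs) == 0)
    return(data.frame(level = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, probs)
}

#' Analyze a cohort: metrics, repeated-measures statistics, pattern table
#'
#' The analysis core behind [run_pipeline()]: preprocesses every run (drop
#' initial volumes, high-pass filter), computes per-subject graph metrics,
#' runs the Friedman + Bonferroni-corrected post-hoc design separately for
#' the learning family (rest, EL learning, T&E learning) and the test family
#' (rest, EL test, T&E test) for each metric, compares EL and T&E scores with
#' the Wilcoxon signed-rank test, and correlates between-network connectivity
#' differences with score differences.
#'
#' @param ts_list Nested list `ts_list[[subject]][[condition]]`.
#' @param scores Data frame `subject`, `el_score`, `te_score` (or `NULL` to
#'   skip behavioral analyses).
#' @param parc A [parcellation()].
#' @param config A [run_config()] supplying constants.
#' @return A list of class `run_report`: `metrics` (tidy table),
#'   `family_results` (named list of `lc_test_result` per metric x family),
#'   `pattern` (relation table), `score_test`, `brain_behavior`,
#'   `provenance`.
#' @export
analyze_cohort <- function(ts_list, scores, parc, config = run_config()) {
  val <- validate_inputs(ts_list, parc)
  if (any(val$level == "fatal"))
    stop(paste(c("input validation failed:", val$message[val$level == "fatal"]),
               collapse = "\n  "))
  pre <- lapply(ts_list, function(by_cond) lapply(by_cond, function(ts) {
    ts <- drop_initial_volumes(ts, config$drop_k)
    if (!is.na(config$cutoff_hz)) ts <- highpass_filter(ts, config$cutoff_hz)
    ts
  }))
  metrics <- subject_condition_metrics(pre, parc, p = config$threshold_p,
                                       networks = config$networks,
                                       ranking = config$ranking)
  conds <- unique(metrics$condition)
  families <- list()
  if (all(c("rest", "el_learn", "te_learn") %in% conds))
    families$learning <- c("rest", "el_learn", "te_learn")
  if (all(c("rest", "el_test", "te_test") %in% conds))
    families$test <- c("rest", "el_test", "te_test")
  metric_names <- unique(metrics$metric)
  family_results <- list()
  tables <- list()
  for (fam in names(families)) {
    for (mn in metric_names) {
      tb <- metrics_table(metrics, mn, families[[fam]])
      key <- sprintf("%s.%s", fam, mn)
      tables[[key]] <- tb
      family_results[[key]] <- posthoc_pairwise(tb, alpha = config$alpha)
    }
  }
  pattern <- if (length(tables)) pattern_summary(tables, alpha = config$alpha) else NULL
  score_res <- NULL
  bb <- NULL
  if (!is.null(scores)) {
    score_res <- wilcoxon_signed_rank(scores$te_score, scores$el_score)
    between_metric <- grep("^between_", metric_names, value = TRUE)[1]
    if (all(c("el_learn", "te_learn") %in% conds) && !is.na(between_metric) &&
        nrow(scores) >= 5)  # Spearman needs at least 5 pairs
      bb <- brain_behavior_analysis(metrics, scores, metric = between_metric)
  }
  structure(list(metrics = metrics, family_results = family_results,
                 pattern = pattern, score_test = score_res,
                 brain_behavior = bb, scores = scores,
                 provenance = list(config = config,
                                   package_version =
                                     as.character(utils::packageVersion("learnconn")),
                                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "run_report")
}

#' Reshape tidy metrics into a cohort table
#'
#' @param metrics Tidy table from [subject_condition_metrics()].
#' @param metric Metric name to extract.
#' @param conditions Condition columns, in order.
#' @return A [cohort_table()] (subjects x conditions).
#' @export
metrics_table <- function(metrics, metric, conditions) {
  sub <- metrics[metrics$metric == metric & metrics$condition %in% conditions, ]
  wide <- stats::reshape(sub[, c("subject", "condition", "value")],
                         idvar = "subject", timevar = "condition",
                         direction = "wide")
  m <- as.matrix(wide[, sprintf("value.%s", conditions), drop = FALSE])
  rownames(m) <- wide$subject
  colnames(m) <- conditions
  cohort_table(m)
}

#' @export
print.run_report <- function(x, ...) {
  cat("== learnconn run report ==\n")
  cat(sprintf("%d subjects, conditions: %s\n",
              length(unique(x$metrics$subject)),
              paste(unique(x$metrics$condition), collapse = ", ")))
  if (!is.null(x$score_test)) {
    cat("\nT&E vs EL scores — ")
    print(x$score_test)
  }
  if (!is.null(x$pattern)) {
    cat("\nRelation pattern:\n")
    print(x$pattern, row.names = FALSE)
  }
  if (!is.null(x$brain_behavior)) {
    cat("\nBrain-behavior (connectivity diff vs score diff) — ")
    print(x$brain_behavior$test)
  }
  invisible(x)
}

#' Run the full pipeline from a configuration
#'
#' Simulate-mode runs set the seed, generate a synthetic cohort and analyze
#' it; roi-tsv runs load time series, parcellation and scores from
#' `input_dir`. If `output_dir` is set, tidy TSV artifacts are written:
#' `metrics.tsv`, `stat_results.tsv`, `pattern.tsv`, `differences.tsv`.
#'
#' @param config A [run_config()] (or a path to a YAML file readable by
#'   [read_run_config()]).
#' @return A `run_report`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "simulate") {
    set.seed(config$seed)
    cohort <- simulate_cohort(config$sim)
    ts_list <- cohort$ts; scores <- cohort$scores; parc <- cohort$parcellation
  } else {
    parc <- read_parcellation(file.path(config$input_dir, "parcellation.tsv"))
    score_path <- file.path(config$input_dir, "scores.tsv")
    scores <- if (file.exists(score_path))
      utils::read.table(score_path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE) else NULL
    files <- list.files(config$input_dir, pattern = "^.+_.+\\.tsv$",
                        full.names = TRUE)
    files <- files[!basename(files) %in% c("parcellation.tsv", "scores.tsv")]
    if (length(files) == 0) stop("no time-series TSV files found in input_dir")
    ts_list <- list()
    for (f in files) {
      ts <- read_roi_timeseries(f)
      subj <- attr(ts, "subject"); cond <- attr(ts, "condition")
      if (is.null(subj) || is.null(cond)) {
        base <- sub("\\.tsv$", "", basename(f))
        parts <- strsplit(base, "_", fixed = TRUE)[[1]]
        subj <- parts[1]; cond <- paste(parts[-1], collapse = "_")
      }
      ts_list[[subj]][[cond]] <- ts
    }
  }
  report <- analyze_cohort(ts_list, scores, parc, config)
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write a run report's tables as TSV
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(report$metrics, "metrics.tsv")
  if (length(report$family_results)) {
    res <- do.call(rbind, lapply(names(report$family_results), function(k) {
      r <- report$family_results[[k]]
      cbind(family_metric = k, omnibus_stat = r$statistic,
            omnibus_p = r$p_value, r$comparisons)
    }))
    w(res, "stat_results.tsv")
  }
  if (!is.null(report$pattern)) w(report$pattern, "pattern.tsv")
  if (!is.null(report$brain_behavior))
    w(report$brain_behavior$differences, "differences.tsv")
  invisible(paths)
}

#' Write a synthetic cohort to disk in the pipeline's TSV formats
#'
#' Produces the same layout `run_pipeline()`'s roi-tsv mode reads:
#' one `<subject>_<condition>.tsv` per run, `parcellation.tsv`, `scores.tsv`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.tsv"))
  utils::write.table(cohort$scores, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (subj in names(cohort$ts))
    for (cond in names(cohort$ts[[subj]]))
      write_roi_timeseries(cohort$ts[[subj]][[cond]],
                           file.path(dir, sprintf("%s_%s.tsv", subj, cond)),
                           subject = subj, condition = cond)
  invisible(dir)
}
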