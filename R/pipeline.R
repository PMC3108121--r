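CONFIG_KEYS <- c("seed", "n_per_group", "sampling_rate", "duration",
                 "shared_frac", "axes", "segment_sec", "overlap",
                 "cf_rest_threshold", "postural_ratio_threshold",
                 "cf_postural_threshold", "log_level")

#' Run configuration
#'
#' Validated key/value configuration for the pipeline runners. Unknown keys
#' are rejected so that typos never silently fall back to defaults.
#'
#' @param ... configuration values among: `seed`, `n_per_group`,
#'   `sampling_rate`, `duration`, `shared_frac`, `axes`, `segment_sec`,
#'   `overlap`, `cf_rest_threshold`, `postural_ratio_threshold`,
#'   `cf_postural_threshold`, `log_level`.
#' @return A `run_config` list with defaults filled in.
#' @export
run_config <- function(...) {
  vals <- list(...)
  if (length(vals) && (is.null(names(vals)) || any(names(vals) == "")))
    stop_tremor("all configuration values must be named")
  unknown <- setdiff(names(vals), CONFIG_KEYS)
  if (length(unknown))
    stop_tremor("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(seed = 1L, n_per_group = c(37L, 20L, 20L),
                   sampling_rate = 128, duration = 16, shared_frac = 0.8,
                   axes = 2L, segment_sec = 4, overlap = 0.5,
                   cf_rest_threshold = 6.5, postural_ratio_threshold = 1.5,
                   cf_postural_threshold = 6.5, log_level = "info")
  cfg <- utils::modifyList(defaults, vals)
  # touch the constructors so invalid values fail here, not mid-pipeline
  signal_spec(cfg$sampling_rate, cfg$duration, cfg$seed)
  spectral_config(segment_sec = cfg$segment_sec, overlap = cfg$overlap)
  tremor_rule(cfg$cf_rest_threshold, cfg$postural_ratio_threshold,
              cfg$cf_postural_threshold)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_tremor("config file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, as.list(vals))
}

config_fingerprint <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

run_meta <- function(cfg) {
  list(tool = "tremorspec",
       version = as.character(packageVersion("tremorspec")),
       seed = cfg$seed, config_md5 = config_fingerprint(cfg))
}

write_tsv_with_meta <- function(df, path, cfg) {
  meta <- run_meta(cfg)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tremorspec %s seed=%s config_md5=%s",
                     meta$version, meta$seed, meta$config_md5), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline stage: simulate a cohort to disk
#'
#' @param out_dir output directory (signal files, `cohort.tsv`,
#'   `manifest.json`).
#' @param config a [run_config].
#' @return The simulation object, invisibly.
#' @export
run_simulate <- function(out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  sim <- simulate_cohort(
    n_per_group = config$n_per_group,
    spec = signal_spec(config$sampling_rate, config$duration),
    seed = config$seed, shared_frac = config$shared_frac,
    axes = config$axes, dir = out_dir)
  invisible(sim)
}

#' Pipeline stage: batch tremor metrics over a signal directory
#'
#' @param signals_dir directory of signal files.
#' @param out_file output TSV (optional).
#' @param config a [run_config].
#' @return The metrics `data.frame`; attribute `"n_failed"` counts skipped
#'   files.
#' @export
run_analyze <- function(signals_dir, out_file = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  scfg <- spectral_config(segment_sec = config$segment_sec,
                          overlap = config$overlap)
  metrics <- analyze_records(signals_dir, scfg)
  if (!is.null(out_file)) write_tsv_with_meta(metrics, out_file, config)
  metrics
}

#' Read a cohort or metrics TSV written by the pipeline
#'
#' @param path TSV path (comment headers starting with `#` are skipped).
#' @return A `data.frame`.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop_tremor("file not found: ", path)
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Normative reference table for healthy controls
#'
#' Reads an optional user-supplied table of healthy-control postural tremor
#' values per age decade (columns `decade`, `postural_intensity_mean`,
#' `postural_cf_mean`), used only for fold-of-control reporting. No
#' normative values are bundled: they derive from an external published
#' source and must be supplied by the user.
#'
#' @param path TSV path.
#' @return A validated `data.frame`.
#' @export
read_normative_table <- function(path) {
  df <- read_cohort_table(path)
  need <- c("decade", "postural_intensity_mean", "postural_cf_mean")
  if (!all(need %in% names(df)))
    stop_tremor("normative table needs columns: ", paste(need, collapse = ", "))
  if (is.unsorted(df$decade, strictly = TRUE))
    stop_tremor("normative table decades must be strictly increasing")
  if (any(df$postural_intensity_mean <= 0) || any(df$postural_cf_mean <= 0))
    stop_tremor("normative values must be positive")
  df
}

#' Pipeline stage: cohort statistics report
#'
#' Composes the statistics layer over an analyzed cohort: group mean/SEM
#' summaries in the layout of the study tables, rest-vs-postural fold
#' changes with paired t-tests per group and side, two-way ANOVA variance
#' partitions, slope-vs-zero regressions of intensity and Cf on age (plus
#' exposure covariates for welders), and the clinical-sign Fisher panel
#' from the published counts. When a normative table is supplied, postural
#' intensity fold-of-control columns are added.
#'
#' @param cohort cohort `data.frame` with attached metrics (see
#'   [attach_metrics()]), or a path to such a TSV.
#' @param out_file optional JSON report path.
#' @param config a [run_config].
#' @param normative optional normative table (see [read_normative_table()]).
#' @return The report as a list.
#' @export
run_stats <- function(cohort, out_file = NULL, config = run_config(),
                      normative = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(cohort)) cohort <- read_cohort_table(cohort)
  if (nrow(cohort) == 0L) stop_tremor("empty cohort")
  groups <- intersect(GROUPS, unique(cohort$group))
  summaries <- summarize_groups(cohort, groups = groups)
  folds <- list()
  for (g in groups) for (sd_ in SIDES) {
    fc <- tryCatch(fold_change(cohort, g, sd_), tremorspec_error = function(e) NULL)
    if (!is.null(fc)) folds[[paste(g, sd_, sep = "_")]] <- unclass(fc)
  }
  anovas <- lapply(setNames(groups, groups), function(g) {
    tryCatch(as.data.frame(two_way_anova(cohort, g)),
             tremorspec_error = function(e) NULL)
  })
  regs <- list()
  for (g in groups) {
    preds <- "age"
    if (g == "WELDER")
      preds <- c(preds, "years_exposure", "years_since_exposure")
    for (p in preds) for (m in c("intensity", "center_freq")) {
      rr <- tryCatch(
        regress_vs_covariate(cohort, g, m, p, condition = "postural",
                             side = "R"),
        tremorspec_error = function(e) NULL)
      if (!is.null(rr)) regs[[paste(g, m, p, sep = "_")]] <- unclass(rr)
    }
  }
  report <- list(meta = run_meta(config),
                 group_summaries = summaries,
                 fold_changes = folds,
                 anova = anovas,
                 regressions = regs,
                 sign_panel = table2_report(),
                 note = "Unadjusted per-test p-values, matching per-row reporting.")
  if (!is.null(normative)) {
    ctrl <- mean(normative$postural_intensity_mean)
    pc <- summaries[summaries$metric == "intensity" &
                      summaries$condition == "postural", ]
    pc$fold_of_control <- pc$mean / ctrl
    report$fold_of_control <- pc
    report$control_postural_intensity_mean <- ctrl
  }
  if (!is.null(out_file))
    jsonlite::write_json(report, out_file, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE, force = TRUE)
  report
}

#' Pipeline stage: classify an analyzed cohort
#'
#' @param cohort cohort with attached metrics (or TSV path).
#' @param out_file optional TSV of per-subject classifications.
#' @param config a [run_config] (thresholds are taken from it).
#' @return Classification table; if true labels are present, attribute
#'   `"evaluation"` holds the [evaluate_classifier()] result.
#' @export
run_classify <- function(cohort, out_file = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(cohort)) cohort <- read_cohort_table(cohort)
  rule <- tremor_rule(config$cf_rest_threshold,
                      config$postural_ratio_threshold,
                      config$cf_postural_threshold)
  cls <- classify_cohort(cohort, rule)
  if (!is.null(out_file)) write_tsv_with_meta(cls, out_file, config)
  if ("group" %in% names(cls))
    attr(cls, "evaluation") <- evaluate_classifier(cohort, rule)
  cls
}

#' End-to-end pipeline report
#'
#' Runs simulate -> analyze -> stats -> classify in one call (or starting
#' from an existing signal directory) and writes a combined JSON report.
#'
#' @param out_dir working directory for signals and outputs.
#' @param config a [run_config].
#' @param simulate if `FALSE`, `out_dir` must already contain signals and
#'   `cohort.tsv`.
#' @param normative optional normative table.
#' @return The combined report list, invisibly.
#' @export
run_report <- function(out_dir, config = run_config(), simulate = TRUE,
                       normative = NULL) {
  if (simulate) run_simulate(out_dir, config)
  metrics <- run_analyze(out_dir, file.path(out_dir, "metrics.tsv"), config)
  cohort <- attach_metrics(read_cohort_table(file.path(out_dir, "cohort.tsv")),
                           metrics)
  stats <- run_stats(cohort, config = config, normative = normative)
  cls <- run_classify(cohort, file.path(out_dir, "classifications.tsv"),
                      config)
  ev <- attr(cls, "evaluation")
  report <- c(stats, list(
    classifier = if (!is.null(ev))
      list(accuracy = ev$accuracy,
           recall = as.list(ev$recall),
           confusion = as.data.frame(ev$confusion))))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, force = TRUE)
  invisible(report)
}
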