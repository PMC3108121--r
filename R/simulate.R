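#' Simulate one subject from a group archetype
#'
#' Draws a subject profile: demographics (age, sex, age at symptom onset,
#' and for welders years of / since fume exposure), independent Bernoulli
#' clinical signs at the archetype's rates, and realized tremor component
#' parameters for each condition x side cell.
#'
#' Between-subject draws reproduce the archetype's cell means and SDs
#' exactly: intensities are lognormal matched to the target mean/SD (the
#' published SDs exceed the means for most cells, so a zero-truncated normal
#' would not preserve the mean), and center frequencies are normal truncated
#' to the analysis band by resampling. A subject-level latent severity and a
#' subject-level frequency trait are shared across the four cells with
#' weight `shared_frac` (default 0.8 of the variance), reflecting the strong
#' within-subject correlation of repeated tremor measurements; cell margins
#' are unaffected by this choice.
#'
#' @param archetype a [tremor_archetype].
#' @param spec a [signal_spec] (stored for later rendering).
#' @param seed optional seed; a fixed seed gives an identical subject.
#' @param shared_frac fraction of between-subject variance shared across the
#'   four condition x side cells, in `[0, 1]`.
#' @param subject_id subject label.
#' @return A `subject_profile` list with elements `subject_id`, `group`,
#'   demographics, `signs` (named 0/1 vector), and `components` (a list of
#'   [tremor_component]s keyed `"rest_R"`, `"rest_L"`, `"postural_R"`,
#'   `"postural_L"`, each with attributes `target_intensity` and `target_cf`).
#' @export
simulate_subject <- function(archetype, spec = signal_spec(), seed = NULL,
                             shared_frac = 0.8, subject_id = NULL) {
  stopifnot(inherits(archetype, "tremor_archetype"))
  if (shared_frac < 0 || shared_frac > 1)
    stop_tremor("'shared_frac' must lie in [0, 1]")
  with_seed(seed, {
    d <- archetype$demographics
    age <- rnorm_trunc(1, d$age_mean, d$age_sd, lower = 18, upper = 95)
    onset <- rnorm_trunc(1, d$onset_mean, d$onset_sd, lower = 10,
                         upper = age - 0.5)
    sex <- if (runif(1) < d$male_prop) "M" else "F"
    expo <- since <- NA_real_
    if (archetype$group == "WELDER") {
      expo <- rnorm_trunc(1, d$exposure_mean, d$exposure_sd, lower = 0.5)
      since <- rnorm_trunc(1, d$since_exposure_mean, d$since_exposure_sd,
                           lower = 0)
    }
    signs <- vapply(archetype$sign_probs, function(p) rbinom(1, 1, p),
                    integer(1))
    z_int <- rnorm(1)  # latent severity trait (log-intensity scale)
    z_cf <- rnorm(1)   # latent frequency trait
    a <- sqrt(shared_frac); b <- sqrt(1 - shared_frac)
    cells <- archetype$cells
    components <- vector("list", nrow(cells))
    names(components) <- paste(cells$condition, cells$side, sep = "_")
    for (i in seq_len(nrow(cells))) {
      zi <- a * z_int + b * rnorm(1)
      intensity <- rlnorm_matched(1, cells$intensity_mean[i],
                                  cells$intensity_sd[i], z = zi)
      cf <- NA_real_
      for (try in 1:200) {
        cf <- cells$cf_mean[i] + cells$cf_sd[i] * (a * z_cf + b * rnorm(1))
        if (cf > 0.95 && cf < 14.9) break
        if (try == 200) cf <- min(max(cf, 0.95), 14.9)
      }
      comp <- component_from_targets(
        intensity = intensity, center_freq = cf,
        harmonic_fraction = cells$hi_mean[i],
        freq_jitter_sd = cells$dispersion_mean[i] / 2)
      attr(comp, "target_intensity") <- intensity
      attr(comp, "target_cf") <- cf
      components[[i]] <- comp
    }
    structure(list(
      subject_id = subject_id %||% "S1", group = archetype$group,
      age = age, sex = sex, age_at_onset = onset,
      years_exposure = expo, years_since_exposure = since,
      signs = signs, components = components, spec = spec),
      class = "subject_profile")
  })
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s (%s), age %.0f, sex %s\n",
              x$subject_id, x$group, x$age, x$sex))
  tg <- vapply(x$components, attr, numeric(1), "target_intensity")
  cat("  target intensities:",
      paste(sprintf("%s=%.3f", names(tg), tg), collapse = ", "), "\n")
  invisible(x)
}

#' Render the four recordings of one subject
#'
#' @param profile a `subject_profile`.
#' @param axes number of accelerometer axes.
#' @return Named list of four [accel_record]s (`rest_R`, `rest_L`,
#'   `postural_R`, `postural_L`).
#' @export
render_subject <- function(profile, axes = 2) {
  stopifnot(inherits(profile, "subject_profile"))
  out <- lapply(names(profile$components), function(key) {
    cs <- strsplit(key, "_", fixed = TRUE)[[1]]
    render_tremor_signal(profile$components[[key]], profile$spec, axes = axes,
                         subject_id = profile$subject_id,
                         condition = cs[1], side = cs[2])
  })
  names(out) <- names(profile$components)
  out
}

#' Simulate a labelled multi-group tremor cohort
#'
#' Generates `n_per_group` subjects from each archetype and, when
#' `render = TRUE`, the four acceleration recordings (rest/postural x R/L)
#' of every subject. With `dir` set, writes one signal file per recording,
#' the cohort table (`cohort.tsv`), and a `manifest.json` recording seed,
#' package version and file list, so all downstream stages can run from the
#' directory alone.
#'
#' @param archetypes list of [tremor_archetype]s (defaults to the three
#'   built-in groups).
#' @param n_per_group integer vector (recycled) of subjects per archetype;
#'   the study sizes are `c(37, 20, 20)`.
#' @param spec a [signal_spec].
#' @param seed integer seed; fixed seed implies a bit-identical cohort.
#' @param shared_frac see [simulate_subject()].
#' @param render render signals (set `FALSE` for a parameters-only cohort).
#' @param axes accelerometer axes per recording.
#' @param dir optional output directory.
#' @return A `tremor_cohort_sim` list: `cohort` (data.frame of demographics
#'   and signs), `profiles`, and `records` (flat named list, or `NULL`).
#' @examples
#' sim <- simulate_cohort(n_per_group = 1, seed = 1, render = FALSE)
#' sim$cohort[, 1:5]
#' @export
simulate_cohort <- function(archetypes = tremor_archetypes(),
                            n_per_group = c(37, 20, 20),
                            spec = signal_spec(), seed = NULL,
                            shared_frac = 0.8, render = TRUE, axes = 2,
                            dir = NULL) {
  n_per_group <- rep_len(as.integer(n_per_group), length(archetypes))
  if (any(n_per_group < 1L)) stop_tremor("'n_per_group' must be >= 1")
  with_seed(seed, {
    profiles <- list()
    prefixes <- substr(names(archetypes) %||%
                         vapply(archetypes, `[[`, "", "group"), 1, 1)
    for (g in seq_along(archetypes)) {
      for (i in seq_len(n_per_group[g])) {
        id <- sprintf("%s%03d", prefixes[g], i)
        profiles[[id]] <- simulate_subject(archetypes[[g]], spec = spec,
                                           shared_frac = shared_frac,
                                           subject_id = id)
      }
    }
    records <- NULL
    if (render) {
      records <- list()
      for (id in names(profiles)) {
        recs <- render_subject(profiles[[id]], axes = axes)
        names(recs) <- paste(id, names(recs), sep = "_")
        records <- c(records, recs)
      }
    }
    cohort <- do.call(rbind, lapply(profiles, function(p) {
      base <- data.frame(
        subject_id = p$subject_id, group = p$group, age = p$age, sex = p$sex,
        age_at_onset = p$age_at_onset, years_exposure = p$years_exposure,
        years_since_exposure = p$years_since_exposure,
        stringsAsFactors = FALSE)
      cbind(base, as.data.frame(as.list(p$signs)))
    }))
    rownames(cohort) <- NULL
    out <- structure(list(cohort = cohort, profiles = profiles,
                          records = records, seed = seed, spec = spec),
                     class = "tremor_cohort_sim")
    if (!is.null(dir)) write_cohort_sim(out, dir)
    out
  })
}

#' @export
print.tremor_cohort_sim <- function(x, ...) {
  cat(sprintf("<tremor_cohort_sim> %d subjects (%s), %s recordings\n",
              nrow(x$cohort),
              paste(sprintf("%s=%d", names(table(x$cohort$group)),
                            table(x$cohort$group)), collapse = ", "),
              if (is.null(x$records)) "no" else length(x$records)))
  invisible(x)
}

write_cohort_sim <- function(sim, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_tremor("cannot create output directory: ", dir)
  write.table(sim$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- character(0)
  for (nm in names(sim$records)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    write_accel_record(sim$records[[nm]], f)
    files <- c(files, basename(f))
  }
  manifest <- list(tool = "tremorspec",
                   version = as.character(packageVersion("tremorspec")),
                   seed = sim$seed,
                   sampling_rate_hz = sim$spec$sampling_rate,
                   duration_s = sim$spec$duration,
                   n_subjects = nrow(sim$cohort),
                   signal_files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Attach per-recording metrics to a cohort table
#'
#' Pivots a long metrics table (one row per subject x condition x side, as
#' returned by [analyze_records()]) into wide per-cell columns named
#' `<condition>_<side>_<metric>` and joins them onto the cohort table by
#' `subject_id`. For biaxial pipelines each row of `metrics` already reflects
#' the axis-averaged spectrum.
#'
#' @param cohort cohort `data.frame` with a `subject_id` column.
#' @param metrics long metrics `data.frame`.
#' @return The cohort with metric columns appended.
#' @export
attach_metrics <- function(cohort, metrics) {
  stopifnot("subject_id" %in% names(cohort),
            all(c("subject_id", "condition", "side") %in% names(metrics)))
  vals <- setdiff(names(metrics), c("subject_id", "condition", "side"))
  for (cond in CONDITIONS) for (sd in SIDES) {
    sub <- metrics[metrics$condition == cond & metrics$side == sd, ]
    idx <- match(cohort$subject_id, sub$subject_id)
    for (v in vals)
      cohort[[paste(cond, sd, v, sep = "_")]] <- sub[[v]][idx]
  }
  cohort
}
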