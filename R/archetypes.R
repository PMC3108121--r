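#' Built-in group archetypes
#'
#' Population targets driving the cohort simulator, one archetype per study
#' group: occupationally exposed welders with a manganism diagnosis
#' (`"WELDER"`, n = 37), de novo idiopathic Parkinson's disease (`"IPD"`,
#' n = 20) and essential tremor (`"ET"`, n = 20). Each archetype carries, per
#' condition (rest/postural) x side (R/L) cell, the target mean and
#' between-subject SD of tremor intensity and center frequency, the target
#' dispersion and harmonic-index means, plus demographic moments and
#' clinical-sign Bernoulli rates. Between-subject SDs are reconstructed from
#' the published standard errors as `SEM * sqrt(n)`.
#'
#' Clinical-sign rates for welders and IPD come from the published sign
#' frequencies; the essential-tremor archetype (whose signs were not
#' tabulated) presents tremor in every subject and no parkinsonian signs.
#'
#' @param group `"WELDER"`, `"IPD"` or `"ET"`.
#' @return A `tremor_archetype` object.
#' @seealso [simulate_subject()], [simulate_cohort()]
#' @export
tremor_archetype <- function(group = c("WELDER", "IPD", "ET")) {
  group <- match.arg(group)
  .archetypes[[group]]
}

#' @rdname tremor_archetype
#' @export
tremor_archetypes <- function() .archetypes

make_archetype <- function(group, n_study, cells, demographics, sign_probs) {
  stopifnot(nrow(cells) == 4L, all(cells$intensity_mean > 0),
            all(cells$cf_mean > 0.9 & cells$cf_mean < 15),
            all(sign_probs >= 0 & sign_probs <= 1))
  cells$intensity_sd <- cells$intensity_sem * sqrt(n_study)
  cells$cf_sd <- cells$cf_sem * sqrt(n_study)
  structure(list(group = group, n_study = n_study, cells = cells,
                 demographics = demographics, sign_probs = sign_probs),
            class = "tremor_archetype")
}

#' @export
print.tremor_archetype <- function(x, ...) {
  cat(sprintf("<tremor_archetype> %s (study n = %d)\n", x$group, x$n_study))
  print.data.frame(x$cells[c("condition", "side", "intensity_mean",
                             "intensity_sd", "cf_mean", "cf_sd",
                             "dispersion_mean", "hi_mean")],
                   row.names = FALSE, digits = 3)
  invisible(x)
}

archetype_cells <- function(int_mean, int_sem, cf_mean, cf_sem, disp, hi) {
  data.frame(
    condition = rep(CONDITIONS, each = 2L), side = rep(SIDES, 2L),
    intensity_mean = int_mean, intensity_sem = int_sem,
    cf_mean = cf_mean, cf_sem = cf_sem,
    dispersion_mean = disp, hi_mean = hi, stringsAsFactors = FALSE)
}

# cell order: rest-R, rest-L, postural-R, postural-L
.archetypes <- list(
  WELDER = make_archetype(
    "WELDER", 37L,
    archetype_cells(
      int_mean = c(0.774, 0.706, 1.61, 1.07),
      int_sem  = c(0.194, 0.175, 0.457, 0.335),
      cf_mean  = c(7.05, 7.59, 7.12, 7.28),
      cf_sem   = c(0.263, 0.227, 0.208, 1.54),
      disp     = c(1.19, 1.90, 1.36, 2.04),
      hi       = c(0.941, 0.917, 0.910, 0.936)),
    demographics = list(age_mean = 54.8, age_sd = 10.7,
                        onset_mean = 47.9, onset_sd = 11.7,
                        male_prop = 36 / 37,
                        exposure_mean = 25.6, exposure_sd = 10.8,
                        since_exposure_mean = 7.8, since_exposure_sd = 10.7),
    sign_probs = c(initial_tremor = 29 / 32, initial_bradykinesia = 5 / 32,
                   initial_balance = 7 / 31, initial_limb_cramping = 7 / 32,
                   resting_tremor = 19 / 31, action_tremor = 27 / 31,
                   postural_tremor = 21 / 31, dystonic_limb = 1 / 31,
                   cogwheel_rigidity = 8 / 29, asymmetric_tremor = 4 / 29,
                   asymmetric_rigidity = 11 / 29, asymmetric_bradykinesia = 11 / 29,
                   dyshidrosis = 11 / 29, dizziness_standing = 0 / 29)),
  IPD = make_archetype(
    "IPD", 20L,
    archetype_cells(
      int_mean = c(0.867, 0.633, 0.937, 0.613),
      int_sem  = c(0.338, 0.424, 0.377, 0.235),
      cf_mean  = c(6.64, 6.65, 6.10, 6.32),
      cf_sem   = c(0.367, 0.377, 0.315, 0.323),
      disp     = c(1.93, 1.59, 2.21, 2.24),
      hi       = c(0.946, 0.944, 0.94, 0.936)),
    demographics = list(age_mean = 65.3, age_sd = 9.15,
                        onset_mean = 59.5, onset_sd = 9.68,
                        male_prop = 13 / 20,
                        exposure_mean = NA, exposure_sd = NA,
                        since_exposure_mean = NA, since_exposure_sd = NA),
    sign_probs = c(initial_tremor = 14 / 17, initial_bradykinesia = 3 / 17,
                   initial_balance = 1 / 17, initial_limb_cramping = 0 / 17,
                   resting_tremor = 9 / 16, action_tremor = 3 / 16,
                   postural_tremor = 2 / 16, dystonic_limb = 1 / 17,
                   cogwheel_rigidity = 3 / 17, asymmetric_tremor = 10 / 16,
                   asymmetric_rigidity = 11 / 12, asymmetric_bradykinesia = 11 / 11,
                   dyshidrosis = 0 / 17, dizziness_standing = 1 / 17)),
  ET = make_archetype(
    "ET", 20L,
    archetype_cells(
      int_mean = c(0.241, 0.124, 0.588, 0.599),
      int_sem  = c(0.076, 0.035, 0.140, 0.175),
      cf_mean  = c(5.829, 5.995, 6.674, 7.055),
      cf_sem   = c(0.291, 0.355, 0.340, 0.386),
      disp     = c(1.755, 2.270, 2.580, 2.855),
      hi       = c(0.956, 0.939, 0.936, 0.918)),
    demographics = list(age_mean = 59.5, age_sd = 14.9,
                        onset_mean = 50, onset_sd = 14.8,
                        male_prop = 9 / 20,
                        exposure_mean = NA, exposure_sd = NA,
                        since_exposure_mean = NA, since_exposure_sd = NA),
    sign_probs = c(initial_tremor = 1, initial_bradykinesia = 0,
                   initial_balance = 0, initial_limb_cramping = 0,
                   resting_tremor = 0, action_tremor = 1,
                   postural_tremor = 1, dystonic_limb = 0,
                   cogwheel_rigidity = 0, asymmetric_tremor = 0,
                   asymmetric_rigidity = 0, asymmetric_bradykinesia = 0,
                   dyshidrosis = 0, dizziness_standing = 0))
)

#' Published clinical-sign 2x2 counts (welders vs IPD)
#'
#' The per-sign counts of subjects presenting each symptom or sign among the
#' welder and IPD groups, with their varying per-sign denominators
#' (complete-case examination counts). These printed counts are the input for
#' reproducing the clinical-sign Fisher panel; see [table2_report()].
#'
#' @return A `data.frame` with columns `sign`, `welders_pos`, `welders_n`,
#'   `ipd_pos`, `ipd_n`.
#' @export
clinical_sign_counts <- function() {
  data.frame(
    sign = c("initial_tremor", "initial_bradykinesia", "initial_balance",
             "initial_limb_cramping", "resting_tremor", "action_tremor",
             "postural_tremor", "dystonic_limb", "cogwheel_rigidity",
             "asymmetric_tremor", "asymmetric_rigidity",
             "asymmetric_bradykinesia", "dyshidrosis", "dizziness_standing"),
    welders_pos = c(29L, 5L, 7L, 7L, 19L, 27L, 21L, 1L, 8L, 4L, 11L, 11L, 11L, 0L),
    welders_n   = c(32L, 32L, 31L, 32L, 31L, 31L, 31L, 31L, 29L, 29L, 29L, 29L, 29L, 29L),
    ipd_pos     = c(14L, 3L, 1L, 0L, 9L, 3L, 2L, 1L, 3L, 10L, 11L, 11L, 0L, 1L),
    ipd_n       = c(17L, 17L, 17L, 17L, 16L, 16L, 16L, 17L, 17L, 16L, 12L, 11L, 17L, 17L),
    stringsAsFactors = FALSE)
}
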