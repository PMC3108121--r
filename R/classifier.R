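#' Rule-based tremor group classifier
#'
#' A transparent three-branch decision rule over the headline discriminating
#' features: postural intensification of tremor and the center frequency of
#' rest and postural tremor. With features averaged over available sides:
#'
#' 1. postural/rest intensity ratio below `postural_ratio_threshold` **and**
#'    postural Cf below `cf_postural_threshold` -> `IPD` (tremor does not
#'    intensify with arms extended and oscillates slowly);
#' 2. otherwise, rest Cf at or above `cf_rest_threshold` -> `WELDER`
#'    (fast rest tremor distinguishes welders from essential tremor);
#' 3. otherwise -> `ET`.
#'
#' Threshold defaults (6.5 Hz, 1.5, 6.5 Hz) sit in the gaps between the
#' published group means (welder rest Cf about 7.0-7.6 Hz vs essential
#' tremor about 5.8-6.0 Hz; parkinsonian postural Cf about 6.1-6.3 Hz with
#' intensity ratio near 1).
#'
#' @param cf_rest_threshold Hz; rest-tremor Cf split between welders and ET.
#' @param postural_ratio_threshold unitless postural/rest intensity ratio.
#' @param cf_postural_threshold Hz; postural Cf ceiling of the IPD branch.
#' @return A `tremor_rule` object; use [predict.tremor_rule()] /
#'   [classify_cohort()] to apply it.
#' @export
tremor_rule <- function(cf_rest_threshold = 6.5, postural_ratio_threshold = 1.5,
                        cf_postural_threshold = 6.5) {
  for (v in c(cf_rest_threshold, cf_postural_threshold))
    if (v <= 0.9 || v >= 15)
      stop_tremor("Cf thresholds must lie inside the 0.9-15 Hz analysis band")
  if (postural_ratio_threshold <= 0)
    stop_tremor("'postural_ratio_threshold' must be positive")
  structure(list(cf_rest_threshold = cf_rest_threshold,
                 postural_ratio_threshold = postural_ratio_threshold,
                 cf_postural_threshold = cf_postural_threshold),
            class = "tremor_rule")
}

#' @export
print.tremor_rule <- function(x, ...) {
  cat("<tremor_rule>\n",
      sprintf("  IPD    if intensity ratio < %g and postural Cf < %g Hz\n",
              x$postural_ratio_threshold, x$cf_postural_threshold),
      sprintf("  WELDER else if rest Cf >= %g Hz\n", x$cf_rest_threshold),
      "  ET     otherwise\n", sep = "")
  invisible(x)
}

#' Classifier features of each subject
#'
#' Side-averaged rest Cf, postural Cf and postural/rest intensity ratio
#' (ratio computed per side, then averaged over sides with both conditions
#' present). Subjects missing both sides of any feature get `NA`.
#'
#' @param cohort cohort with attached metrics.
#' @return `data.frame` with columns `subject_id`, `group` (if present),
#'   `rest_cf`, `postural_cf`, `intensity_ratio`.
#' @export
subject_features <- function(cohort) {
  pick <- function(cond, sd_, m) {
    col <- paste(cond, sd_, m, sep = "_")
    if (col %in% names(cohort)) cohort[[col]] else rep(NA_real_, nrow(cohort))
  }
  row_mean <- function(a, b) {
    out <- rowMeans(cbind(a, b), na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  }
  ratio_side <- function(sd_) pick("postural", sd_, "intensity") /
    pick("rest", sd_, "intensity")
  out <- data.frame(
    subject_id = cohort$subject_id,
    rest_cf = row_mean(pick("rest", "R", "center_freq"),
                       pick("rest", "L", "center_freq")),
    postural_cf = row_mean(pick("postural", "R", "center_freq"),
                           pick("postural", "L", "center_freq")),
    intensity_ratio = row_mean(ratio_side("R"), ratio_side("L")),
    stringsAsFactors = FALSE)
  if ("group" %in% names(cohort)) out$group <- cohort$group
  out
}

#' Classify one subject from its features
#'
#' @param rest_cf,postural_cf,intensity_ratio side-averaged features.
#' @param rule a [tremor_rule].
#' @return A `classification` list: `predicted`, `trace` (which branch
#'   fired), and the features.
#' @export
classify_subject <- function(rest_cf, postural_cf, intensity_ratio,
                             rule = tremor_rule()) {
  stopifnot(inherits(rule, "tremor_rule"))
  if (!is.finite(rest_cf) || !is.finite(postural_cf) ||
      !is.finite(intensity_ratio))
    stop_tremor("all three features must be available (both sides missing?)")
  if (intensity_ratio < rule$postural_ratio_threshold &&
      postural_cf < rule$cf_postural_threshold) {
    predicted <- "IPD"
    trace <- sprintf("ratio %.2f < %g and postural Cf %.2f < %g",
                     intensity_ratio, rule$postural_ratio_threshold,
                     postural_cf, rule$cf_postural_threshold)
  } else if (rest_cf >= rule$cf_rest_threshold) {
    predicted <- "WELDER"
    trace <- sprintf("not IPD branch; rest Cf %.2f >= %g",
                     rest_cf, rule$cf_rest_threshold)
  } else {
    predicted <- "ET"
    trace <- sprintf("not IPD branch; rest Cf %.2f < %g",
                     rest_cf, rule$cf_rest_threshold)
  }
  structure(list(predicted = predicted, trace = trace, rest_cf = rest_cf,
                 postural_cf = postural_cf, intensity_ratio = intensity_ratio),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification> %s (%s)\n", x$predicted, x$trace))
  invisible(x)
}

#' Classify every subject of a cohort
#'
#' @param cohort cohort with attached metrics (or a [subject_features()]
#'   table).
#' @param rule a [tremor_rule].
#' @return The feature table with `predicted` and `trace` columns appended.
#' @export
classify_cohort <- function(cohort, rule = tremor_rule()) {
  feats <- if (all(c("rest_cf", "postural_cf", "intensity_ratio") %in%
                   names(cohort))) cohort else subject_features(cohort)
  cls <- lapply(seq_len(nrow(feats)), function(i) {
    classify_subject(feats$rest_cf[i], feats$postural_cf[i],
                     feats$intensity_ratio[i], rule)
  })
  feats$predicted <- vapply(cls, `[[`, "", "predicted")
  feats$trace <- vapply(cls, `[[`, "", "trace")
  feats
}

#' @rdname classify_cohort
#' @param object a [tremor_rule].
#' @param newdata passed to [classify_cohort()] as `cohort`.
#' @param ... ignored.
#' @export
predict.tremor_rule <- function(object, newdata, ...) {
  classify_cohort(newdata, object)$predicted
}

#' Evaluate the rule classifier on a labelled cohort
#'
#' @param cohort labelled cohort with attached metrics (must carry `group`).
#' @param rule a [tremor_rule].
#' @return A `classifier_evaluation` list: `confusion` (true x predicted
#'   counts), `accuracy`, `recall` (per true group), `n`.
#' @export
evaluate_classifier <- function(cohort, rule = tremor_rule()) {
  cls <- classify_cohort(cohort, rule)
  if (!"group" %in% names(cls))
    stop_tremor("cohort must carry true 'group' labels")
  truth <- factor(cls$group, GROUPS)
  pred <- factor(cls$predicted, GROUPS)
  confusion <- table(truth = truth, predicted = pred)
  recall <- diag(confusion) / pmax(rowSums(confusion), 1L)
  structure(list(confusion = confusion,
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 recall = recall, n = sum(confusion)),
            class = "classifier_evaluation")
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("<classifier_evaluation> accuracy %.3f over %d subjects\n",
              x$accuracy, x$n))
  print(x$confusion)
  cat("per-group recall:",
      paste(sprintf("%s %.2f", names(x$recall), x$recall), collapse = ", "),
      "\n")
  invisible(x)
}
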