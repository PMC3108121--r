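metric_column <- function(cohort, condition, side, metric) {
  col <- paste(condition, side, metric, sep = "_")
  if (!col %in% names(cohort))
    stop_tremor("cohort has no column '", col, "'; run attach_metrics() first")
  cohort[[col]]
}

#' Group summaries (mean and SEM) of tremor metrics
#'
#' One row per metric x group x condition x side, in the mean +/- SEM layout
#' of the study tables. SEM is `sd/sqrt(n)`; for a single subject the SEM is
#' reported as 0 and flagged in the `degenerate` column.
#'
#' @param cohort cohort `data.frame` with attached metrics (see
#'   [attach_metrics()]).
#' @param metrics metric names to summarize.
#' @param groups groups to include (default: all present).
#' @return A `data.frame` with columns `metric`, `group`, `condition`,
#'   `side`, `n`, `mean`, `sem`, `degenerate`.
#' @export
summarize_groups <- function(cohort,
                             metrics = c("intensity", "center_freq",
                                         "dispersion", "harmonic_index"),
                             groups = NULL) {
  groups <- groups %||% unique(cohort$group)
  rows <- list()
  for (g in groups) {
    sub <- cohort[cohort$group == g, , drop = FALSE]
    if (nrow(sub) == 0L) stop_tremor("no subjects in group '", g, "'")
    for (m in metrics) for (cond in CONDITIONS) for (sd_ in SIDES) {
      x <- metric_column(sub, cond, sd_, m)
      x <- x[is.finite(x)]
      n <- length(x)
      if (n == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group = g, condition = cond, side = sd_, n = n,
        mean = mean(x), sem = if (n > 1L) sd(x) / sqrt(n) else 0,
        degenerate = n == 1L, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Rest-to-postural fold change with a paired t-test
#'
#' Ratio of the group's mean postural metric to its mean rest metric for one
#' side (the convention behind the published fold values), together with a
#' paired two-sided t-test across subjects.
#'
#' @param cohort cohort with attached metrics.
#' @param group group label.
#' @param side `"R"` or `"L"`.
#' @param metric metric name (default `"intensity"`).
#' @return A `fold_change` list: `group`, `side`, `rest_mean`,
#'   `postural_mean`, `ratio`, `t`, `df`, `p`, `n`.
#' @export
fold_change <- function(cohort, group, side = c("R", "L"),
                        metric = "intensity") {
  side <- match.arg(side)
  sub <- cohort[cohort$group == group, , drop = FALSE]
  if (nrow(sub) == 0L) stop_tremor("no subjects in group '", group, "'")
  rest <- metric_column(sub, "rest", side, metric)
  post <- metric_column(sub, "postural", side, metric)
  ok <- is.finite(rest) & is.finite(post)
  if (sum(ok) < 2L)
    stop_tremor("fewer than 2 complete rest/postural pairs in group '",
                group, "'")
  rest <- rest[ok]; post <- post[ok]
  if (all(abs(post - rest) < 1e-300)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(rest) - 1),
               p.value = 1)
  } else tt <- t.test(post, rest, paired = TRUE)
  structure(list(group = group, side = side, metric = metric,
                 rest_mean = mean(rest), postural_mean = mean(post),
                 ratio = mean(post) / mean(rest),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, n = length(rest)),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf(
    "<fold_change> %s %s %s: %.3f -> %.3f (%.2f-fold), paired t(%g) = %.2f, p = %.3g\n",
    x$group, x$side, x$metric, x$rest_mean, x$postural_mean, x$ratio,
    x$df, x$t, x$p))
  invisible(x)
}

#' Two-way ANOVA of a tremor metric (position x side)
#'
#' Fixed-effects two-factor ANOVA with interaction over the four
#' condition x side observations per subject, pooled across the subjects of
#' one group. Reports, per factor, the percent of total sum of squares
#' (eta-squared x 100), F and p; the percent column (including residual)
#' sums to 100.
#'
#' @inheritParams fold_change
#' @return An `anova_partition` data.frame with rows `position`, `side`,
#'   `interaction`, `residual` and columns `percent_variance`, `df`, `F`, `p`.
#' @export
two_way_anova <- function(cohort, group, metric = "intensity") {
  sub <- cohort[cohort$group == group, , drop = FALSE]
  if (nrow(sub) == 0L) stop_tremor("no subjects in group '", group, "'")
  long <- list()
  for (cond in CONDITIONS) for (sd_ in SIDES) {
    v <- metric_column(sub, cond, sd_, metric)
    long[[paste(cond, sd_)]] <- data.frame(
      subject_id = sub$subject_id, value = v, position = cond, side = sd_,
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, long)
  bad <- !is.finite(long$value)
  if (any(bad))
    stop_tremor("missing ", metric, " cells for subjects: ",
                paste(unique(long$subject_id[bad]), collapse = ", "))
  long$position <- factor(long$position, CONDITIONS)
  long$side <- factor(long$side, SIDES)
  fit <- aov(value ~ position * side, data = long)
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]
  out <- data.frame(
    factor = c("position", "side", "interaction", "residual"),
    percent_variance = 100 * ss / sum(ss),
    df = tab[["Df"]],
    F = c(tab[["F value"]][1:3], NA),
    p = c(tab[["Pr(>F)"]][1:3], NA),
    stringsAsFactors = FALSE)
  class(out) <- c("anova_partition", "data.frame")
  out
}

#' @export
print.anova_partition <- function(x, ...) {
  cat("<anova_partition> percent of total variance by factor\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Standard two-sided convention: the p-value sums the hypergeometric
#' probabilities (margins fixed) of every table whose point probability does
#' not exceed that of the observed table. The odds ratio is the sample
#' cross-product ratio; when any cell is zero, 0.5 is added to all cells for
#' the odds ratio only (flagged by `continuity`), never for the p-value.
#'
#' @param a,b,c,d non-negative integer counts, row-wise
#'   (`a` exposed-positive, `b` exposed-negative, `c` control-positive,
#'   `d` control-negative).
#' @return A `contingency_result` list: `table`, `odds_ratio`, `continuity`,
#'   `p`.
#' @examples
#' fisher_exact(7, 25, 0, 17)$p  # ~0.08
#' @export
fisher_exact <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9))
    stop_tremor("counts must be non-negative integers")
  counts <- round(counts)
  m <- matrix(counts, 2L, 2L, byrow = TRUE)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L))
    stop_tremor("a margin of the 2x2 table is zero; the test is undefined")
  p <- fisher.test(m, alternative = "two.sided")$p.value
  cont <- any(m == 0L)
  mm <- if (cont) m + 0.5 else m
  structure(list(table = m, odds_ratio = (mm[1, 1] * mm[2, 2]) /
                   (mm[1, 2] * mm[2, 1]),
                 continuity = cont, p = min(p, 1)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> OR = %.3f%s, two-sided Fisher p = %.4g\n",
              x$odds_ratio, if (x$continuity) " (0.5 continuity)" else "",
              x$p))
  invisible(x)
}

#' Ordinary least-squares regression of a metric on a covariate
#'
#' Simple linear regression with a two-sided t-test of the slope against
#' zero, for the slope-vs-age and slope-vs-exposure analyses.
#'
#' @param cohort cohort with attached metrics.
#' @param group group label.
#' @param metric metric name; either a bare metric (averaged over the
#'   requested `condition`/`side`) or a full column name already present.
#' @param predictor one of `"age"`, `"years_exposure"`,
#'   `"years_since_exposure"`, `"age_at_onset"` (or any numeric column).
#' @param condition,side cell selectors used when `metric` is bare.
#' @return A `regression_result` list: `slope`, `intercept`, `t`, `df`, `p`,
#'   `r_squared`, `n`, plus labels.
#' @export
regress_vs_covariate <- function(cohort, group, metric = "intensity",
                                 predictor = "age", condition = "postural",
                                 side = "R") {
  sub <- cohort[cohort$group == group, , drop = FALSE]
  if (nrow(sub) == 0L) stop_tremor("no subjects in group '", group, "'")
  if (!predictor %in% names(sub))
    stop_tremor("no predictor column '", predictor, "'")
  y <- if (metric %in% names(sub)) sub[[metric]]
       else metric_column(sub, condition, side, metric)
  x <- sub[[predictor]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 3L)
    stop_tremor("need >= 3 distinct predictor values (got ",
                length(unique(x)), ")")
  if (var(y) == 0)  # constant response: flat fit, nothing explained
    return(structure(list(group = group, metric = metric,
                          predictor = predictor, slope = 0,
                          intercept = mean(y), t = 0, df = length(x) - 2L,
                          p = 1, r_squared = 0, n = length(x)),
                     class = "regression_result"))
  fit <- lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  slope_p <- if (nrow(co) > 1L && is.finite(co[2, 4])) co[2, 4] else 1
  structure(list(group = group, metric = metric, predictor = predictor,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 t = if (nrow(co) > 1L) co[2, 3] else 0,
                 df = fit$df.residual, p = slope_p,
                 r_squared = sm$r.squared, n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> %s: %s ~ %s, slope %.4g/yr (p = %.3g), R^2 = %.3f, n = %d\n",
    x$group, x$metric, x$predictor, x$slope, x$p, x$r_squared, x$n))
  invisible(x)
}

#' Clinical-sign Fisher panel
#'
#' Runs [fisher_exact()] on every row of a per-sign 2x2 count table
#' (welders vs IPD), defaulting to the published counts from
#' [clinical_sign_counts()]. Per-sign denominators are honoured as given
#' (complete-case per row). No multiple-testing correction is applied,
#' matching the per-row reporting convention; a note is attached.
#'
#' @param counts `data.frame` with columns `sign`, `welders_pos`,
#'   `welders_n`, `ipd_pos`, `ipd_n`.
#' @return A `data.frame` with one row per sign: counts, `odds_ratio`,
#'   `continuity`, `p`.
#' @export
table2_report <- function(counts = clinical_sign_counts()) {
  need <- c("sign", "welders_pos", "welders_n", "ipd_pos", "ipd_n")
  if (!all(need %in% names(counts)))
    stop_tremor("counts must have columns: ", paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    fe <- fisher_exact(r$welders_pos, r$welders_n - r$welders_pos,
                       r$ipd_pos, r$ipd_n - r$ipd_pos)
    data.frame(sign = r$sign,
               welders = sprintf("%d/%d", r$welders_pos, r$welders_n),
               ipd = sprintf("%d/%d", r$ipd_pos, r$ipd_n),
               odds_ratio = fe$odds_ratio, continuity = fe$continuity,
               p = fe$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "note") <- "Unadjusted per-row Fisher tests (no multiplicity correction)."
  out
}
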