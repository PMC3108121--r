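wide_cohort <- function(n, group = "G", f = function(cond, side, i) rnorm(1)) {
  coh <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), group = group,
                    stringsAsFactors = FALSE)
  for (cond in c("rest", "postural")) for (side in c("R", "L"))
    coh[[paste(cond, side, "intensity", sep = "_")]] <-
      vapply(seq_len(n), function(i) f(cond, side, i), numeric(1))
  coh
}

test_that("group summaries reproduce hand-computed means and SEMs", {
  vals <- c(0.5, 0.8, 1.1)
  coh <- wide_cohort(3, f = function(cond, side, i) vals[i])
  sm <- summarize_groups(coh, metrics = "intensity", groups = "G")
  expect_equal(nrow(sm), 4)
  expect_equal(sm$mean, rep(0.8, 4))
  expect_equal(sm$sem, rep(sd(vals) / sqrt(3), 4))
  one <- summarize_groups(coh[1, ], metrics = "intensity", groups = "G")
  expect_equal(one$sem, rep(0, 4))
  expect_true(all(one$degenerate))
  expect_error(summarize_groups(coh, groups = "NOPE"), "NOPE")
})

test_that("fold change: identity case, scale invariance, and pairing", {
  coh <- wide_cohort(4, f = function(cond, side, i) i / 2)
  fc <- fold_change(coh, "G", "R")
  expect_equal(fc$ratio, 1)
  expect_equal(fc$p, 1)
  coh2 <- wide_cohort(6, f = function(cond, side, i)
    if (cond == "postural") 2 * i else i)
  fc2 <- fold_change(coh2, "G", "L")
  scaled <- coh2
  for (col in grep("intensity", names(scaled))) scaled[[col]] <- scaled[[col]] * 7.3
  fc2s <- fold_change(scaled, "G", "L")
  expect_equal(fc2$ratio, 2)
  expect_equal(fc2s$ratio, fc2$ratio, tolerance = 1e-12)
  expect_equal(fc2s$p, fc2$p, tolerance = 1e-12)
  expect_error(fold_change(coh2[1, ], "G", "R"), "fewer than 2")
})

test_that("two-way ANOVA matches a brute-force sum-of-squares decomposition", {
  set.seed(77)
  n <- 12
  eff <- c(rest = 0, postural = 0.9)
  seff <- c(R = 0.25, L = 0)
  coh <- wide_cohort(n, f = function(cond, side, i)
    1 + eff[[cond]] + seff[[side]] + rnorm(1, sd = 0.3))
  res <- two_way_anova(coh, "G")
  # brute-force decomposition on the long data
  long <- do.call(rbind, lapply(c("rest", "postural"), function(cond)
    do.call(rbind, lapply(c("R", "L"), function(side)
      data.frame(y = coh[[paste(cond, side, "intensity", sep = "_")]],
                 a = cond, b = side)))))
  g <- mean(long$y)
  ma <- tapply(long$y, long$a, mean)[long$a]
  mb <- tapply(long$y, long$b, mean)[long$b]
  mab <- tapply(long$y, paste(long$a, long$b), mean)[paste(long$a, long$b)]
  ss <- c(position = sum((ma - g)^2), side = sum((mb - g)^2),
          interaction = sum((mab - ma - mb + g)^2),
          residual = sum((long$y - mab)^2))
  expect_equal(res$percent_variance, unname(100 * ss / sum(ss)),
               tolerance = 1e-9)
  expect_equal(sum(res$percent_variance), 100, tolerance = 1e-9)
  expect_lt(res$p[res$factor == "position"], 0.01)
})

test_that("ANOVA percent variance collapses when a factor effect is removed", {
  set.seed(78)
  coh <- wide_cohort(40, f = function(cond, side, i) rnorm(1))
  res <- two_way_anova(coh, "G")
  expect_lt(res$percent_variance[res$factor == "side"], 5)
  expect_equal(sum(res$percent_variance), 100, tolerance = 1e-9)
  coh$rest_R_intensity[3] <- NA
  expect_error(two_way_anova(coh, "G"), "S003")
})

test_that("fisher_exact matches the enumeration oracle on assorted tables", {
  set.seed(101)
  tabs <- rbind(
    c(7, 25, 0, 17), c(7, 24, 1, 16), c(19, 12, 9, 7), c(5, 27, 3, 14),
    c(27, 4, 3, 13), c(1, 1, 1, 1), c(10, 0, 0, 10), c(0, 10, 10, 0),
    matrix(sample(0:15, 4 * 40, replace = TRUE), ncol = 4))
  keep <- rowSums(tabs[, 1:2]) > 0 & rowSums(tabs[, 3:4]) > 0 &
    (tabs[, 1] + tabs[, 3]) > 0 & (tabs[, 2] + tabs[, 4]) > 0
  tabs <- tabs[keep, ]
  for (i in seq_len(nrow(tabs))) {
    fe <- fisher_exact(tabs[i, 1], tabs[i, 2], tabs[i, 3], tabs[i, 4])
    expect_equal(fe$p, oracle_fisher_p(tabs[i, 1], tabs[i, 2], tabs[i, 3],
                                       tabs[i, 4]), tolerance = 1e-10)
    expect_gt(fe$p, 0)
    expect_lte(fe$p, 1)
  }
})

test_that("fisher_exact flags continuity-corrected odds ratios and rejects bad input", {
  fe <- fisher_exact(7, 25, 0, 17)
  expect_true(fe$continuity)
  expect_equal(fe$odds_ratio, (7.5 * 17.5) / (25.5 * 0.5))
  fe2 <- fisher_exact(19, 12, 9, 7)
  expect_false(fe2$continuity)
  expect_equal(fe2$odds_ratio, (19 * 7) / (12 * 9))
  expect_error(fisher_exact(0, 0, 3, 4), "margin")
  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact(1.5, 2, 3, 4), "integer")
})

test_that("OLS regression matches the closed-form normal equations", {
  set.seed(55)
  coh <- wide_cohort(15, f = function(cond, side, i) NA)
  coh$age <- runif(15, 40, 75)
  coh$postural_R_intensity <- 0.4 + 0.01 * coh$age + rnorm(15, sd = 0.1)
  rr <- regress_vs_covariate(coh, "G", "intensity", "age")
  x <- coh$age; y <- coh$postural_R_intensity
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(rr$slope, slope, tolerance = 1e-9)
  expect_equal(rr$intercept, intercept, tolerance = 1e-9)
  r2 <- 1 - sum((y - intercept - slope * x)^2) / sum((y - mean(y))^2)
  expect_equal(rr$r_squared, r2, tolerance = 1e-9)
})

test_that("regression handles exact lines, constant responses and bad predictors", {
  coh <- wide_cohort(10, f = function(cond, side, i) NA)
  coh$age <- 1:10
  coh$postural_R_intensity <- 2 * coh$age + 1
  # base lm warns on a zero-residual fit; the estimates are still exact
  rr <- suppressWarnings(regress_vs_covariate(coh, "G", "intensity", "age"))
  expect_equal(rr$slope, 2, tolerance = 1e-12)
  expect_equal(rr$intercept, 1, tolerance = 1e-12)
  expect_equal(rr$r_squared, 1, tolerance = 1e-12)
  coh$postural_R_intensity <- 0.7
  rc <- regress_vs_covariate(coh, "G", "intensity", "age")
  expect_equal(rc$slope, 0, tolerance = 1e-12)
  expect_equal(rc$r_squared, 0)
  coh$age <- 50
  expect_error(regress_vs_covariate(coh, "G", "intensity", "age"),
               "distinct predictor")
})

test_that("the clinical-sign panel covers every published row and handles symmetry", {
  panel <- table2_report()
  expect_equal(nrow(panel), 14)
  expect_true(all(panel$p > 0 & panel$p <= 1))
  sym <- table2_report(data.frame(sign = "even", welders_pos = 6,
                                  welders_n = 18, ipd_pos = 3, ipd_n = 9))
  expect_equal(sym$p, 1)
})
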