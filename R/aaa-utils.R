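#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm runif rbinom aov lm anova coef fisher.test
#'   t.test var sd qnorm pt setNames complete.cases
#' @importFrom utils read.table write.table packageVersion head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the Mersenne-Twister generator with `seed`, runs `expr`, and restores
#' the caller's RNG state afterwards, so seeded simulations never disturb the
#' global random stream. With `seed = NULL` the expression runs on the current
#' stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

stop_tremor <- function(..., class = "tremorspec_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_tremor("'", name, "' must be a single finite number")
  as.numeric(x)
}

#' Draw from a normal distribution truncated to an interval by resampling
#' @noRd
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf, max_iter = 1000L) {
  x <- rnorm(n, mean, sd)
  for (i in seq_len(max_iter)) {
    bad <- x < lower | x > upper
    if (!any(bad)) return(x)
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

#' Lognormal draws matched to a target mean and standard deviation
#'
#' Moment-matched on the natural scale: E[X] = mean, SD[X] = sd exactly.
#' Used for strictly positive quantities whose printed SD exceeds the mean,
#' where a zero-truncated normal would inflate the population mean.
#' `z` optionally supplies the standard-normal innovations (for building
#' correlated within-subject draws).
#' @noRd
rlnorm_matched <- function(n, mean, sd, z = NULL) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(rep(mean, n))
  sig2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sig2 / 2
  if (is.null(z)) z <- rnorm(n)
  exp(mu + sqrt(sig2) * z)
}

GROUPS <- c("WELDER", "IPD", "ET")
CONDITIONS <- c("rest", "postural")
SIDES <- c("R", "L")
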