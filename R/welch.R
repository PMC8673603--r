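#' Welch's two-sample t-test with Cohen's d
#'
#' Unequal-variance t-test with the Welch-Satterthwaite degrees of freedom,
#' computable either from raw vectors or from `(mean, sd, n)` summaries —
#' both routes give identical results, which lets printed summary tables be
#' re-analysed directly. Cohen's d uses the pooled standard deviation
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))`; its 95% confidence
#' interval uses the large-sample normal approximation
#' `se_d = sqrt((n1+n2)/(n1 n2) + d^2 / (2 (n1+n2-2)))`.
#'
#' @param x,y numeric vectors, or summaries as `c(mean=, sd=, n=)` /
#'   `list(mean=, sd=, n=)`.
#' @param conf_level confidence level of the effect-size interval.
#' @return object of class `welch_result` with fields `mean_x`, `sd_x`,
#'   `n_x`, `mean_y`, `sd_y`, `n_y`, `t`, `df`, `p_value`, `cohen_d`,
#'   `d_ci` (length-2), `conf_level`.
#' @export
welch_t_test <- function(x, y, conf_level = 0.95) {
  sx <- as_group_summary(x)
  sy <- as_group_summary(y)
  if (sx$n < 2 || sy$n < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sx$sd <= 0 || sy$sd <= 0)
    stop("group standard deviations must be positive", call. = FALSE)
  vx <- sx$sd^2 / sx$n
  vy <- sy$sd^2 / sy$n
  se <- sqrt(vx + vy)
  t_stat <- (sx$mean - sy$mean) / se
  df <- (vx + vy)^2 / (vx^2 / (sx$n - 1) + vy^2 / (sy$n - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  sp <- sqrt(((sx$n - 1) * sx$sd^2 + (sy$n - 1) * sy$sd^2) / (sx$n + sy$n - 2))
  d <- (sx$mean - sy$mean) / sp
  se_d <- sqrt((sx$n + sy$n) / (sx$n * sy$n) + d^2 / (2 * (sx$n + sy$n - 2)))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(mean_x = sx$mean, sd_x = sx$sd, n_x = sx$n,
                 mean_y = sy$mean, sd_y = sy$sd, n_y = sy$n,
                 t = t_stat, df = df, p_value = p,
                 cohen_d = d, d_ci = c(d - zc * se_d, d + zc * se_d),
                 conf_level = conf_level),
            class = "welch_result")
}

as_group_summary <- function(x) {
  if (is.numeric(x) && is.null(names(x)) && length(x) > 3) {
    return(list(mean = mean(x), sd = stats::sd(x), n = length(x)))
  }
  if (is.list(x) || (!is.null(names(x)) && all(c("mean", "sd", "n") %in% names(x)))) {
    x <- as.list(x)
    return(list(mean = as.numeric(x$mean), sd = as.numeric(x$sd),
                n = as.numeric(x$n)))
  }
  if (is.numeric(x)) return(list(mean = mean(x), sd = stats::sd(x), n = length(x)))
  stop("supply a numeric vector or c(mean=, sd=, n=)", call. = FALSE)
}

#' @export
print.welch_result <- function(x, ...) {
  cat("Welch two-sample t-test\n")
  cat(sprintf("  group 1: mean %.3f, sd %.3f, n %d; group 2: mean %.3f, sd %.3f, n %d\n",
              x$mean_x, x$sd_x, as.integer(x$n_x),
              x$mean_y, x$sd_y, as.integer(x$n_y)))
  cat(sprintf("  t = %.3f, df = %.2f, p = %.4g\n", x$t, x$df, x$p_value))
  cat(sprintf("  Cohen's d = %.3f, %d%% CI [%.3f, %.3f]\n",
              x$cohen_d, round(100 * x$conf_level), x$d_ci[1], x$d_ci[2]))
  invisible(x)
}

#' Advisory normality and variance-homogeneity checks
#'
#' Shapiro-Wilk W and p per group (via [stats::shapiro.test()]) and a
#' Brown-Forsythe Levene test (absolute deviations from the group medians,
#' one-way F). Advisory only: results never gate the t-test.
#'
#' @param x,y numeric vectors (n >= 3 each).
#' @return list with `shapiro_x`, `shapiro_y` (each `W`, `p`), and `levene`
#'   (`F`, `df1`, `df2`, `p`).
#' @export
normality_and_variance_checks <- function(x, y) {
  stopifnot(length(x) >= 3L, length(y) >= 3L)
  sx <- stats::shapiro.test(x)
  sy <- stats::shapiro.test(y)
  zx <- abs(x - stats::median(x))
  zy <- abs(y - stats::median(y))
  z <- c(zx, zy)
  g <- factor(rep(1:2, c(length(x), length(y))))
  n <- length(z)
  gm <- tapply(z, g, mean)
  ssb <- sum(tabulate(g) * (gm - mean(z))^2)
  ssw <- sum((z - gm[as.integer(g)])^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  list(shapiro_x = list(W = unname(sx$statistic), p = sx$p.value),
       shapiro_y = list(W = unname(sy$statistic), p = sy$p.value),
       levene = list(F = f, df1 = 1L, df2 = n - 2L,
                     p = stats::pf(f, 1, n - 2, lower.tail = FALSE)))
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise significance level.
#' @param k number of tests.
#' @return `alpha / k`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, k = 1L) {
  stopifnot(k >= 1, alpha > 0, alpha < 1)
  alpha / k
}
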