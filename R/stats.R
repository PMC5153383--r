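#' Statistical test result container
#'
#' @param method method label.
#' @param statistic test statistic value.
#' @param p_value p-value in `[0, 1]`.
#' @param n sample size.
#' @param ... extra named fields (estimates, degrees of freedom, ...).
#' @return A `stat_result` with a `significant` flag at alpha = 0.05.
#' @export
stat_result <- function(method, statistic, p_value, n, ...) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value must lie in [0, 1]")
  structure(c(list(method = method, statistic = unname(statistic),
                   p_value = unname(p_value), n = n,
                   significant = !is.na(p_value) && p_value < 0.05),
              list(...)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic %.4g, p = %.4g (n = %d)%s\n",
              x$method, x$statistic, x$p_value, x$n,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Normality screening (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' KS distance against a normal law with sample-estimated mean and SD.
#' With estimated parameters the plain KS p-value is anticonservative, so
#' the Lilliefors correction is used by default; `correct = FALSE` gives the
#' uncorrected KS p for comparison.
#'
#' @param x numeric sample (n >= 4, non-zero variance).
#' @param correct apply the Lilliefors correction (default `TRUE`).
#' @return A [stat_result()].
#' @export
ks_normality <- function(x, correct = TRUE) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0) stop("zero variance sample")
  if (correct) {
    lt <- nortest::lillie.test(x)
    stat_result("Lilliefors (KS) normality", lt$statistic, lt$p.value,
                length(x))
  } else {
    kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x),
                                          stats::sd(x)))
    stat_result("Kolmogorov-Smirnov normality (estimated parameters)",
                kt$statistic, kt$p.value, length(x))
  }
}

#' Paired-sample t test
#'
#' Two-sided t test on the paired differences, df = n - 1.
#'
#' @param pre,post paired numeric vectors of equal length (>= 2).
#' @return A [stat_result()] with fields `df` and `mean_difference`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must be paired")
  if (length(pre) < 2) stop("need at least 2 pairs")
  d <- post - pre
  if (stats::sd(d) == 0) stop("zero-variance differences")
  tt <- stats::t.test(post, pre, paired = TRUE)
  stat_result("paired t", tt$statistic, tt$p.value, length(pre),
              df = unname(tt$parameter), mean_difference = mean(d))
}

#' Spearman rank correlation (tie-corrected)
#'
#' Mid-ranks for ties, then the product-moment correlation of ranks.  The
#' p-value uses the t approximation `t = rho sqrt((n-2)/(1-rho^2))` with
#' n - 2 df (two-sided); for n <= 10 an exact permutation p-value is
#' available.
#'
#' @param x,y numeric vectors of equal length (>= 4); neither may be
#'   entirely tied.
#' @param exact use exact permutation p (only for n <= 10).
#' @return A [stat_result()] with field `rho`.
#' @export
spearman <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("all-tied vector: rank correlation undefined")
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 10) stop("exact permutation p only supported for n <= 10")
    p <- cpp_spearman_perm_p(rx, ry)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  stat_result(if (exact) "Spearman rho (exact permutation)"
              else "Spearman rho (t approximation)",
              rho, p, n, rho = rho)
}

#' Simple linear regression against a constant model
#'
#' Least-squares line `y ~ x`; the F test compares the fit to the
#' constant (intercept-only) model: `F = (n-2) R^2 / (1-R^2)` on
#' `(1, n-2)` df.
#'
#' @param x,y numeric vectors, length >= 3; `x` must not be constant.
#' @return A [stat_result()] with fields `slope`, `intercept`,
#'   `r_squared`, `f_statistic`.
#' @export
regress_vs_constant <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("constant x: slope undefined")
  fit <- stats::lm(y ~ x)
  r2 <- suppressWarnings(summary(fit))$r.squared
  fstat <- if (r2 >= 1) Inf else (n - 2) * r2 / (1 - r2)
  p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  stat_result("linear regression vs constant model (F test)", fstat, p, n,
              slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = r2, f_statistic = fstat)
}

#' Correlation strength gate for follow-up regression
#'
#' Regression against tumor volume is pursued only when the rank
#' correlation is moderate or better: `|rho| > 0.5` (strict).
#'
#' @param rho Spearman correlation coefficient.
#' @return Logical.
#' @export
correlation_gate <- function(rho) abs(rho) > 0.5

#' Full statistical battery for a cohort table
#'
#' Runs the cohort analysis over a [cohort_table()]: normality screening of
#' each metric delta, paired t tests pre vs post for every dose metric, and
#' Spearman correlations of each metric delta against pre-ablation tumor
#' volume with follow-up regression where `|rho| > 0.5`.
#'
#' @param tab a [cohort_table()] with metric columns.
#' @return A named list of [stat_result()]s (and regression results).
#' @export
cohort_stats <- function(tab) {
  out <- list()
  vol <- tab$pre_volume_cm3
  for (m in c("d_avg", "d50", "d70", "d90", "v100")) {
    pre <- tab[[paste0("pre_", m)]]
    post <- tab[[paste0("post_", m)]]
    if (is.null(pre) || is.null(post)) next
    delta <- post - pre
    if (stats::sd(delta) > 0) {
      out[[paste0("normality_delta_", m)]] <- ks_normality(delta)
      out[[paste0("paired_t_", m)]] <- paired_t(pre, post)
      sp <- spearman(vol, delta)
      out[[paste0("spearman_volume_delta_", m)]] <- sp
      if (correlation_gate(sp$rho))
        out[[paste0("regression_volume_delta_", m)]] <-
          regress_vs_constant(vol, delta)
    }
  }
  out
}

#' Export a statistics report to JSON
#'
#' @param results a named list of [stat_result()]s (e.g. from
#'   [cohort_stats()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_stats <- function(results, path) {
  jsonlite::write_json(lapply(results, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
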