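test_that("paired t matches the closed form and its symmetries", {
  pre <- c(10, 20, 30)
  post <- pre + c(1, 2, 3)
  r <- paired_t(pre, post)
  d <- post - pre
  t_oracle <- mean(d) / (sd(d) / sqrt(3))
  expect_lt(abs(r$statistic - t_oracle), 1e-10)
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(r$df, 2)
  p_oracle <- 2 * pt(-abs(t_oracle), df = 2)
  expect_lt(abs(r$p_value - p_oracle), 1e-10)

  # swapping pre/post negates t, keeps p; constant shifts change nothing
  r2 <- paired_t(post, pre)
  expect_equal(r2$statistic, -r$statistic, tolerance = 1e-12)
  expect_equal(r2$p_value, r$p_value, tolerance = 1e-12)
  r3 <- paired_t(pre + 100, post + 100)
  expect_equal(r3$statistic, r$statistic, tolerance = 1e-12)
  expect_error(paired_t(pre, pre + 1), "zero-variance")
})

test_that("Spearman uses mid-ranks and the t approximation", {
  x <- 1:10
  expect_equal(spearman(x, 2 * x + 3)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)

  # tied data vs a brute-force mid-rank oracle
  set.seed(43)
  for (i in 1:5) {
    a <- sample(1:5, 12, replace = TRUE)
    b <- sample(1:5, 12, replace = TRUE)
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    midrank <- function(v) vapply(v, function(vi)
      mean(which(sort(v) == vi)), numeric(1))
    ra <- midrank(a); rb <- midrank(b)
    rho_oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
    r <- spearman(a, b)
    expect_lt(abs(r$rho - rho_oracle), 1e-12)
    n <- 12
    t_or <- rho_oracle * sqrt((n - 2) / (1 - rho_oracle^2))
    expect_lt(abs(r$p_value - 2 * pt(-abs(t_or), n - 2)), 1e-12)
  }
  expect_error(spearman(rep(1, 5), 1:5), "all-tied")

  # invariance under strictly monotone transforms
  set.seed(47)
  x <- rnorm(20); y <- rnorm(20)
  r0 <- spearman(x, y)$rho
  expect_equal(spearman(exp(x), y)$rho, r0, tolerance = 1e-12)
  expect_equal(spearman(x, y^3 + 5 * y)$rho, r0, tolerance = 1e-12)
})

test_that("exact permutation p matches full enumeration on a small sample", {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  set.seed(53)
  x <- rnorm(5); y <- rnorm(5)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- abs(cor(rx, ry))
  all_p <- perms(ry)
  count <- sum(vapply(all_p, function(p)
    abs(cor(rx, p)) >= rho_obs - 1e-12, logical(1)))
  p_oracle <- count / length(all_p)
  expect_equal(spearman(x, y, exact = TRUE)$p_value, p_oracle,
               tolerance = 1e-12)
})

test_that("KS normality screening behaves under null and alternative", {
  # statistic equals the manual supremum for a hand-sorted 5-point sample
  x5 <- c(-1.2, -0.4, 0.1, 0.8, 2.0)
  r5 <- ks_normality(x5, correct = FALSE)
  z <- pnorm(sort(x5), mean(x5), sd(x5))
  d_oracle <- max(pmax(abs((1:5) / 5 - z), abs(z - (0:4) / 5)))
  expect_lt(abs(r5$statistic - d_oracle), 1e-12)

  # standard-normal draws: non-significant in the vast majority of seeds
  # (the test has ~5% size under the null, so demand >= 88% over 200 seeds,
  # three binomial standard errors below the nominal 95%)
  sig <- vapply(1:200, function(s) {
    set.seed(s)
    ks_normality(rnorm(500))$significant
  }, logical(1))
  expect_gte(mean(!sig), 0.88)

  # heavily bimodal sample: significant
  set.seed(59)
  bim <- c(rnorm(100, -5, 0.5), rnorm(100, 5, 0.5))
  expect_true(ks_normality(bim)$significant)
  expect_error(ks_normality(rep(3, 10)), "zero variance")
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
})

test_that("regression vs constant model matches the normal equations", {
  # exactly collinear points
  r <- regress_vs_constant(1:5, 2 * (1:5) - 1)
  expect_equal(r$r_squared, 1)
  expect_equal(r$p_value, 0)

  # 3-point hand example vs normal-equations oracle
  x <- c(0, 1, 3); y <- c(1, 3, 4)
  r3 <- regress_vs_constant(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_lt(abs(r3$intercept - beta[1]), 1e-10)
  expect_lt(abs(r3$slope - beta[2]), 1e-10)
  fit <- X %*% beta
  r2_oracle <- 1 - sum((y - fit)^2) / sum((y - mean(y))^2)
  expect_lt(abs(r3$r_squared - r2_oracle), 1e-10)
  f_oracle <- (3 - 2) * r2_oracle / (1 - r2_oracle)
  expect_lt(abs(r3$f_statistic - f_oracle), 1e-10)
  expect_lt(abs(r3$p_value - pf(f_oracle, 1, 1, lower.tail = FALSE)), 1e-10)

  # y independent of x: slope near zero, rarely significant
  sig <- vapply(1:50, function(s) {
    set.seed(s)
    regress_vs_constant(rnorm(200), rnorm(200))$significant
  }, logical(1))
  expect_gte(mean(!sig), 0.9)
  expect_error(regress_vs_constant(rep(2, 5), rnorm(5)), "constant x")
})

test_that("correlation gate is strict at 0.5", {
  expect_true(correlation_gate(-0.64))
  expect_false(correlation_gate(-0.34))
  expect_false(correlation_gate(0.5))
  expect_true(correlation_gate(0.51))
})

test_that("paired-t p-values are uniform under a simulated null", {
  set.seed(61)
  ps <- vapply(1:1000, function(i) {
    a <- rnorm(10)
    b <- a + rnorm(10)
    paired_t(a, b)$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the cohort battery runs end to end on a synthetic table", {
  set.seed(67)
  n <- 15
  tab <- data.frame(pre_volume_cm3 = runif(n, 40, 380))
  tab$post_volume_cm3 <- tab$pre_volume_cm3 * runif(n, 0.7, 0.95)
  tab$n_sites <- sample(1:4, n, TRUE)
  for (m in c("d_avg", "d50", "d70", "d90", "v100")) {
    tab[[paste0("pre_", m)]] <- runif(n, 40, 120)
    tab[[paste0("post_", m)]] <-
      tab[[paste0("pre_", m)]] + 12 - 0.04 * tab$pre_volume_cm3 + rnorm(n)
  }
  res <- cohort_stats(tab)
  expect_true(all(c("paired_t_d_avg", "spearman_volume_delta_d_avg") %in%
                    names(res)))
  for (r in res) expect_true(r$p_value >= 0 && r$p_value <= 1)
  # regression only follows moderate-or-better correlations
  for (m in c("d_avg", "d50", "d70", "d90", "v100")) {
    sp <- res[[paste0("spearman_volume_delta_", m)]]
    has_reg <- !is.null(res[[paste0("regression_volume_delta_", m)]])
    expect_identical(has_reg, correlation_gate(sp$rho))
  }
})

test_that("statistics reports export as JSON records", {
  res <- list(paired = paired_t(c(1, 2, 3, 4), c(2, 2.5, 4, 5.5)))
  p <- tempfile(fileext = ".json")
  export_stats(res, p)
  back <- jsonlite::fromJSON(p)
  expect_equal(back$paired$statistic, res$paired$statistic,
               tolerance = 1e-12)
  expect_equal(back$paired$n, 4)
})
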