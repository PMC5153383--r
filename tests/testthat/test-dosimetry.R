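test_that("local deposition dose is concentration times the dose constant", {
  # 1 GBq spread over exactly 1 kg of voxels -> 49.67 Gy everywhere
  h <- (1e6 / 1060 / 1000)^(1 / 3) * 10 # 1000 voxels weigh 1 kg at 1060 kg/m^3
  g <- voxel_grid(c(10, 10, 10), h)
  act <- scalar_map(array(1e9 / 1000, c(10, 10, 10)), g, "Bq")
  d <- ldm_dose(act)
  expect_equal(unname(range(d$values)), c(49.67, 49.67), tolerance = 1e-12)

  # zero activity -> zero dose; doubling activity doubles dose
  set.seed(3)
  act2 <- scalar_map(array(runif(1000) * 1e6, c(10, 10, 10)), g, "Bq")
  expect_true(all(ldm_dose(scalar_map(array(0, c(10, 10, 10)), g))$values == 0))
  d1 <- ldm_dose(act2)
  d2 <- ldm_dose(scalar_map(2 * act2$values, g))
  expect_equal(d2$values, 2 * d1$values)
  expect_error(ldm_dose(scalar_map(array(-1, c(2, 2, 2)), cube_grid(2))),
               "non-negative")
})

test_that("energy bookkeeping: total dose-mass product equals constant times activity", {
  set.seed(9)
  g <- cube_grid(12, 2.7)
  act <- scalar_map(array(rexp(12^3) * 1e5, g$shape), g, "Bq")
  cst <- ldm_constants()
  d <- ldm_dose(act, cst)
  vox_kg <- voxel_volume(g) * 1e-9 * cst$tissue_density
  lhs <- sum(d$values * vox_kg)
  rhs <- cst$gy_per_gbq_per_kg * sum(act$values) * 1e-9
  expect_lt(abs(lhs - rhs) / rhs, 1e-9)
})

test_that("dose metrics follow the descending-rank definition", {
  g2 <- voxel_grid(c(2, 1, 1), 2)
  m <- dose_metrics(scalar_map(c(50, 150), g2, "Gy"),
                    label_mask(c(TRUE, TRUE), g2))
  expect_equal(m$d_avg, 100)
  expect_equal(m$d50, 150)
  expect_equal(m$d70, 50)
  expect_equal(m$d90, 50)
  expect_equal(m$v100, 50)

  # uniform tumor
  gu <- cube_grid(5)
  mu <- dose_metrics(scalar_map(array(120, gu$shape), gu, "Gy"),
                     label_mask(array(TRUE, gu$shape), gu))
  expect_equal(unlist(mu[c("d_avg", "d_max", "d50", "d70", "d90")]),
               c(d_avg = 120, d_max = 120, d50 = 120, d70 = 120, d90 = 120))
  expect_equal(mu$v100, 100)

  # random 1000-voxel field vs the independent sort-and-index oracle
  set.seed(13)
  g <- cube_grid(10)
  for (i in 1:5) {
    doses <- array(rlnorm(1000, 4, 0.8), g$shape)
    sel <- array(runif(1000) > 0.3, g$shape)
    sel[1] <- TRUE
    m <- dose_metrics(scalar_map(doses, g, "Gy"), label_mask(sel, g))
    o <- metrics_oracle(doses[sel])
    for (f in names(o)) expect_equal(m[[f]], o[[f]])
  }
  expect_error(dose_metrics(scalar_map(array(1, g$shape), g),
                            label_mask(array(FALSE, g$shape), g)),
               "no voxels in mask")
})

test_that("metric ordering invariants hold on random fields", {
  set.seed(17)
  g <- cube_grid(8)
  for (i in 1:10) {
    doses <- array(rlnorm(8^3, 4.3, 1), g$shape)
    m <- dose_metrics(scalar_map(doses, g, "Gy"),
                      label_mask(array(TRUE, g$shape), g))
    expect_true(m$d90 <= m$d70 && m$d70 <= m$d50 && m$d50 <= m$d_max)
    expect_true(m$d_avg <= m$d_max)
    expect_true(m$v100 >= 0 && m$v100 <= 100)
  }
})

test_that("removing only lowest-dose voxels never degrades any metric", {
  set.seed(19)
  g <- cube_grid(8)
  for (i in 1:10) {
    doses <- array(rlnorm(8^3, 4.5, 0.9), g$shape)
    dm <- scalar_map(doses, g, "Gy")
    full <- label_mask(array(TRUE, g$shape), g)
    cutoff <- quantile(doses, runif(1, 0.05, 0.5))
    keep <- doses > cutoff
    if (sum(keep) < 10) next
    pre <- dose_metrics(dm, full)
    post <- dose_metrics(dm, label_mask(keep, g))
    for (f in c("d_avg", "d50", "d70", "d90", "v100"))
      expect_gte(post[[f]], pre[[f]])
    expect_equal(post$d_max, pre$d_max)
  }
})

test_that("DVH matches direct voxel counting and mixes additively", {
  g <- cube_grid(6)
  # uniform field: step from 100 to 0 at the field value
  u <- dvh(scalar_map(array(42, g$shape), g, "Gy"),
           label_mask(array(TRUE, g$shape), g), bin_width = 1)
  expect_equal(u$volume_pct[1], 100)
  expect_true(all(u$volume_pct[u$dose_gy <= 42] == 100))
  expect_true(all(u$volume_pct[u$dose_gy > 42] == 0))
  expect_true(all(diff(u$volume_pct) <= 0))

  set.seed(23)
  doses <- array(rlnorm(6^3, 4, 0.7), g$shape)
  dm <- scalar_map(doses, g, "Gy")
  full <- label_mask(array(TRUE, g$shape), g)
  v <- dvh(dm, full, bin_width = 1)
  for (j in seq(1, nrow(v), by = 7))
    expect_equal(v$volume_pct[j], 100 * mean(doses >= v$dose_gy[j]))

  # volume-weighted mixing of two disjoint masks
  a <- array(FALSE, g$shape); a[1:3, , ] <- TRUE
  b <- array(FALSE, g$shape); b[4:6, , ] <- TRUE
  va <- dvh(dm, label_mask(a, g), 5)
  vb <- dvh(dm, label_mask(b, g), 5)
  vab <- dvh(dm, label_mask(a | b, g), 5)
  nmin <- min(nrow(va), nrow(vb), nrow(vab))
  mix <- (va$volume_pct[1:nmin] * sum(a) + vb$volume_pct[1:nmin] * sum(b)) /
    sum(a | b)
  expect_equal(vab$volume_pct[1:nmin], mix)

  # DVH-read V100 agrees with the metric within one bin
  m <- dose_metrics(dm, full)
  at100 <- v$volume_pct[findInterval(100, v$dose_gy)]
  expect_lt(abs(at100 - m$v100), 100 * 1 / length(doses) + 1e-9 +
              100 * mean(doses == 100))
})

test_that("eligibility thresholds are strict and device-specific", {
  mk <- function(d70) structure(list(d70 = d70), class = "dose_metrics")
  expect_true(eligibility(mk(99.9), "resin"))
  expect_false(eligibility(mk(100), "resin"))
  expect_true(eligibility(mk(120), "glass"))
  expect_false(eligibility(mk(150), "glass"))
  expect_error(eligibility(mk(50), "steel"), "unknown device")
})

test_that("isodose masks are nested and match brute-force counts", {
  set.seed(29)
  g <- cube_grid(10)
  doses <- array(rlnorm(1000, 4.5, 0.8), g$shape)
  dm <- scalar_map(doses, g, "Gy")
  expect_true(all(isodose_mask(dm, 0)$membership))
  m100 <- isodose_mask(dm, 100)
  m120 <- isodose_mask(dm, 120)
  m150 <- isodose_mask(dm, 150)
  expect_true(all(m150$membership <= m120$membership))
  expect_true(all(m120$membership <= m100$membership))
  for (lev in c(50, 100, 200))
    expect_equal(sum(isodose_mask(dm, lev)$membership), sum(doses >= lev))
})

test_that("implant decay timing follows the exponential closed form", {
  expect_equal(dose_fraction_delivered(0), 0)
  expect_equal(dose_fraction_delivered(64.05), 0.5)
  # two weeks: ~97.4%, within 0.2 percentage points of the quoted 97.5%
  f <- 100 * dose_fraction_delivered(336)
  expect_lt(abs(f - 97.5), 0.2)
  expect_error(dose_fraction_delivered(-1), ">= 0")
})
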