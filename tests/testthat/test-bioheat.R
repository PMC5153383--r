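test_that("tissue presets carry the published central values", {
  nl <- tissue_properties("normal_liver")
  expect_equal(c(nl$sigma, nl$w_b_nc, nl$rho), c(0.260, 0.0180, 1060))
  ci <- tissue_properties("cirrhotic_liver")
  expect_equal(c(ci$sigma, ci$w_b_nc, ci$rho), c(0.260, 0.0115, 1040))
  hc <- tissue_properties("hcc")
  expect_equal(c(hc$sigma, hc$w_b_nc), c(0.504, 0.0155))
  expect_equal(nl$c_b, 3617)
  expect_error(tissue_properties(sigma = -1), "positive")
})

test_that("the unit-drive potential honours its boundary conditions", {
  el <- electrode_spec(c(0, 0, 10), c(0, 0, 1), active_length = 20)
  g <- cube_grid(31, 2, centered = TRUE)
  v <- solve_potential(g, 0.26, el)
  tip <- attr(v, "tip_mask")
  bnd <- ablate90:::boundary_mask_array(g$shape)
  expect_true(all(v$values[tip] == 1))
  expect_true(all(v$values[bnd] == 0))
  # discrete maximum principle
  expect_true(all(v$values >= 0 & v$values <= 1))
  # with uniform conductivity, sigma cancels out of the Laplace problem
  v2 <- solve_potential(g, 0.52, el)
  expect_lt(max(abs(v2$values - v$values)), 1e-6)
  # tip outside the domain is rejected
  expect_error(solve_potential(g, 0.26,
                               electrode_spec(c(0, 0, 100), c(0, 0, 1))),
               "outside")
})

test_that("Joule power scales quadratically and balances boundary flux", {
  # resolved cubic electrode so every boundary face lies exactly on the
  # voxel lattice
  g <- cube_grid(40, 1.5, centered = TRUE)
  shp <- g$shape
  sig <- 0.4
  tip <- array(FALSE, shp)
  tip[18:23, 18:23, 14:27] <- TRUE
  bnd <- ablate90:::boundary_mask_array(shp)
  fv <- array(0, shp); fv[tip] <- 1
  v <- solve_laplace_dirichlet(g, sig, tip | bnd, fv)

  q0 <- power_density(v, sig, applied_volts = 0)
  expect_true(all(q0$values == 0))
  q1 <- power_density(v, sig, applied_volts = 20)
  q2 <- power_density(v, sig, applied_volts = 40)
  expect_equal(sum(q2$values), 4 * sum(q1$values), tolerance = 1e-12)

  # divergence-theorem oracle: total dissipation equals the current drawn
  # from the electrode surface times the applied voltage
  vox_m3 <- prod(g$spacing * 1e-3)
  total_w <- sum(q1$values) * vox_m3
  h <- g$spacing * 1e-3
  flux <- 0
  V <- v$values
  for (a in 1:3) {
    idx_lo <- lapply(shp, seq_len); idx_lo[[a]] <- 1:(shp[a] - 1)
    idx_hi <- lapply(shp, seq_len); idx_hi[[a]] <- 2:shp[a]
    vlo <- do.call(`[`, c(list(V), idx_lo))
    vhi <- do.call(`[`, c(list(V), idx_hi))
    tlo <- do.call(`[`, c(list(tip), idx_lo))
    thi <- do.call(`[`, c(list(tip), idx_hi))
    cross <- xor(tlo, thi) # faces between tip and tissue
    flux <- flux + sum(sig * abs(vlo - vhi)[cross] / h[a]) * vox_m3 / h[a]
  }
  expect_lt(abs(total_w - flux * 20^2) / total_w, 0.01)
})

test_that("bioheat stepping preserves equilibrium and relaxes exactly", {
  g <- cube_grid(12, 2)
  tis <- tissue_properties("normal_liver")
  T0 <- scalar_map(array(37, g$shape), g, "degC")
  T1 <- T0
  for (i in 1:5) T1 <- step_bioheat(T1, 0, tis, dt = 0.5)
  expect_equal(T1$values, T0$values, tolerance = 1e-12)

  # conduction disabled: exponential relaxation toward 37 at w_b c_b/(rho c)
  tis0 <- tis; tis0$k <- 0
  Tm <- scalar_map(array(50, g$shape), g, "degC")
  lam <- tis$w_b_nc * tis$c_b / (tis$rho * tis$c)
  nofix <- array(FALSE, g$shape)
  for (s in 1:10) {
    Tm <- step_bioheat(Tm, 0, tis0, dt = 0.5, fixed = nofix)
    expected <- 37 + 13 * exp(-lam * 0.5 * s)
    expect_lt(abs(Tm$values[5] - expected) / (expected - 37 + 1e-12), 0.005)
  }
})

test_that("steady conduction from a small spherical source follows 1/r", {
  n <- 49; h <- 1
  g <- cube_grid(n, h, centered = TRUE)
  r <- radius_array(g)
  R <- 23
  src <- r <= 3
  q <- array(0, g$shape); q[src] <- 5e4
  tis <- tissue_properties("normal_liver", w_b_nc = 0)
  fx <- r >= R
  Tm <- scalar_map(array(37, g$shape), g, "degC")
  qm <- scalar_map(q, g, "W/m^3")
  for (i in 1:1200) Tm <- step_bioheat(Tm, qm, tis, w_b = 0, dt = 10,
                                       fixed = fx, fixed_values = 37)
  P <- sum(q) * (h * 1e-3)^3
  sel <- abs(r - 12) < 0.5 # mid-domain shell
  pred <- P / (4 * pi * tis$k) * (1 / (r[sel] * 1e-3) - 1 / (R * 1e-3))
  # closed-form shell solution, exact for this pinned spherical boundary
  obs <- Tm$values[sel] - 37
  expect_lt(max(abs(obs - pred) / pred), 0.05)
})

test_that("a zero-duration ablation changes nothing", {
  el <- electrode_spec(c(0, 0, 15))
  cfg <- simulation_config(domain_size = c(60, 60, 60), grid_spacing = 2.5,
                           duration = 0)
  r <- simulate_ablation(el, "normal_liver", cfg)
  expect_equal(sum(r$kill_mask_fine$membership), 0)
  free <- r$final_temperature$values[
    !ablate90:::boundary_mask_array(r$grid$shape)]
  expect_true(all(abs(free - 37) < 1e-9 | abs(free - 25) < 1e-9))
})

test_that("short ablation runs respect the cap and accumulate monotonically", {
  el <- electrode_spec(c(0, 0, 15))
  cfg <- simulation_config(domain_size = c(80, 80, 80), grid_spacing = 2,
                           duration = 120, snapshot_times = c(60, 120))
  r <- simulate_ablation(el, "hcc", cfg)
  expect_lte(max(r$applied_voltage_trace$t_hot), cfg$temp_cap + 0.5)
  expect_true(all(diff(r$kill_volume_trace$volume_cm3) >= 0))
  expect_true(all(r$coagulation_map$values >= 0 &
                    r$coagulation_map$values <= 1))
  expect_true(all(r$omega_map$values >= 0))
  # snapshots: the 60-s kill mask is a subset of the 120-s mask
  expect_length(r$snapshots, 2)
  expect_true(all(r$snapshots[[2]]$membership | !r$snapshots[[1]]$membership))
  expect_identical(r$snapshots[[2]]$membership, r$kill_mask_fine$membership)
  # determinism
  r2 <- simulate_ablation(el, "hcc", cfg)
  expect_identical(r$omega_map$values, r2$omega_map$values)
})

test_that("freezing perfusion at baseline cannot enlarge the kill zone", {
  el <- electrode_spec(c(0, 0, 15))
  base <- simulation_config(domain_size = c(80, 80, 80), grid_spacing = 2,
                            duration = 240)
  frozen <- base; frozen$coagulation <- FALSE
  kc <- mask_volume(simulate_ablation(el, "normal_liver", base)$kill_mask_fine)
  kf <- mask_volume(simulate_ablation(el, "normal_liver",
                                      frozen)$kill_mask_fine)
  expect_lte(kf, kc)
})

test_that("the temperature field is four-fold symmetric about the electrode axis", {
  el <- electrode_spec(c(0, 0, 15), c(0, 0, 1))
  # odd-shaped grid so the axis passes through voxel centres
  cfg <- simulation_config(domain_size = c(82, 82, 82), grid_spacing = 2,
                           time_step = 0.25, duration = 60)
  r <- simulate_ablation(el, "hcc", cfg)
  Tm <- r$final_temperature$values
  n <- dim(Tm)[1]
  Trot <- aperm(Tm, c(2, 1, 3))[n:1, , ]
  expect_lt(max(abs(Tm - Trot)), 0.1)
})

test_that("kill zones rebin consistently onto the dose grid", {
  el <- electrode_spec(c(0, 0, 15))
  cfg <- simulation_config(domain_size = c(80, 80, 80), grid_spacing = 2,
                           duration = 180)
  r <- simulate_ablation(el, "hcc", cfg)
  dg <- voxel_grid(c(32, 32, 32), 2.5, r$grid$origin)
  zone <- ablation_zone_on_grid(r, dg)
  vf <- mask_volume(r$kill_mask_fine)
  vc <- mask_volume(zone)
  # within one coarse-voxel surface layer of the fine volume
  surf <- 6 * (pi * (3 * vf * 1000 / (4 * pi))^(2 / 3)) * 2.5 / 1000
  expect_lt(abs(vc - vf), max(surf, 2))
  # empty fine mask -> empty coarse mask
  cfg0 <- cfg; cfg0$duration <- 0
  r0 <- simulate_ablation(el, "hcc", cfg0)
  expect_equal(sum(ablation_zone_on_grid(r0, dg)$membership), 0)
  # two disjoint sites union exactly
  el2 <- electrode_spec(c(0, 0, -15))
  zs <- lapply(list(r, r), function(x) ablation_zone_on_grid(x, dg))
  u <- mask_union(zs[[1]], zs[[2]])
  expect_identical(u$membership, zs[[1]]$membership)
})

test_that("YAML scenarios round-trip into electrode and config objects", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c("tissue: hcc", "tip_mm: [5, -3, 20]", "direction: [0, 1, 0]",
               "duration_s: 300", "grid_spacing_mm: 2.5", "domain_mm: 60",
               "time_step_s: 1"), p)
  sc <- read_scenario(p)
  expect_equal(sc$electrode$tip_position, c(5, -3, 20))
  expect_equal(sc$electrode$direction, c(0, 1, 0))
  expect_equal(sc$tissue, "hcc")
  expect_equal(sc$config$duration, 300)
  expect_equal(sc$config$grid_spacing, 2.5)
  expect_equal(sc$config$domain_size, rep(60, 3))
})
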