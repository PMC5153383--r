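make_dose_with_cold <- function(grid, hot = 150, cold = 30,
                                cold_radius = 12.5,
                                offset = c(0, 0, 0)) {
  d <- array(hot, grid$shape)
  cold_mask <- ball_mask(grid, cold_radius, offset)
  d[cold_mask$membership] <- cold
  list(dose = scalar_map(d, grid, "Gy"), cold = cold_mask)
}

test_that("cold regions are found, size-filtered and sorted largest-first", {
  g <- cube_grid(40, 2, centered = TRUE)
  tumor <- ball_mask(g, 35)
  # uniformly hot tumor: nothing to target
  hot <- scalar_map(array(150, g$shape), g, "Gy")
  expect_length(cold_regions(hot, tumor), 0)

  # one embedded 25-mm cold sphere
  mk <- make_dose_with_cold(g, cold_radius = 12.5)
  regs <- cold_regions(mk$dose, tumor)
  expect_length(regs, 1)
  v_built <- mask_volume(mk$cold)
  expect_lt(abs(mask_volume(regs[[1]]) - v_built) / v_built, 0.10)

  # two cold spheres of different sizes, returned largest-first
  d <- array(150, g$shape)
  big <- ball_mask(g, 14, c(-18, 0, 0))
  small <- ball_mask(g, 11, c(20, 0, 0))
  d[big$membership] <- 20
  d[small$membership] <- 20
  regs2 <- cold_regions(scalar_map(d, g, "Gy"), tumor)
  expect_length(regs2, 2)
  expect_gt(mask_volume(regs2[[1]]), mask_volume(regs2[[2]]))
  # the sub-2cm sphere is filtered out at the default minimum size
  d3 <- array(150, g$shape)
  tiny <- ball_mask(g, 8)
  d3[tiny$membership] <- 20
  expect_length(cold_regions(scalar_map(d3, g, "Gy"), tumor), 0)
})

test_that("plan validation flags margins and overlaps, passes clean plans", {
  g <- cube_grid(50, 2, centered = TRUE)
  tumor <- ball_mask(g, 30)
  dose <- scalar_map(array(50, g$shape), g, "Gy")
  el <- electrode_spec(c(0, 0, 15))
  plan <- ablation_plan(list(electrode_placement(el, 600)))
  zone <- ball_mask(g, 10)

  gi_far <- ball_mask(g, 6, c(44, 0, 0))   # ~28 mm from zone surface
  rep1 <- validate_plan(plan, list(zone), dose, tumor,
                        plan_constraints(spare_masks = list(gi = gi_far)))
  expect_true(rep1$ok)
  expect_equal(rep1$placements[[1]]$frac_outside_tumor, 0)

  gi_near <- ball_mask(g, 6, c(21, 0, 0))  # ~5 mm gap
  rep2 <- validate_plan(plan, list(zone), dose, tumor,
                        plan_constraints(spare_masks = list(gi = gi_near)))
  expect_false(rep2$ok)
  expect_match(rep2$placements[[1]]$violations, "margin")

  gb <- ball_mask(g, 8, c(12, 0, 0))       # overlaps the zone
  rep3 <- validate_plan(plan, list(zone), dose, tumor,
                        plan_constraints(spare_masks = list(gallbladder = gb)))
  expect_false(rep3$ok)
  expect_match(rep3$placements[[1]]$violations, "gallbladder")

  # the soft isodose warning is not a hard violation
  hotdose <- scalar_map(array(150, g$shape), g, "Gy")
  rep4 <- validate_plan(plan, list(zone), hotdose, tumor, plan_constraints())
  expect_true(rep4$ok)
  expect_gt(length(rep4$placements[[1]]$warnings), 0)
})

test_that("mask distances match a brute-force all-pairs voxel oracle", {
  set.seed(71)
  g <- cube_grid(16, 2)
  for (i in 1:4) {
    a <- array(FALSE, g$shape)
    b <- array(FALSE, g$shape)
    a[sample(16^3, 40)] <- TRUE
    b[sample(16^3, 40)] <- TRUE
    ma <- label_mask(a, g); mb <- label_mask(b, g)
    ia <- which(a, arr.ind = TRUE); ib <- which(b, arr.ind = TRUE)
    pa <- (ia - 1) * 2; pb <- (ib - 1) * 2
    d_oracle <- min(sqrt(outer(rowSums(pa^2), rowSums(pb^2), `+`) -
                           2 * pa %*% t(pb)))
    expect_equal(mask_distance(ma, mb), max(d_oracle, 0), tolerance = 1e-9)
  }
})

test_that("the greedy planner targets cold centroids deterministically", {
  g <- cube_grid(40, 2, centered = TRUE)
  tumor <- ball_mask(g, 32)
  mk <- make_dose_with_cold(g, cold_radius = 12.5, offset = c(5, -4, 3))
  pred <- fake_zone_predictor(g)
  cons <- plan_constraints()
  res <- auto_plan(mk$dose, tumor, cons, pred)
  expect_length(res$plan$placements, 1)
  # the electrode axis passes within 5 mm of the cold-region centroid
  ctr <- mask_centroid(cold_regions(mk$dose, tumor)[[1]])
  pl <- res$plan$placements[[1]]
  p1 <- pl$electrode$tip_position
  p0 <- p1 - pl$electrode$active_length * pl$electrode$direction
  tpar <- sum((ctr - p0) * (p1 - p0)) / sum((p1 - p0)^2)
  proj <- p0 + min(max(tpar, 0), 1) * (p1 - p0)
  expect_lt(sqrt(sum((ctr - proj)^2)), 5)

  # determinism: identical inputs give identical plans
  res2 <- auto_plan(mk$dose, tumor, cons, pred)
  expect_identical(res$plan, res2$plan)

  # no cold regions: empty plan with a reason
  hot <- scalar_map(array(150, g$shape), g, "Gy")
  res3 <- auto_plan(hot, tumor, cons, pred)
  expect_null(res3$plan)
  expect_match(res3$reasons, "no cold regions")
})

test_that("the planner honours site and duration caps", {
  g <- cube_grid(48, 2, centered = TRUE)
  tumor <- ball_mask(g, 44)
  d <- array(150, g$shape)
  for (off in list(c(-25, -25, 0), c(25, 25, 0), c(-25, 25, 0),
                   c(25, -25, 0), c(0, 0, 25)))
    d[ball_mask(g, 11, off)$membership] <- 20
  res <- auto_plan(scalar_map(d, g, "Gy"), tumor, plan_constraints(),
                   fake_zone_predictor(g))
  expect_lte(length(res$plan$placements), 4)
  for (p in res$plan$placements) {
    expect_lte(p$duration, 600)
    expect_gt(p$duration, 0)
  }
})

test_that("plans survive a JSON round trip", {
  el <- electrode_spec(c(10, -5, 30), c(0, 1, 1))
  plan <- ablation_plan(list(electrode_placement(el, 480),
                             electrode_placement(electrode_spec(c(0, 0, 0)),
                                                 240)))
  p <- tempfile(fileext = ".json")
  write_plan(plan, p)
  plan2 <- read_plan(p)
  expect_equal(length(plan2$placements), 2)
  expect_equal(plan2$placements[[1]]$duration, 480)
  expect_equal(plan2$placements[[1]]$electrode$tip_position, c(10, -5, 30))
  expect_equal(plan2$placements[[1]]$electrode$direction,
               el$direction, tolerance = 1e-12)
})
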