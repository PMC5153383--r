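#' Phantom specification
#'
#' Parameters of one synthetic post-radioembolization case: a lumpy
#' ellipsoidal tumor with heterogeneous microsphere uptake, at least one
#' embedded cold (low-uptake) sub-region larger than 2 cm, a surrounding
#' liver background, and organ-at-risk masks.  Defaults emulate the
#' inclusion population the analysis assumes: tumor volumes of
#' 42.5-374.6 cm^3, infused activities 0.62-4.13 GBq, cold regions > 2 cm.
#'
#' When `liver_background_fraction` is `NULL` it is derived so the tumor
#' mean dose lands at `target_davg` (the activity/volume ratios of real
#' cohorts vary too widely for a fixed tumor/liver split to keep the mean
#' dose in a realistic 67-210 Gy band).
#'
#' @param seed integer seed driving the single generator stream.
#' @param grid the dose-grid [voxel_grid()] (default 2 mm isotropic,
#'   128^3).
#' @param tumor_volume target tumor volume, cm^3.
#' @param n_cold_regions number of cold spheres (>= 1).
#' @param cold_diameter cold-sphere diameter, mm (> 20 to satisfy the
#'   2-cm visibility criterion).
#' @param cold_uptake_fraction relative activity concentration in cold vs
#'   surrounding tumor (default 0.15).
#' @param infused_activity infused activity, GBq.
#' @param device `"resin"` or `"glass"`.
#' @param liver_background_fraction share of total activity deposited
#'   outside the tumor, or `NULL` to derive from `target_davg`.
#' @param target_davg target tumor mean dose, Gy (used when
#'   `liver_background_fraction` is `NULL`).
#' @param texture_sigma log-SD of the lognormal intratumoral texture.
#' @param texture_corr_mm correlation length of the texture field, mm.
#' @param rim_gain relative uptake increase at the tumor rim.
#' @param tissue tissue preset for ablation simulation.
#' @param id case identifier (default derived from the seed).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(seed, grid = voxel_grid(c(128, 128, 128), 2),
                         tumor_volume = 150, n_cold_regions = 1,
                         cold_diameter = 25, cold_uptake_fraction = 0.15,
                         infused_activity = 1.5, device = "resin",
                         liver_background_fraction = NULL,
                         target_davg = 130, texture_sigma = 0.8,
                         texture_corr_mm = 8, rim_gain = 0.6,
                         tissue = "hcc", id = NULL) {
  stopifnot(tumor_volume > 0, n_cold_regions >= 1, cold_diameter > 0,
            cold_uptake_fraction > 0, infused_activity > 0)
  if (!device %in% c("resin", "glass")) stop("unknown device label: ", device)
  structure(list(seed = as.integer(seed), grid = grid,
                 tumor_volume = tumor_volume,
                 n_cold_regions = n_cold_regions,
                 cold_diameter = cold_diameter,
                 cold_uptake_fraction = cold_uptake_fraction,
                 infused_activity = infused_activity, device = device,
                 liver_background_fraction = liver_background_fraction,
                 target_davg = target_davg, texture_sigma = texture_sigma,
                 texture_corr_mm = texture_corr_mm, rim_gain = rim_gain,
                 tissue = tissue,
                 id = id %||% sprintf("phantom-%d", as.integer(seed))),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

fft_freqs <- function(n) {
  f <- seq_len(n) - 1
  f[f > n / 2] <- f[f > n / 2] - n
  f / n
}

# Standardized Gaussian random field with the given correlation length (mm),
# generated by Fourier-domain smoothing of white noise.
gaussian_random_field <- function(grid, corr_mm) {
  shp <- grid$shape
  noise <- array(stats::rnorm(prod(shp)), shp)
  sig_vox <- corr_mm / grid$spacing
  H1 <- exp(-2 * pi^2 * sig_vox[1]^2 * fft_freqs(shp[1])^2)
  H2 <- exp(-2 * pi^2 * sig_vox[2]^2 * fft_freqs(shp[2])^2)
  H3 <- exp(-2 * pi^2 * sig_vox[3]^2 * fft_freqs(shp[3])^2)
  H <- outer(outer(H1, H2), H3)
  sm <- Re(stats::fft(stats::fft(noise) * H, inverse = TRUE)) / prod(shp)
  (sm - mean(sm)) / stats::sd(sm)
}

grid_coord_arrays <- function(grid) {
  shp <- grid$shape
  list(x = array(voxel_centers(grid, 1), shp),
       y = array(rep(voxel_centers(grid, 2), each = shp[1]), shp),
       z = array(rep(voxel_centers(grid, 3), each = shp[1] * shp[2]), shp))
}

#' Generate a synthetic post-radioembolization case
#'
#' Builds a lumpy ellipsoidal tumor mask hitting the requested volume
#' within 5%, an activity map with a smooth lognormal texture
#' (rim-weighted, depressed inside embedded cold spheres) over a liver
#' background ellipsoid, renormalized so the map total equals the infused
#' activity exactly, plus organ masks (a gastrointestinal tube, a
#' gallbladder ellipsoid and a capsule shell).  Deterministic given the
#' spec seed.
#'
#' @param spec a [phantom_spec()].
#' @return A [tumor_case()]; the generating spec and the cold-region masks
#'   are attached as attributes `phantom_spec` and `cold_masks`.
#' @export
make_phantom <- function(spec) with_seed(spec$seed, {
  grid <- spec$grid
  shp <- grid$shape
  co <- grid_coord_arrays(grid)
  center <- grid$origin + (shp - 1) / 2 * grid$spacing
  extent <- shp * grid$spacing

  ratios <- stats::runif(3, 0.75, 1.3)
  target_mm3 <- spec$tumor_volume * 1000
  r0 <- (3 * target_mm3 / (4 * pi * prod(ratios)))^(1 / 3)
  semi <- r0 * ratios
  if (any(2 * semi > 0.85 * extent))
    stop("tumor does not fit inside the grid; enlarge the grid or shrink it")
  lump <- gaussian_random_field(grid, corr_mm = 12)

  u <- NULL
  tumor <- NULL
  for (iter in 1:5) {
    u <- sqrt(((co$x - center[1]) / semi[1])^2 +
              ((co$y - center[2]) / semi[2])^2 +
              ((co$z - center[3]) / semi[3])^2)
    tumor <- u <= 1 + 0.12 * lump
    vol <- sum(tumor) * voxel_volume(grid) / 1000
    fac <- (spec$tumor_volume / vol)^(1 / 3)
    if (abs(fac - 1) < 0.005) break
    semi <- semi * fac
  }
  vol <- sum(tumor) * voxel_volume(grid) / 1000
  if (abs(vol - spec$tumor_volume) > 0.05 * spec$tumor_volume)
    stop(sprintf("tumor volume calibration failed: %.1f vs target %.1f cm^3",
                 vol, spec$tumor_volume))

  # cold spheres, fully inside the tumor, non-overlapping: admissible
  # centres are found by eroding the tumor with an r_c ball (binary
  # convolution of the tumor complement with the ball kernel via FFT)
  r_c <- spec$cold_diameter / 2
  kern <- array(0, shp)
  kr <- ((co$x - co$x[1] - (shp[1] %/% 2) * grid$spacing[1])^2 +
         (co$y - co$y[1] - (shp[2] %/% 2) * grid$spacing[2])^2 +
         (co$z - co$z[1] - (shp[3] %/% 2) * grid$spacing[3])^2)
  kern[kr <= (r_c + 0.5 * max(grid$spacing))^2] <- 1
  # recentre kernel at the array origin for circular convolution
  for (a in 1:3) {
    idx <- lapply(shp, seq_len)
    idx[[a]] <- c((shp[a] %/% 2 + 1):shp[a], 1:(shp[a] %/% 2))
    kern <- do.call(`[`, c(list(kern), idx))
  }
  outside_hits <- Re(stats::fft(stats::fft(array(as.numeric(!tumor), shp)) *
                                stats::fft(kern), inverse = TRUE)) / prod(shp)
  admissible <- tumor & (outside_hits < 0.5)
  cold_masks <- list()
  cold_all <- array(FALSE, shp)
  cand <- which(admissible)
  centres <- matrix(numeric(0), ncol = 3)
  for (k in seq_len(spec$n_cold_regions)) {
    if (length(cand) == 0)
      stop("cold region cannot fit: no admissible centre found")
    i <- cand[sample.int(length(cand), 1)]
    cc <- c(co$x[i], co$y[i], co$z[i])
    sph <- ((co$x - cc[1])^2 + (co$y - cc[2])^2 + (co$z - cc[3])^2) <= r_c^2
    cold_masks[[k]] <- label_mask(sph, grid)
    cold_all <- cold_all | sph
    centres <- rbind(centres, cc)
    # keep later centres at least one diameter away (disjoint spheres)
    keep <- sqrt((co$x[cand] - cc[1])^2 + (co$y[cand] - cc[2])^2 +
                 (co$z[cand] - cc[3])^2) > 2 * r_c
    cand <- cand[keep]
  }

  # activity texture
  G <- gaussian_random_field(grid, corr_mm = spec$texture_corr_mm)
  rel <- exp(spec$texture_sigma * G) * (1 + spec$rim_gain * pmin(u, 1)^2)
  rel[cold_all] <- rel[cold_all] * spec$cold_uptake_fraction

  # liver background ellipsoid containing the tumor
  semi_l <- pmin(semi * 1.8 + 15, extent / 2 - 3 * grid$spacing)
  ul <- sqrt(((co$x - center[1]) / semi_l[1])^2 +
             ((co$y - center[2]) / semi_l[2])^2 +
             ((co$z - center[3]) / semi_l[3])^2)
  liver <- ul <= 1
  bg_region <- liver & !tumor
  bg_rel <- exp(0.3 * G)

  vox_kg <- voxel_volume(grid) * 1e-9 * 1060
  m_t <- sum(tumor) * vox_kg
  if (is.null(spec$liver_background_fraction)) {
    a_t <- spec$target_davg * m_t / ldm_constants()$gy_per_gbq_per_kg
    f_bg <- min(max(1 - a_t / spec$infused_activity, 0.02), 0.98)
  } else f_bg <- spec$liver_background_fraction
  a_total_bq <- spec$infused_activity * 1e9
  act <- array(0, shp)
  act[tumor] <- rel[tumor] / sum(rel[tumor]) * (1 - f_bg) * a_total_bq
  if (any(bg_region))
    act[bg_region] <- bg_rel[bg_region] / sum(bg_rel[bg_region]) *
      f_bg * a_total_bq
  act <- act * (a_total_bq / sum(act)) # exact renormalization

  # organ masks: GI tube, gallbladder, capsule shell
  gi_x <- min(center[1] + semi_l[1] + 12, max(voxel_centers(grid, 1)) - 4)
  gi <- sqrt((co$x - gi_x)^2 + (co$z - center[3])^2) <= 6
  gb_c <- center + c(-semi_l[1] * 0.8, semi_l[2] * 0.25, 0)
  gb <- sqrt(((co$x - gb_c[1]) / 12)^2 + ((co$y - gb_c[2]) / 9)^2 +
             ((co$z - gb_c[3]) / 9)^2) <= 1
  gb <- gb & !tumor
  capsule <- ul <= 1 & ul >= 1 - 1.5 * max(grid$spacing) / min(semi_l)

  case <- tumor_case(id = spec$id, device = spec$device,
                     activity_map = scalar_map(act, grid, units = "Bq"),
                     tumor_mask = label_mask(tumor, grid),
                     organ_masks = list(gi = label_mask(gi, grid),
                                        gallbladder = label_mask(gb, grid),
                                        capsule = label_mask(capsule, grid)),
                     tissue = spec$tissue)
  attr(case, "phantom_spec") <- spec
  attr(case, "cold_masks") <- cold_masks
  case
})

#' Rescale cold-region uptake until the case is treatment-eligible
#'
#' A generated case qualifies for adjuvant ablation when its tumor D70
#' falls below the device threshold (100 Gy resin / 150 Gy glass).  An
#' already-eligible case is returned unchanged; otherwise the cold-region
#' uptake fraction is bisected downward (deepening the cold regions, which
#' lowers D70) until eligibility holds, while the tumor mean dose must stay
#' within 67.3-210.2 Gy.
#'
#' @param case a case from [make_phantom()].
#' @param device device label (defaults to the case's own).
#' @param constants [ldm_constants()] for the dose computation.
#' @param max_steps bisection step limit (default 50).
#' @param davg_range admissible tumor mean dose band, Gy.
#' @return An eligible [tumor_case()] (regenerated with the rescaled cold
#'   uptake when needed).
#' @export
calibrate_to_eligibility <- function(case, device = case$device,
                                     constants = ldm_constants(),
                                     max_steps = 50,
                                     davg_range = c(67.3, 210.2)) {
  spec <- attr(case, "phantom_spec")
  if (is.null(spec)) stop("case was not generated by make_phantom")
  metrics_at <- function(s) {
    sp <- spec
    sp$cold_uptake_fraction <- s
    cs <- make_phantom(sp)
    list(case = cs, m = dose_metrics(ldm_dose(cs$activity_map, constants),
                                     cs$tumor_mask))
  }
  check_davg <- function(m) m$d_avg >= davg_range[1] && m$d_avg <= davg_range[2]
  m0 <- dose_metrics(ldm_dose(case$activity_map, constants), case$tumor_mask)
  if (eligibility(m0, device)) {
    if (!check_davg(m0))
      stop(sprintf("tumor mean dose %.1f Gy outside the admissible band",
                   m0$d_avg))
    return(case)
  }
  lo <- 1e-3
  hi <- spec$cold_uptake_fraction
  flo <- metrics_at(lo)
  if (!eligibility(flo$m, device))
    stop(sprintf(paste0("infeasible: D70 = %.1f Gy even with cold uptake ",
                        "fraction %.3g; the cold volume fraction is too ",
                        "small to move D70 below the threshold"),
                 flo$m$d70, lo))
  best <- list(s = lo, res = flo)
  for (step in seq_len(max_steps)) {
    mid <- (lo + hi) / 2
    fm <- metrics_at(mid)
    if (eligibility(fm$m, device)) {
      lo <- mid
      best <- list(s = mid, res = fm)
    } else hi <- mid
  }
  if (!check_davg(best$res$m))
    stop(sprintf(paste0("calibration failed after %d steps: mean dose %.1f ",
                        "Gy left the admissible band"),
                 max_steps, best$res$m$d_avg))
  best$res$case
}

#' Generate a synthetic cohort
#'
#' Draws `n` phantom cases with tumor volumes and infused activities
#' uniform over the stated ranges, roughly 70% flagged as HCC (exercising
#' the tissue-preset rule: `hcc` preset for HCC, `normal_liver` otherwise),
#' and calibrates every case to ablation eligibility.  Deterministic per
#' seed.
#'
#' @param n number of cases (>= 1).
#' @param seed master seed.
#' @param grid dose grid shared by all cases.
#' @param volume_range tumor volume range, cm^3.
#' @param activity_range infused activity range, GBq.
#' @param davg_range tumor mean-dose band the generator targets, Gy.
#' @param hcc_fraction probability a case is HCC (default 10/14).
#' @param glass_fraction probability a case used glass microspheres.
#' @param ... further fields forwarded to [phantom_spec()].
#' @return A list of [tumor_case()]s.
#' @export
make_cohort <- function(n, seed, grid = voxel_grid(c(128, 128, 128), 2),
                        volume_range = c(42.5, 374.6),
                        activity_range = c(0.62, 4.13),
                        davg_range = c(80, 180),
                        hcc_fraction = 10 / 14, glass_fraction = 3 / 15,
                        ...) {
  stopifnot(n >= 1)
  draws <- cohort_draws(n, seed, volume_range, activity_range, davg_range,
                        hcc_fraction, glass_fraction)
  lapply(seq_len(n), function(i) {
    sp <- phantom_spec(seed = draws$seed[i], grid = grid,
                       tumor_volume = draws$tumor_volume[i],
                       infused_activity = draws$infused_activity[i],
                       device = draws$device[i],
                       target_davg = draws$target_davg[i],
                       tissue = draws$tissue[i],
                       id = draws$id[i], ...)
    calibrate_to_eligibility(make_phantom(sp))
  })
}

#' Cohort parameter draws
#'
#' The random draws behind [make_cohort()], exposed separately: per-case
#' sub-seeds, tumor volumes, infused activities, target mean doses, device
#' labels and tissue presets.  Deterministic per seed.
#'
#' @inheritParams make_cohort
#' @return A data frame with one row per case.
#' @export
cohort_draws <- function(n, seed, volume_range = c(42.5, 374.6),
                         activity_range = c(0.62, 4.13),
                         davg_range = c(80, 180), hcc_fraction = 10 / 14,
                         glass_fraction = 3 / 15) {
  with_seed(seed, {
    data.frame(
      id = sprintf("case%02d", seq_len(n)),
      seed = sample.int(2147483646L, n),
      tumor_volume = stats::runif(n, volume_range[1], volume_range[2]),
      infused_activity = stats::runif(n, activity_range[1],
                                      activity_range[2]),
      target_davg = stats::runif(n, davg_range[1], davg_range[2]),
      tissue = ifelse(stats::runif(n) < hcc_fraction, "hcc", "normal_liver"),
      device = ifelse(stats::runif(n) < glass_fraction, "glass", "resin"))
  })
}
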