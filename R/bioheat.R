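#' Tissue electrothermal properties
#'
#' Property sets for the RF ablation simulation: electrical conductivity
#' `sigma` (S/m), density `rho` (kg/m^3), specific heat `c` (J/kg/degC),
#' thermal conductivity `k` (W/m/degC), baseline blood perfusion `w_b_nc`
#' (m^3/m^3/s), blood specific heat `c_b` (J/kg/degC) and arterial
#' temperature `T_a` (degC).  Three literature presets are shipped
#' (central values):
#'
#' * `normal_liver`: sigma 0.260, rho 1060, c 3540, k 0.52, w_b_nc 0.0180,
#'   c_b 3617
#' * `cirrhotic_liver`: sigma 0.260, rho 1040, c 3540, k 0.52, w_b_nc
#'   0.0115, c_b 3617
#' * `hcc`: sigma 0.504, rho 1060, c 3540, k 0.52, w_b_nc 0.0155, c_b 3617
#'
#' The convention for patient cases: the `hcc` preset for hepatocellular
#' carcinoma, `normal_liver` for metastatic or cholangiocarcinoma cases
#' (no tumor-specific data available for those).
#'
#' @param preset one of `"normal_liver"`, `"cirrhotic_liver"`, `"hcc"`, or
#'   `NULL` to give fields directly.
#' @param sigma,rho,c,k,w_b_nc,c_b,T_a individual property overrides.
#' @return An object of class `tissue_properties`.
#' @export
tissue_properties <- function(preset = NULL, sigma = NULL, rho = NULL,
                              c = NULL, k = NULL, w_b_nc = NULL,
                              c_b = NULL, T_a = 37) {
  presets <- list(
    normal_liver = list(sigma = 0.260, rho = 1060, c = 3540, k = 0.52,
                        w_b_nc = 0.0180, c_b = 3617),
    cirrhotic_liver = list(sigma = 0.260, rho = 1040, c = 3540, k = 0.52,
                           w_b_nc = 0.0115, c_b = 3617),
    hcc = list(sigma = 0.504, rho = 1060, c = 3540, k = 0.52,
               w_b_nc = 0.0155, c_b = 3617))
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(presets))
    p <- presets[[preset]]
  } else p <- list()
  p$sigma <- sigma %||% p$sigma
  p$rho <- rho %||% p$rho
  p$c <- c %||% p$c
  p$k <- k %||% p$k
  p$w_b_nc <- w_b_nc %||% p$w_b_nc
  p$c_b <- c_b %||% p$c_b
  p$T_a <- T_a
  if (any(vapply(p[c("sigma", "rho", "c", "k", "c_b")], function(v)
    is.null(v) || v <= 0, logical(1))))
    stop("all tissue properties must be given and positive")
  if (is.null(p$w_b_nc) || p$w_b_nc < 0)
    stop("w_b_nc must be given and >= 0")
  p$preset <- preset %||% "custom"
  structure(p, class = "tissue_properties")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Water-cooled RF electrode geometry
#'
#' A straight 17-gauge electrode (outer diameter 1.473 mm) with a 30-mm
#' active tip.  `tip_position` is the distal end of the active tip; the
#' active segment extends back along `-direction` by `active_length`.
#'
#' @param tip_position world position (mm) of the distal tip.
#' @param direction unit insertion direction (normalized internally).
#' @param active_length active-tip length, mm.
#' @param radius electrode radius, mm (17 gauge default).
#' @param insulated_shaft logical; the shaft proximal to the active tip is
#'   electrically insulated.
#' @param coolant_temp internal water-cooling temperature, degC.
#' @return An object of class `electrode_spec`.
#' @export
electrode_spec <- function(tip_position, direction = c(0, 0, 1),
                           active_length = 30, radius = 0.7365,
                           insulated_shaft = TRUE, coolant_temp = 25) {
  if (active_length <= 0) stop("active_length must be > 0")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a non-zero vector")
  structure(list(tip_position = as.numeric(tip_position),
                 direction = as.numeric(direction) / nrm,
                 active_length = active_length, radius = radius,
                 insulated_shaft = insulated_shaft,
                 coolant_temp = coolant_temp),
            class = "electrode_spec")
}

#' Simulation configuration for RF ablation
#'
#' @param domain_size edge lengths of the simulated tissue block, mm.
#' @param grid_spacing uniform voxel spacing of the simulation grid, mm.
#' @param time_step solver time step, s.
#' @param duration ablation duration, s (<= 600 per site).
#' @param max_duration hard ceiling on duration, s.
#' @param temp_cap feedback cap on the hottest tissue node, degC.
#' @param boundary_temp Dirichlet temperature of the block boundary, degC.
#' @param kp proportional controller gain (fractional voltage change per
#'   degC of lead-predicted error).
#' @param ki slow corrective gain on the instantaneous error (removes the
#'   steady offset the lead term would otherwise leave).
#' @param lead_s controller lead time, s (anticipates the heating trend to
#'   avoid overshoot).
#' @param v0,vmax initial and maximum applied voltage, V.
#' @param setpoint_margin controller setpoint is `temp_cap -
#'   setpoint_margin` (degC).
#' @param omega_threshold cell-death damage threshold defining the kill
#'   mask.
#' @param coagulation logical; update perfusion as `w_b = w_b_nc (1 - C_f)`
#'   during the run (`FALSE` freezes perfusion at baseline).
#' @param snapshot_times optional times (s) at which intermediate kill
#'   masks are recorded.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(domain_size = c(100, 100, 100),
                              grid_spacing = 1.0, time_step = 0.5,
                              duration = 600, max_duration = 600,
                              temp_cap = 105, boundary_temp = 37,
                              kp = 0.02, ki = 0.004, lead_s = 3, v0 = 10,
                              vmax = 150,
                              setpoint_margin = 1.0,
                              omega_threshold = 6.9, coagulation = TRUE,
                              snapshot_times = NULL) {
  if (duration < 0) stop("duration must be >= 0")
  if (duration > max_duration)
    stop("duration exceeds the configured maximum of ", max_duration, " s")
  if (temp_cap <= boundary_temp) stop("temp_cap must exceed boundary_temp")
  structure(list(domain_size = rep_len(domain_size, 3),
                 grid_spacing = grid_spacing, time_step = time_step,
                 duration = duration, max_duration = max_duration,
                 temp_cap = temp_cap, boundary_temp = boundary_temp,
                 kp = kp, ki = ki, lead_s = lead_s, v0 = v0, vmax = vmax,
                 setpoint_margin = setpoint_margin,
                 omega_threshold = omega_threshold,
                 coagulation = coagulation,
                 snapshot_times = snapshot_times),
            class = "simulation_config")
}

# Voxels within `radius` mm of the segment from p0 to p1 (world mm).
segment_mask <- function(grid, p0, p1, radius) {
  xs <- voxel_centers(grid, 1); ys <- voxel_centers(grid, 2)
  zs <- voxel_centers(grid, 3)
  d <- p1 - p0
  len2 <- sum(d^2)
  X <- array(xs, grid$shape)
  Y <- array(rep(ys, each = grid$shape[1]), grid$shape)
  Z <- array(rep(zs, each = grid$shape[1] * grid$shape[2]), grid$shape)
  if (len2 == 0) {
    dist2 <- (X - p0[1])^2 + (Y - p0[2])^2 + (Z - p0[3])^2
  } else {
    tpar <- ((X - p0[1]) * d[1] + (Y - p0[2]) * d[2] + (Z - p0[3]) * d[3]) / len2
    tpar <- pmin(pmax(tpar, 0), 1)
    dist2 <- (X - (p0[1] + tpar * d[1]))^2 + (Y - (p0[2] + tpar * d[2]))^2 +
      (Z - (p0[3] + tpar * d[3]))^2
  }
  dist2 <= radius^2
}

# Active-tip voxel mask: voxels within the electrode radius of the active
# segment, plus the voxels the segment passes through (so the electrode is
# represented even when coarser voxels' centres all lie outside its radius).
electrode_tip_voxels <- function(grid, electrode) {
  p1 <- electrode$tip_position
  p0 <- p1 - electrode$active_length * electrode$direction
  m <- segment_mask(grid, p0, p1, electrode$radius)
  step <- min(grid$spacing) / 4
  npt <- max(2, ceiling(electrode$active_length / step))
  tt <- seq(0, 1, length.out = npt)
  pts <- cbind(p0[1] + tt * (p1[1] - p0[1]), p0[2] + tt * (p1[2] - p0[2]),
               p0[3] + tt * (p1[3] - p0[3]))
  idx <- sweep(pts, 2, grid$origin) / rep(grid$spacing, each = nrow(pts))
  idx <- round(idx) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= grid$shape[1] &
    idx[, 2] >= 1 & idx[, 2] <= grid$shape[2] &
    idx[, 3] >= 1 & idx[, 3] <= grid$shape[3]
  idx <- idx[ok, , drop = FALSE]
  m[cbind(idx[, 1], idx[, 2], idx[, 3])] <- TRUE
  m
}

# nb[i] = m[i + o] (FALSE outside the array)
shift_logical <- function(m, o) {
  shp <- dim(m)
  out <- array(FALSE, shp)
  src <- lapply(shp, seq_len)
  dst <- lapply(shp, seq_len)
  for (a in 1:3) {
    if (o[a] == 1) { dst[[a]] <- 1:(shp[a] - 1); src[[a]] <- 2:shp[a] }
    else if (o[a] == -1) { dst[[a]] <- 2:shp[a]; src[[a]] <- 1:(shp[a] - 1) }
  }
  do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(m), src)))))
}

face_offsets <- function() {
  list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
       c(0, 0, -1), c(0, 0, 1))
}

# Sub-voxel boundary fractions: for every free voxel with a rasterized
# electrode voxel as face neighbour, the fraction theta of the grid step at
# which the true electrode (capsule) surface is crossed.  Makes the
# effective electrode radius independent of the grid spacing.
electrode_theta <- function(grid, electrode, tip) {
  n <- prod(grid$shape)
  theta <- rep(1, 6L * n)
  p1 <- electrode$tip_position
  p0 <- p1 - electrode$active_length * electrode$direction
  a <- electrode$radius
  dseg <- function(P) {
    d <- p1 - p0
    len2 <- sum(d^2)
    tpar <- ((P[, 1] - p0[1]) * d[1] + (P[, 2] - p0[2]) * d[2] +
               (P[, 3] - p0[3]) * d[3]) / len2
    tpar <- pmin(pmax(tpar, 0), 1)
    sqrt((P[, 1] - (p0[1] + tpar * d[1]))^2 +
         (P[, 2] - (p0[2] + tpar * d[2]))^2 +
         (P[, 3] - (p0[3] + tpar * d[3]))^2)
  }
  co <- grid_coord_arrays(grid)
  offs <- face_offsets()
  for (f in 1:6) {
    o <- offs[[f]]
    nb <- shift_logical(tip, o)
    sel <- which(!tip & nb)
    if (!length(sel)) next
    P <- cbind(co$x[sel], co$y[sel], co$z[sel])
    step <- o * grid$spacing
    P1 <- P + matrix(step, nrow(P), 3, byrow = TRUE)
    f0 <- dseg(P) - a
    f1 <- dseg(P1) - a
    cross <- f0 > 0 & f1 < 0
    th <- rep(1, length(sel))
    if (any(cross)) {
      lo <- rep(0, sum(cross))
      hi <- rep(1, sum(cross))
      Pc <- P[cross, , drop = FALSE]
      for (it in 1:30) {
        mid <- (lo + hi) / 2
        Pm <- Pc + outer(mid, step)
        inside <- dseg(Pm) < a
        hi[inside] <- mid[inside]
        lo[!inside] <- mid[!inside]
      }
      th[cross] <- pmax((lo + hi) / 2, 0.1)
    }
    theta[sel + n * (f - 1)] <- th
  }
  theta
}

boundary_mask_array <- function(shape) {
  m <- array(FALSE, shape)
  m[c(1, shape[1]), , ] <- TRUE
  m[, c(1, shape[2]), ] <- TRUE
  m[, , c(1, shape[3])] <- TRUE
  m
}

#' Generic Dirichlet Poisson/Laplace solve on a voxel grid
#'
#' Solves `-div(c grad u) = rhs` with values pinned on `fixed` voxels, by
#' preconditioned conjugate gradients on the 7-point finite-volume stencil
#' (harmonic-mean face conductivities).  Used for the quasi-static electric
#' potential and available for steady conduction problems.
#'
#' @param grid a [voxel_grid()].
#' @param cond conductivity: a scalar or a [scalar_map()].
#' @param fixed logical array of pinned voxels.
#' @param fixed_values numeric array of pinned values (same shape).
#' @param rhs right-hand side (scalar or array), same units balance as
#'   `cond * u / length^2`.
#' @param tol relative residual tolerance.
#' @param maxit maximum CG iterations.
#' @return A [scalar_map()] of the solution.
#' @export
solve_laplace_dirichlet <- function(grid, cond, fixed, fixed_values,
                                    rhs = 0, tol = 1e-8, maxit = 2000,
                                    theta = NULL) {
  n <- prod(grid$shape)
  cv <- if (inherits(cond, "scalar_map")) as.numeric(cond$values)
        else as.numeric(cond)
  fx <- as.logical(fixed)
  fv <- rep_len(as.numeric(fixed_values), n)
  rv <- rep_len(as.numeric(rhs), n)
  h <- grid$spacing * 1e-3 # mm -> m
  res <- cpp_cg_poisson(grid$shape, h, cv, fx, fv, rv, tol, as.integer(maxit),
                        theta %||% numeric(0))
  if (res$residual > max(tol * 100, 1e-5) && res$iterations >= maxit)
    stop("linear solve did not converge (residual ", format(res$residual), ")")
  scalar_map(res$u, grid)
}

#' Quasi-static electric potential for a unit electrode drive
#'
#' Solves `div(sigma grad V) = 0` with `V = 1` on the active electrode tip
#' and `V = 0` on the domain boundary (dispersive ground).  The solution
#' obeys the discrete maximum principle (`0 <= V <= 1`) and, with uniform
#' conductivity, is independent of the value of `sigma`.
#'
#' @param grid simulation [voxel_grid()].
#' @param sigma_field electrical conductivity, S/m: scalar or
#'   [scalar_map()].
#' @param electrode an [electrode_spec()]; the active tip must lie inside
#'   the domain.
#' @param tol,maxit CG controls.
#' @return A [scalar_map()] of the unit-drive potential (volts).
#' @export
solve_potential <- function(grid, sigma_field, electrode, tol = 1e-8,
                            maxit = 5000) {
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$shape - 0.5) * grid$spacing
  p1 <- electrode$tip_position
  p0 <- p1 - electrode$active_length * electrode$direction
  if (any(p1 < lo | p1 > hi | p0 < lo | p0 > hi))
    stop("electrode active tip lies outside the simulation domain")
  tip <- electrode_tip_voxels(grid, electrode)
  bnd <- boundary_mask_array(grid$shape)
  if (any(tip & bnd)) stop("electrode active tip touches the domain boundary")
  fixed <- tip | bnd
  fv <- array(0, grid$shape)
  fv[tip] <- 1
  theta <- electrode_theta(grid, electrode, tip)
  v <- solve_laplace_dirichlet(grid, sigma_field, fixed, fv, rhs = 0,
                               tol = tol, maxit = maxit, theta = theta)
  v$units <- "V"
  attr(v, "tip_mask") <- tip
  attr(v, "theta") <- theta
  v
}

#' Joule heating power density
#'
#' `q = sigma |grad(V_applied)|^2` (W/m^3) computed by attributing each
#' face's dissipation `sigma_f (dV/h)^2` half to each adjacent voxel, which
#' makes the discrete volume integral of `q` equal the discrete boundary
#' flux (exact energy bookkeeping).  Scales with the square of the applied
#' voltage.
#'
#' @param potential unit-drive potential from [solve_potential()].
#' @param sigma_field conductivity, scalar or [scalar_map()] (S/m).
#' @param applied_volts applied electrode voltage (V).
#' @return A [scalar_map()] of power density, W/m^3.
#' @export
power_density <- function(potential, sigma_field, applied_volts = 1,
                          tip = NULL, theta = NULL) {
  g <- potential$grid
  V <- potential$values * applied_volts
  sig <- if (inherits(sigma_field, "scalar_map")) sigma_field$values
         else array(sigma_field, g$shape)
  h <- g$spacing * 1e-3
  n_tot <- prod(g$shape)
  if (is.null(tip)) tip <- attr(potential, "tip_mask")
  if (is.null(theta)) theta <- attr(potential, "theta")
  use_theta <- !is.null(tip) && !is.null(theta)
  q <- array(0, g$shape)
  for (a in 1:3) {
    n <- g$shape[a]
    if (n < 2) next
    idx_lo <- lapply(g$shape, seq_len); idx_lo[[a]] <- 1:(n - 1)
    idx_hi <- lapply(g$shape, seq_len); idx_hi[[a]] <- 2:n
    Vlo <- do.call(`[`, c(list(V), idx_lo))
    Vhi <- do.call(`[`, c(list(V), idx_hi))
    slo <- do.call(`[`, c(list(sig), idx_lo))
    shi <- do.call(`[`, c(list(sig), idx_hi))
    sf <- ifelse(slo + shi > 0, 2 * slo * shi / (slo + shi), 0)
    e <- sf * ((Vhi - Vlo) / h[a])^2
    wl <- wh <- e * 0 + 0.5 # attribution weights
    if (use_theta) {
      tlo <- do.call(`[`, c(list(tip), idx_lo))
      thi <- do.call(`[`, c(list(tip), idx_hi))
      # faces inside the electrode dissipate nothing; faces crossing its
      # surface dissipate over the tissue gap theta*h, attributed to the
      # free voxel
      e[tlo & thi] <- 0
      th_arr <- array(1, dim(e))
      # free lower voxel, electrode upper neighbour: face direction +axis
      lin_lo <- which(!tlo & thi)
      if (length(lin_lo)) {
        flat <- do.call(`[`, c(list(array(seq_len(n_tot), g$shape)), idx_lo))
        th <- theta[flat[lin_lo] + n_tot * (2 * a - 1)]
        e[lin_lo] <- e[lin_lo] / th
        wl[lin_lo] <- 1; wh[lin_lo] <- 0
      }
      # electrode lower voxel, free upper neighbour: direction -axis
      lin_hi <- which(tlo & !thi)
      if (length(lin_hi)) {
        flat <- do.call(`[`, c(list(array(seq_len(n_tot), g$shape)), idx_hi))
        th <- theta[flat[lin_hi] + n_tot * (2 * a - 2)]
        e[lin_hi] <- e[lin_hi] / th
        wl[lin_hi] <- 0; wh[lin_hi] <- 1
      }
    }
    ql <- do.call(`[`, c(list(q), idx_lo)) + e * wl
    q <- do.call(`[<-`, c(list(q), idx_lo, list(ql)))
    qh <- do.call(`[`, c(list(q), idx_hi)) + e * wh
    q <- do.call(`[<-`, c(list(q), idx_hi, list(qh)))
  }
  scalar_map(q, g, units = "W/m^3")
}

#' One bioheat time step
#'
#' Advances the Pennes bioheat equation
#' `rho c dT/dt = div(k grad T) + w_b c_b (T_a - T) + q`
#' by one unconditionally stable operator-split step: the perfusion/source
#' term is relaxed exactly per voxel, then conduction is solved implicitly
#' by dimensional-split tridiagonal sweeps.  Setting `k = 0` in the tissue
#' properties disables conduction (useful for perfusion-only analyses).
#'
#' @param temperature a [scalar_map()] of temperatures, degC.
#' @param q a [scalar_map()] (or scalar) volumetric source, W/m^3.
#' @param tissue a [tissue_properties()] object.
#' @param w_b perfusion field, m^3/m^3/s: scalar or [scalar_map()]
#'   (defaults to the tissue baseline).
#' @param dt time step, s (> 0).
#' @param fixed logical array of pinned (Dirichlet) voxels; defaults to the
#'   domain boundary.
#' @param fixed_values pinned temperatures (array or scalar, default 37).
#' @return A [scalar_map()] of updated temperatures.
#' @export
step_bioheat <- function(temperature, q, tissue, w_b = NULL, dt,
                         fixed = NULL, fixed_values = 37, theta = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  g <- temperature$grid
  n <- prod(g$shape)
  qv <- if (inherits(q, "scalar_map")) as.numeric(q$values)
        else as.numeric(q)
  wv <- if (is.null(w_b)) tissue$w_b_nc
        else if (inherits(w_b, "scalar_map")) as.numeric(w_b$values)
        else as.numeric(w_b)
  fx <- if (is.null(fixed)) boundary_mask_array(g$shape) else as.logical(fixed)
  fv <- rep_len(as.numeric(fixed_values), n)
  out <- cpp_bioheat_step(as.numeric(temperature$values), qv, fx, fv, wv,
                          g$shape, g$spacing * 1e-3, tissue$rho, tissue$c,
                          tissue$k, tissue$c_b, tissue$T_a, dt,
                          theta %||% numeric(0))
  if (any(!is.finite(out)))
    stop("non-finite temperatures after bioheat step; aborting")
  scalar_map(out, g, units = "degC")
}

#' Simulate a water-cooled RF ablation
#'
#' Runs the coupled electro-thermal model for one electrode placement: the
#' quasi-static potential is solved once for a unit drive (conductivity is
#' temperature-independent, so the field shape is fixed and only the applied
#' voltage varies), then the bioheat equation is stepped with a
#' proportional-derivative feedback controller that modulates the applied
#' voltage to keep the hottest tissue node below `temp_cap`.  Per step, the
#' vascular Arrhenius integral updates the coagulated fraction `C_f` and
#' perfusion `w_b = w_b_nc (1 - C_f)`, and the cell-death Arrhenius integral
#' accumulates.  All nodes start at 37 degC; the block boundary is held at
#' 37 degC and the active tip at the coolant temperature.
#'
#' @param electrode an [electrode_spec()].
#' @param tissue a preset name or [tissue_properties()] object.
#' @param config a [simulation_config()].
#' @return An object of class `ablation_result` with fields
#'   `final_temperature`, `omega_map` (cell death), `coagulation_map`
#'   (`C_f`), `kill_mask_fine`, `applied_voltage_trace` (data frame of
#'   time/volts/hottest temperature), `kill_volume_trace` (cm^3 vs time),
#'   `snapshots` (kill masks at requested times), `grid`, `electrode`,
#'   `tissue` and `config`.
#' @export
simulate_ablation <- function(electrode, tissue = "normal_liver",
                              config = simulation_config()) {
  if (is.character(tissue)) tissue <- tissue_properties(tissue)
  # domain centred on the active-tip midpoint, axis-aligned
  mid <- electrode$tip_position - electrode$active_length / 2 *
    electrode$direction
  shape <- pmax(3L, as.integer(round(config$domain_size / config$grid_spacing)))
  origin <- mid - (shape - 1) / 2 * config$grid_spacing
  grid <- voxel_grid(shape, config$grid_spacing, origin)

  vunit <- solve_potential(grid, tissue$sigma, electrode)
  tip <- attr(vunit, "tip_mask")
  theta <- attr(vunit, "theta")
  qunit <- power_density(vunit, tissue$sigma, applied_volts = 1,
                         tip = tip, theta = theta)

  bnd <- boundary_mask_array(shape)
  fixed <- bnd | tip
  fv <- array(config$boundary_temp, shape)
  fv[tip] <- electrode$coolant_temp

  dt <- config$time_step
  nsteps <- as.integer(ceiling(config$duration / dt))
  snap_steps <- integer(0)
  if (!is.null(config$snapshot_times))
    snap_steps <- pmin(as.integer(ceiling(config$snapshot_times / dt)),
                       nsteps)
  pc <- arrhenius_params("cell_death")
  pv <- arrhenius_params("vascular")
  res <- cpp_ablation_run(
    grid$shape, grid$spacing * 1e-3, as.numeric(qunit$values),
    as.logical(fixed), as.numeric(fv), tissue$w_b_nc, tissue$rho, tissue$c,
    tissue$k, tissue$c_b, tissue$T_a, dt, nsteps, config$temp_cap,
    config$temp_cap - config$setpoint_margin, config$kp, config$ki,
    config$lead_s, config$v0, config$vmax, pc$log_A, pc$Ea, pv$log_A, pv$Ea,
    config$omega_threshold, config$coagulation, snap_steps, theta)
  if (isTRUE(res$overshoot))
    stop(sprintf(paste0("feedback controller overshoot: hottest tissue node ",
                        "reached %.2f degC (> cap %.1f + 0.5) at t = %.1f s"),
                 max(res$t_hot[seq_len(res$steps_done)]), config$temp_cap,
                 res$steps_done * dt))
  omega <- scalar_map(res$omega_cell, grid, units = "Omega")
  snaps <- lapply(res$snapshots, function(m)
    label_mask(array(m, grid$shape), grid))
  structure(list(
    final_temperature = scalar_map(res$temperature, grid, units = "degC"),
    omega_map = omega,
    coagulation_map = scalar_map(1 - exp(-res$omega_vascular), grid,
                                 units = "C_f"),
    kill_mask_fine = kill_mask(omega, config$omega_threshold),
    applied_voltage_trace = data.frame(
      time_s = seq_len(nsteps) * dt,
      volts = as.numeric(res$volts)[seq_len(nsteps)],
      t_hot = as.numeric(res$t_hot)[seq_len(nsteps)]),
    kill_volume_trace = data.frame(
      time_s = seq_len(nsteps) * dt,
      volume_cm3 = as.numeric(res$kill_count)[seq_len(nsteps)] *
        voxel_volume(grid) / 1000),
    snapshots = snaps,
    snapshot_times = if (length(snap_steps)) snap_steps * dt else numeric(0),
    grid = grid, electrode = electrode, tissue = tissue, config = config),
    class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  kv <- mask_volume(x$kill_mask_fine)
  tmax <- if (nrow(x$applied_voltage_trace)) max(x$applied_voltage_trace$t_hot)
          else 37
  cat(sprintf(paste0("<ablation_result> %s, %.0f s: kill volume %.2f cm^3, ",
                     "peak tissue temperature %.1f degC\n"),
              x$tissue$preset, x$config$duration, kv, tmax))
  invisible(x)
}

#' @export
plot.ablation_result <- function(x, ...) {
  g <- x$grid
  k <- ceiling(g$shape[3] / 2)
  image(voxel_centers(g, 1), voxel_centers(g, 2),
        x$final_temperature$values[, , k],
        xlab = "x (mm)", ylab = "y (mm)",
        main = "Final temperature, central slice (degC)", ...)
  contour(voxel_centers(g, 1), voxel_centers(g, 2),
          x$omega_map$values[, , k], levels = x$config$omega_threshold,
          add = TRUE, lwd = 2, drawlabels = FALSE)
  invisible(x)
}

#' Predicted ablation zone on the dose grid
#'
#' Rebins the fine-grid kill region (cell-death Omega at or above the
#' threshold) onto the coarse dosimetry grid via
#' [rebin_fine_to_coarse()].
#'
#' @param result an [simulate_ablation()] result.
#' @param dose_grid target [voxel_grid()].
#' @param occupancy occupancy fraction for the rebinning (default 0.5).
#' @return A [label_mask()] on `dose_grid`.
#' @export
ablation_zone_on_grid <- function(result, dose_grid, occupancy = 0.5) {
  rebin_fine_to_coarse(result$omega_map, dose_grid,
                       value_threshold = result$config$omega_threshold,
                       occupancy = occupancy)
}

#' Read an ablation scenario from a flat YAML file
#'
#' A scenario file carries one electrode pose and the simulation settings,
#' e.g.:
#'
#' ```yaml
#' tissue: hcc
#' tip_mm: [0, 0, 15]
#' direction: [0, 0, 1]
#' duration_s: 600
#' grid_spacing_mm: 1.0
#' domain_mm: 100
#' time_step_s: 0.5
#' coolant_temp_c: 25
#' ```
#'
#' Omitted keys fall back to the [electrode_spec()] and
#' [simulation_config()] defaults.
#'
#' @param path YAML file path.
#' @return A list with `electrode`, `tissue` (preset name) and `config`,
#'   ready for [simulate_ablation()].
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  el <- electrode_spec(
    tip_position = as.numeric(sc$tip_mm %||% c(0, 0, 15)),
    direction = as.numeric(sc$direction %||% c(0, 0, 1)),
    active_length = sc$active_length_mm %||% 30,
    coolant_temp = sc$coolant_temp_c %||% 25)
  cfg <- simulation_config(
    domain_size = rep_len(as.numeric(sc$domain_mm %||% 100), 3),
    grid_spacing = sc$grid_spacing_mm %||% 1.0,
    time_step = sc$time_step_s %||% 0.5,
    duration = sc$duration_s %||% 600)
  list(electrode = el, tissue = sc$tissue %||% "normal_liver", config = cfg)
}
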