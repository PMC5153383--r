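#' Electrode placement and ablation plan containers
#'
#' An `electrode_placement` pairs an [electrode_spec()] with an ablation
#' duration (0 < duration <= 600 s per site).  An `ablation_plan` holds 1-4
#' placements plus patient/tumor identifiers.
#'
#' @param electrode an [electrode_spec()].
#' @param duration ablation time at this site, s.
#' @return An `electrode_placement`.
#' @export
electrode_placement <- function(electrode, duration) {
  if (duration <= 0 || duration > 600)
    stop("duration must be in (0, 600] s")
  structure(list(electrode = electrode, duration = duration),
            class = "electrode_placement")
}

#' @rdname electrode_placement
#' @param placements list of `electrode_placement`s (1 to 4).
#' @param patient_id,tumor_id identifiers.
#' @export
ablation_plan <- function(placements, patient_id = NA, tumor_id = NA) {
  if (length(placements) < 1 || length(placements) > 4)
    stop("a plan must have between 1 and 4 electrode placements")
  stopifnot(all(vapply(placements, inherits, logical(1),
                       "electrode_placement")))
  structure(list(placements = placements, patient_id = patient_id,
                 tumor_id = tumor_id),
            class = "ablation_plan")
}

#' @export
print.ablation_plan <- function(x, ...) {
  cat(sprintf("<ablation_plan> %d placement(s), durations %s s\n",
              length(x$placements),
              paste(vapply(x$placements, function(p) p$duration, numeric(1)),
                    collapse = "/")))
  invisible(x)
}

#' Planning safety constraints
#'
#' @param target_isodose the ablation zone should stay within tumor below
#'   this dose where possible (Gy, soft constraint).
#' @param gi_margin minimum allowed distance from the ablation-zone
#'   boundary to gastrointestinal tissue, mm (hard constraint).
#' @param spare_masks named list of [label_mask()]s of organs to spare
#'   (e.g. `capsule`, `gallbladder`, `gi`); any overlap is a violation.
#' @param gi_names names within `spare_masks` treated as gastrointestinal
#'   (subject to `gi_margin`).
#' @return A `plan_constraints` object.
#' @export
plan_constraints <- function(target_isodose = 100, gi_margin = 10,
                             spare_masks = list(), gi_names = "gi") {
  if (gi_margin < 0) stop("margins must be >= 0")
  structure(list(target_isodose = target_isodose, gi_margin = gi_margin,
                 spare_masks = spare_masks, gi_names = gi_names),
            class = "plan_constraints")
}

mask_surface_coords <- function(mask) {
  m <- mask$membership
  shp <- mask$grid$shape
  interior <- array(TRUE, shp)
  shift_and <- function(acc, axis, dir) {
    idx_src <- lapply(shp, seq_len)
    idx_dst <- lapply(shp, seq_len)
    n <- shp[axis]
    if (dir > 0) { idx_src[[axis]] <- c(1L, seq_len(n - 1L)) }
    else { idx_src[[axis]] <- c(seq_len(n - 1L) + 1L, n) }
    nb <- do.call(`[`, c(list(m), idx_src))
    # voxels at the array edge count as surface
    edge <- array(FALSE, shp)
    if (dir > 0) { idx_e <- lapply(shp, seq_len); idx_e[[axis]] <- 1L }
    else { idx_e <- lapply(shp, seq_len); idx_e[[axis]] <- n }
    edge <- do.call(`[<-`, c(list(edge), idx_e, list(TRUE)))
    acc & (nb | edge) & !edge
  }
  for (a in 1:3) for (d in c(-1, 1)) interior <- shift_and(interior, a, d)
  surf <- m & !interior
  idx <- which(surf, arr.ind = TRUE)
  cbind(mask$grid$origin[1] + (idx[, 1] - 1) * mask$grid$spacing[1],
        mask$grid$origin[2] + (idx[, 2] - 1) * mask$grid$spacing[2],
        mask$grid$origin[3] + (idx[, 3] - 1) * mask$grid$spacing[3])
}

#' Minimum surface-to-surface distance between two masks
#'
#' Euclidean distance (mm) between the surface voxel centres of two masks;
#' 0 if they overlap.
#'
#' @param a,b [label_mask()]s on a common grid.
#' @return Distance in mm.
#' @export
mask_distance <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid)
  if (sum(a$membership) == 0 || sum(b$membership) == 0) return(Inf)
  if (any(a$membership & b$membership)) return(0)
  cpp_min_dist(mask_surface_coords(a), mask_surface_coords(b))
}

#' Under-dosed (cold) tumor regions
#'
#' Connected components (6-connectivity) of tumor voxels receiving less
#' than `level` Gy, filtered to those whose minimum bounding-box edge is at
#' least `min_diameter` mm, sorted largest-first by volume.  These are the
#' candidate targets for adjuvant ablation.
#'
#' @param dose a [scalar_map()] in Gy.
#' @param tumor a non-empty [label_mask()].
#' @param level dose threshold, Gy (default 100).
#' @param min_diameter minimum bounding-box edge, mm (default 20).
#' @return A (possibly empty) list of [label_mask()]s.
#' @export
cold_regions <- function(dose, tumor, level = 100, min_diameter = 20) {
  stop_if_grid_mismatch(dose$grid, tumor$grid)
  if (sum(tumor$membership) == 0) stop("tumor mask is empty")
  cold <- tumor$membership & (dose$values < level)
  if (!any(cold)) return(list())
  lab <- array(cpp_label_components(as.logical(cold), dose$grid$shape),
               dose$grid$shape)
  out <- list()
  for (l in seq_len(max(lab))) {
    sel <- lab == l
    idx <- which(sel, arr.ind = TRUE)
    ext <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * dose$grid$spacing
    if (min(ext) >= min_diameter)
      out[[length(out) + 1]] <- label_mask(sel, dose$grid)
  }
  if (length(out) == 0) return(list())
  out[order(vapply(out, mask_volume, numeric(1)), decreasing = TRUE)]
}

#' Validate an ablation plan against safety constraints
#'
#' Reports, per placement: the fraction of the predicted zone outside the
#' tumor, the fraction of the zone over voxels at or above the target
#' isodose (a soft warning: ablating already well-treated tumor is wasteful
#' but not unsafe), the minimum distance from the zone to each spare organ,
#' any overlap with spare organs (hard violation), and a hard violation when
#' the zone comes within `gi_margin` of gastrointestinal tissue.
#'
#' @param plan an [ablation_plan()].
#' @param predicted_zones list of [label_mask()]s on the dose grid, one per
#'   placement.
#' @param dose [scalar_map()] in Gy.
#' @param tumor tumor [label_mask()].
#' @param constraints a [plan_constraints()].
#' @return A `plan_report`: per-placement list with elements
#'   `zone_volume_cm3`, `frac_outside_tumor`, `frac_over_isodose`,
#'   `organ_distance_mm`, `violations` (character), `warnings` (character);
#'   plus `ok` (no hard violations anywhere).
#' @export
validate_plan <- function(plan, predicted_zones, dose, tumor, constraints) {
  if (length(predicted_zones) != length(plan$placements))
    stop("one predicted zone per placement is required")
  reports <- vector("list", length(predicted_zones))
  for (i in seq_along(predicted_zones)) {
    zone <- predicted_zones[[i]]
    stop_if_grid_mismatch(zone$grid, dose$grid)
    stop_if_grid_mismatch(zone$grid, tumor$grid)
    nz <- sum(zone$membership)
    frac_out <- if (nz) sum(zone$membership & !tumor$membership) / nz else 0
    frac_hot <- if (nz)
      sum(zone$membership & dose$values >= constraints$target_isodose) / nz
      else 0
    viol <- character(0)
    warns <- character(0)
    dists <- numeric(0)
    for (nm in names(constraints$spare_masks)) {
      org <- constraints$spare_masks[[nm]]
      d <- mask_distance(zone, org)
      dists[nm] <- d
      if (d == 0)
        viol <- c(viol, sprintf("zone overlaps spare tissue '%s'", nm))
      else if (nm %in% constraints$gi_names && d < constraints$gi_margin)
        viol <- c(viol, sprintf(
          "zone boundary %.1f mm from gastrointestinal tissue '%s' (< %.0f mm margin)",
          d, nm, constraints$gi_margin))
    }
    if (frac_hot > 0)
      warns <- c(warns, sprintf(
        "%.0f%% of zone lies over tumor already receiving >= %.0f Gy",
        100 * frac_hot, constraints$target_isodose))
    reports[[i]] <- list(zone_volume_cm3 = mask_volume(zone),
                         frac_outside_tumor = frac_out,
                         frac_over_isodose = frac_hot,
                         organ_distance_mm = dists,
                         violations = viol, warnings = warns)
  }
  structure(list(placements = reports,
                 ok = !any(vapply(reports, function(r)
                   length(r$violations) > 0, logical(1)))),
            class = "plan_report")
}

#' @export
print.plan_report <- function(x, ...) {
  cat(sprintf("<plan_report> %d placement(s), %s\n", length(x$placements),
              if (x$ok) "no hard violations" else "HARD VIOLATIONS"))
  for (i in seq_along(x$placements)) {
    r <- x$placements[[i]]
    cat(sprintf("  [%d] zone %.1f cm^3, %.0f%% outside tumor, %.0f%% over isodose\n",
                i, r$zone_volume_cm3, 100 * r$frac_outside_tumor,
                100 * r$frac_over_isodose))
    for (v in r$violations) cat("      violation: ", v, "\n", sep = "")
    for (w in r$warnings) cat("      warning: ", w, "\n", sep = "")
  }
  invisible(x)
}

#' Centroid of a mask in world coordinates
#'
#' @param mask a non-empty [label_mask()].
#' @return Numeric length-3 vector, mm.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask$membership, arr.ind = TRUE)
  g <- mask$grid
  c(g$origin[1] + (mean(idx[, 1]) - 1) * g$spacing[1],
    g$origin[2] + (mean(idx[, 2]) - 1) * g$spacing[2],
    g$origin[3] + (mean(idx[, 3]) - 1) * g$spacing[3])
}

default_path_directions <- function() {
  d <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 1), c(1, -1, 1), c(-1, 1, 1), c(-1, -1, 1))
  d / sqrt(rowSums(d^2))
}

#' Greedy automatic electrode planning
#'
#' A convenience heuristic, not part of the validated clinical workflow
#' (plans can always be supplied manually, mirroring physician-selected
#' placements): up to `max_sites` iterations take the largest cold region
#' not yet served, place the electrode through its centroid along the
#' candidate straight path whose predicted 600-s zone incurs the fewest
#' constraint violations (ties broken by soft score, then candidate order),
#' then choose the longest duration whose predicted zone passes
#' [validate_plan()].  Deterministic given its inputs.
#'
#' @param dose [scalar_map()] in Gy.
#' @param tumor tumor [label_mask()].
#' @param constraints a [plan_constraints()].
#' @param simulate_fn function `(electrode, duration) -> label_mask` on the
#'   dose grid predicting the ablation zone (see
#'   [make_zone_predictor()]).
#' @param level,min_diameter cold-region definition, passed to
#'   [cold_regions()].
#' @param durations candidate durations, s (descending trial order).
#' @param directions matrix of candidate unit insertion directions (rows).
#' @param active_length,coolant_temp electrode geometry passed to
#'   [electrode_spec()].
#' @param max_sites maximum number of placements (<= 4).
#' @return A list with `plan` (an [ablation_plan()] or `NULL`), `zones`
#'   (predicted zone per placement) and `reasons` (character log).
#' @export
auto_plan <- function(dose, tumor, constraints, simulate_fn,
                      level = 100, min_diameter = 20,
                      durations = c(600, 480, 360, 240, 120),
                      directions = default_path_directions(),
                      active_length = 30, coolant_temp = 25,
                      max_sites = 4) {
  stopifnot(max_sites >= 1, max_sites <= 4)
  regions <- cold_regions(dose, tumor, level, min_diameter)
  reasons <- character(0)
  if (length(regions) == 0)
    return(list(plan = NULL, zones = list(),
                reasons = "no cold regions to target"))
  served <- label_mask(array(FALSE, dose$grid$shape), dose$grid)
  placements <- list()
  zones <- list()
  for (reg in regions) {
    if (length(placements) >= max_sites) break
    unserved <- mask_difference(reg, served)
    if (mask_volume(unserved) < 0.5 * mask_volume(reg)) next
    ctr <- mask_centroid(unserved)
    best <- NULL
    for (di in seq_len(nrow(directions))) {
      dir <- directions[di, ]
      el <- electrode_spec(tip_position = ctr + active_length / 2 * dir,
                           direction = dir, active_length = active_length,
                           coolant_temp = coolant_temp)
      zone <- try(simulate_fn(el, max(durations)), silent = TRUE)
      if (inherits(zone, "try-error")) next
      rep1 <- validate_plan(
        ablation_plan(list(electrode_placement(el, max(durations)))),
        list(zone), dose, tumor, constraints)
      r <- rep1$placements[[1]]
      score <- c(length(r$violations),
                 r$frac_over_isodose + r$frac_outside_tumor)
      if (is.null(best) || score[1] < best$score[1] ||
          (score[1] == best$score[1] && score[2] < best$score[2] - 1e-12)) {
        best <- list(el = el, score = score)
      }
    }
    if (is.null(best)) {
      reasons <- c(reasons, "no feasible path simulated for a cold region")
      next
    }
    chosen <- NULL
    for (dur in durations) {
      zone <- simulate_fn(best$el, dur)
      rep1 <- validate_plan(
        ablation_plan(list(electrode_placement(best$el, dur))),
        list(zone), dose, tumor, constraints)
      if (rep1$ok) { chosen <- list(dur = dur, zone = zone); break }
    }
    if (is.null(chosen)) {
      reasons <- c(reasons,
                   "no duration satisfied the constraints for a cold region")
      next
    }
    placements[[length(placements) + 1]] <-
      electrode_placement(best$el, chosen$dur)
    zones[[length(zones) + 1]] <- chosen$zone
    served <- mask_union(served, chosen$zone)
  }
  if (length(placements) == 0)
    return(list(plan = NULL, zones = list(),
                reasons = c(reasons, "no feasible placement")))
  list(plan = ablation_plan(placements), zones = zones, reasons = reasons)
}

#' Zone predictor backed by the bioheat simulator
#'
#' Returns a `(electrode, duration) -> label_mask` closure for
#' [auto_plan()] and [run_case()], running [simulate_ablation()] on
#' `sim_config` (with the requested duration) and rebinning the kill mask
#' onto `dose_grid`.  Results are cached per electrode pose using duration
#' snapshots, so trying several durations for one pose costs one
#' simulation.
#'
#' @param tissue preset name or [tissue_properties()].
#' @param sim_config a [simulation_config()].
#' @param dose_grid target [voxel_grid()].
#' @param durations durations (s) to snapshot for caching.
#' @return A function `(electrode, duration) -> label_mask`.
#' @export
make_zone_predictor <- function(tissue, sim_config, dose_grid,
                                durations = c(600, 480, 360, 240, 120)) {
  cache <- new.env(parent = emptyenv())
  durations <- sort(unique(durations))
  function(electrode, duration) {
    key <- paste(c(electrode$tip_position, electrode$direction,
                   electrode$active_length), collapse = "|")
    if (!exists(key, envir = cache)) {
      cfg <- sim_config
      cfg$duration <- max(durations)
      cfg$snapshot_times <- durations
      res <- simulate_ablation(electrode, tissue, cfg)
      zl <- lapply(res$snapshots, function(m)
        rebin_fine_to_coarse(m, dose_grid, occupancy = 0.5))
      assign(key, list(times = res$snapshot_times, zones = zl), envir = cache)
    }
    entry <- get(key, envir = cache)
    i <- which.min(abs(entry$times - duration))
    entry$zones[[i]]
  }
}

#' Read or write ablation plans as JSON
#'
#' Plans are stored as a JSON array of
#' `{tip_mm: [x,y,z], direction: [x,y,z], duration_s: t}` records.
#'
#' @param path JSON file path.
#' @param active_length,coolant_temp electrode defaults applied on read.
#' @return [read_plan()]: an [ablation_plan()]; [write_plan()]: `path`.
#' @export
read_plan <- function(path, active_length = 30, coolant_temp = 25) {
  rec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  placements <- lapply(rec, function(r)
    electrode_placement(
      electrode_spec(tip_position = as.numeric(r$tip_mm),
                     direction = as.numeric(r$direction),
                     active_length = active_length,
                     coolant_temp = coolant_temp),
      duration = r$duration_s))
  ablation_plan(placements)
}

#' @rdname read_plan
#' @param plan an [ablation_plan()].
#' @export
write_plan <- function(plan, path) {
  rec <- lapply(plan$placements, function(p)
    list(tip_mm = p$electrode$tip_position,
         direction = p$electrode$direction,
         duration_s = p$duration))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
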