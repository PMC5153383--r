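#' Local-deposition-method physics constants
#'
#' The local deposition method (LDM) assumes each voxel's absorbed dose comes
#' from the beta energy emitted by the activity within that voxel, so dose is
#' proportional to the local activity concentration:
#' `dose [Gy] = gy_per_gbq_per_kg * A [GBq] / m [kg]`.  The default
#' 49.67 Gy.kg/GBq is the closed-form committed dose per unit activity
#' concentration for Y-90 (mean beta energy 0.9267 MeV, half-life 64.05 h,
#' full local absorption).  Density defaults to soft-tissue liver
#' (1060 kg/m^3).
#'
#' @param gy_per_gbq_per_kg dose per activity concentration, Gy.kg/GBq.
#' @param tissue_density kg/m^3.
#' @param half_life physical half-life, hours.
#' @return An object of class `ldm_constants`.
#' @export
ldm_constants <- function(gy_per_gbq_per_kg = 49.67, tissue_density = 1060,
                          half_life = 64.05) {
  stopifnot(gy_per_gbq_per_kg > 0, tissue_density > 0, half_life > 0)
  structure(list(gy_per_gbq_per_kg = gy_per_gbq_per_kg,
                 tissue_density = tissue_density, half_life = half_life),
            class = "ldm_constants")
}

#' Voxel absorbed-dose map by the local deposition method
#'
#' @param activity a [scalar_map()] of activity in Bq per voxel
#'   (non-negative).
#' @param constants an [ldm_constants()] object.
#' @return A [scalar_map()] of absorbed dose in Gy.
#' @export
ldm_dose <- function(activity, constants = ldm_constants()) {
  if (any(activity$values < 0)) stop("activity must be non-negative")
  vox_m3 <- voxel_volume(activity$grid) * 1e-9 # mm^3 -> m^3
  vox_kg <- constants$tissue_density * vox_m3
  gbq <- activity$values * 1e-9
  scalar_map(constants$gy_per_gbq_per_kg * gbq / vox_kg, activity$grid,
             units = "Gy")
}

#' Tumor dose metrics
#'
#' Computes the mean (`d_avg`) and maximum dose, the minimum dose to 50, 70
#' and 90% of the structure volume (`d50`, `d70`, `d90`), and the percentage
#' of volume receiving more than 100 Gy (`v100`) over a mask.  Dxx is the
#' dose of the voxel at rank `ceiling(xx% * N)` in descending order (no
#' interpolation); V100 counts voxels with dose strictly above 100 Gy.
#'
#' @param dose a [scalar_map()] in Gy.
#' @param mask a non-empty [label_mask()] on the same grid.
#' @return An object of class `dose_metrics` with fields `d_avg`, `d_max`,
#'   `d50`, `d70`, `d90`, `v100` and `n_voxels`.
#' @export
dose_metrics <- function(dose, mask) {
  stop_if_grid_mismatch(dose$grid, mask$grid)
  d <- dose$values[mask$membership]
  if (length(d) == 0) stop("no voxels in mask")
  ds <- sort(d, decreasing = TRUE)
  n <- length(ds)
  dxx <- function(xx) ds[ceiling(xx / 100 * n)]
  structure(list(d_avg = mean(d), d_max = ds[1],
                 d50 = dxx(50), d70 = dxx(70), d90 = dxx(90),
                 v100 = 100 * sum(d > 100) / n, n_voxels = n),
            class = "dose_metrics")
}

#' @export
print.dose_metrics <- function(x, ...) {
  cat(sprintf(paste0("<dose_metrics> Davg %.1f Gy | Dmax %.1f | D50 %.1f | ",
                     "D70 %.1f | D90 %.1f Gy | V100 %.1f%% (%d voxels)\n"),
              x$d_avg, x$d_max, x$d50, x$d70, x$d90, x$v100, x$n_voxels))
  invisible(x)
}

#' @export
as.data.frame.dose_metrics <- function(x, ...) {
  data.frame(d_avg = x$d_avg, d_max = x$d_max, d50 = x$d50, d70 = x$d70,
             d90 = x$d90, v100 = x$v100)
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure volume receiving at least each dose edge,
#' starting at 100% at 0 Gy.
#'
#' @param dose a [scalar_map()] in Gy.
#' @param mask a non-empty [label_mask()].
#' @param bin_width histogram bin width in Gy (> 0).
#' @return An object of class `dvh`: a data frame with columns `dose_gy`
#'   (ascending edges) and `volume_pct` (non-increasing, first entry 100).
#' @export
dvh <- function(dose, mask, bin_width = 1) {
  stop_if_grid_mismatch(dose$grid, mask$grid)
  if (bin_width <= 0) stop("bin_width must be > 0")
  d <- dose$values[mask$membership]
  if (length(d) == 0) stop("no voxels in mask")
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  pct <- vapply(edges, function(e) 100 * mean(d >= e), numeric(1))
  structure(data.frame(dose_gy = edges, volume_pct = pct),
            class = c("dvh", "data.frame"))
}

#' @export
plot.dvh <- function(x, ...) {
  plot(x$dose_gy, x$volume_pct, type = "s", xlab = "Dose (Gy)",
       ylab = "Volume (%)", ylim = c(0, 100), ...)
  invisible(x)
}

#' Device-specific eligibility for adjuvant ablation
#'
#' A tumor qualifies when its D70 falls below the device-specific threshold:
#' strictly below 100 Gy for resin microspheres, strictly below 150 Gy for
#' glass.
#'
#' @param metrics a [dose_metrics()] object.
#' @param device `"resin"` or `"glass"`.
#' @return Logical.
#' @export
eligibility <- function(metrics, device) {
  if (!device %in% c("resin", "glass"))
    stop("unknown device label: ", device)
  metrics$d70 < if (device == "resin") 100 else 150
}

#' Isodose mask
#'
#' @param dose a [scalar_map()] in Gy.
#' @param level dose level in Gy (>= 0); voxels with dose >= `level` are set.
#' @return A [label_mask()].
#' @export
isodose_mask <- function(dose, level) {
  if (level < 0) stop("level must be >= 0")
  label_mask(dose$values >= level, dose$grid)
}

#' Fraction of absorbed dose delivered by time t
#'
#' For a permanent implant with physical half-life `T1/2`, the fraction of
#' the committed dose delivered by `t` hours is `1 - exp(-ln(2) t / T1/2)`.
#'
#' @param t time since infusion in hours (>= 0).
#' @param constants an [ldm_constants()] (supplies the half-life).
#' @return Fraction in `[0, 1)`.
#' @export
dose_fraction_delivered <- function(t, constants = ldm_constants()) {
  if (any(t < 0)) stop("t must be >= 0")
  1 - exp(-log(2) * t / constants$half_life)
}

#' Export dose metrics to JSON or a DVH to CSV
#'
#' @param x a [dose_metrics()] or [dvh()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_dosimetry <- function(x, path) {
  if (inherits(x, "dose_metrics")) {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "dvh")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else stop("x must be a dose_metrics or dvh object")
  invisible(path)
}
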