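#' Per-tumor analysis case
#'
#' Bundles everything needed to analyse one tumor: the post-treatment
#' activity map, tumor and organ masks (all on one grid), the treatment
#' device, the tissue preset for ablation simulation, and optionally a
#' pre-specified ablation plan.
#'
#' @param id case identifier.
#' @param device `"resin"` or `"glass"`.
#' @param activity_map [scalar_map()] of Bq per voxel.
#' @param tumor_mask tumor [label_mask()] on the same grid.
#' @param organ_masks named list of organ-at-risk [label_mask()]s.
#' @param plan optional [ablation_plan()].
#' @param tissue tissue preset name or [tissue_properties()] (`"hcc"` for
#'   hepatocellular carcinoma, `"normal_liver"` otherwise).
#' @return A `tumor_case` object.
#' @export
tumor_case <- function(id, device, activity_map, tumor_mask,
                       organ_masks = list(), plan = NULL,
                       tissue = "normal_liver") {
  if (!device %in% c("resin", "glass"))
    stop("unknown device label: ", device)
  stop_if_grid_mismatch(activity_map$grid, tumor_mask$grid)
  for (m in organ_masks) stop_if_grid_mismatch(activity_map$grid, m$grid)
  structure(list(id = id, device = device, activity_map = activity_map,
                 tumor_mask = tumor_mask, organ_masks = organ_masks,
                 plan = plan, tissue = tissue),
            class = "tumor_case")
}

#' @export
print.tumor_case <- function(x, ...) {
  cat(sprintf(paste0("<tumor_case> '%s': %s device, tumor %.1f cm^3, ",
                     "activity %.2f GBq, tissue preset '%s'\n"),
              x$id, x$device, mask_volume(x$tumor_mask),
              sum(x$activity_map$values) * 1e-9,
              if (is.character(x$tissue)) x$tissue else x$tissue$preset))
  invisible(x)
}

#' Subtract ablation zones from a tumor mask
#'
#' `post = tumor AND NOT union(zones)`; overlapping zones are counted once.
#'
#' @param tumor tumor [label_mask()].
#' @param zones list of [label_mask()]s on the same grid.
#' @return A list with `post_mask` (the unablated tumor) and
#'   `ablated_in_tumor_volume` (cm^3 of tumor removed).
#' @export
apply_ablation <- function(tumor, zones) {
  u <- array(FALSE, tumor$grid$shape)
  for (z in zones) {
    stop_if_grid_mismatch(tumor$grid, z$grid)
    u <- u | z$membership
  }
  post <- label_mask(tumor$membership & !u, tumor$grid)
  list(post_mask = post,
       ablated_in_tumor_volume = mask_volume(tumor) - mask_volume(post))
}

#' Percentage tumor volume change from ablation
#'
#' `100 * (pre - post) / post`, the convention under which the per-tumor
#' table cells of the reference cohort reproduce exactly.
#'
#' @param pre,post volumes in cm^3 (`post > 0`).
#' @return Percent change.
#' @export
pct_volume_change <- function(pre, post) {
  if (any(post <= 0)) stop("post-ablation volume must be > 0")
  100 * (pre - post) / post
}

#' Pipeline configuration
#'
#' @param sim a [simulation_config()] used for per-placement ablation
#'   simulations (its `duration` is overridden by each placement).
#' @param constants [ldm_constants()] for dosimetry.
#' @param constraints [plan_constraints()]; organ masks from the case are
#'   merged in automatically.
#' @param auto_plan_if_missing run [auto_plan()] when the case carries no
#'   plan.
#' @param planner_durations candidate durations for the auto-planner, s.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            constants = ldm_constants(),
                            constraints = plan_constraints(),
                            auto_plan_if_missing = TRUE,
                            planner_durations = c(600, 480, 360, 240, 120)) {
  structure(list(sim = sim, constants = constants, constraints = constraints,
                 auto_plan_if_missing = auto_plan_if_missing,
                 planner_durations = planner_durations),
            class = "pipeline_config")
}

#' Run the full adjuvant-ablation analysis for one case
#'
#' Computes the local-deposition dose map once, obtains an ablation plan
#' (the case's own, or the greedy planner's), simulates each electrode
#' placement with the bioheat model, rebins the kill zones to the dose
#' grid, subtracts their union from the tumor mask, and recomputes all dose
#' metrics on the unablated tumor from the same dose map.
#'
#' @param case a [tumor_case()].
#' @param config a [pipeline_config()].
#' @return A `case_result`: pre/post [dose_metrics()], pre/post volumes and
#'   ablated volume (cm^3), percentage volume change, per-metric deltas and
#'   percent changes, the plan and predicted zones.
#' @export
run_case <- function(case, config = pipeline_config()) {
  dose <- ldm_dose(case$activity_map, config$constants)
  pre_metrics <- dose_metrics(dose, case$tumor_mask)
  constraints <- config$constraints
  constraints$spare_masks <- utils::modifyList(
    constraints$spare_masks, case$organ_masks)
  predictor <- make_zone_predictor(case$tissue, config$sim, dose$grid,
                                   durations = config$planner_durations)
  plan <- case$plan
  zones <- NULL
  if (is.null(plan) && config$auto_plan_if_missing) {
    ap <- auto_plan(dose, case$tumor_mask, constraints, predictor,
                    durations = config$planner_durations)
    plan <- ap$plan
    zones <- ap$zones
  }
  if (is.null(plan)) {
    post_metrics <- pre_metrics
    post_mask <- case$tumor_mask
    abl <- 0
    zones <- list()
    durations <- numeric(0)
  } else {
    if (is.null(zones))
      zones <- lapply(plan$placements, function(p)
        predictor(p$electrode, p$duration))
    ap2 <- apply_ablation(case$tumor_mask, zones)
    post_mask <- ap2$post_mask
    abl <- ap2$ablated_in_tumor_volume
    post_metrics <- if (sum(post_mask$membership) > 0)
      dose_metrics(dose, post_mask) else pre_metrics
    durations <- vapply(plan$placements, function(p) p$duration, numeric(1))
  }
  pre_v <- mask_volume(case$tumor_mask)
  post_v <- mask_volume(post_mask)
  mnames <- c("d_avg", "d_max", "d50", "d70", "d90", "v100")
  deltas <- vapply(mnames, function(m) post_metrics[[m]] - pre_metrics[[m]],
                   numeric(1))
  pcts <- vapply(mnames, function(m)
    if (pre_metrics[[m]] != 0)
      100 * (post_metrics[[m]] - pre_metrics[[m]]) / pre_metrics[[m]]
    else 0, numeric(1))
  structure(list(id = case$id, device = case$device,
                 pre_metrics = pre_metrics, post_metrics = post_metrics,
                 pre_volume = pre_v, post_volume = post_v,
                 ablated_in_tumor_volume = abl,
                 pct_volume_change = if (post_v > 0)
                   pct_volume_change(pre_v, post_v) else NA_real_,
                 n_sites = length(durations), durations = durations,
                 deltas = deltas, pct_changes = pcts,
                 plan = plan, zones = zones, dose_grid = dose$grid),
            class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf(paste0("<case_result> '%s': %d site(s); tumor %.1f -> %.1f ",
                     "cm^3 (%.1f%% change); dDavg %.1f Gy, dV100 %.1f pp\n"),
              x$id, x$n_sites, x$pre_volume, x$post_volume,
              ifelse(is.na(x$pct_volume_change), 0, x$pct_volume_change),
              x$deltas["d_avg"], x$deltas["v100"]))
  invisible(x)
}

#' Assemble per-tumor results into a cohort table
#'
#' One row per tumor: site count, durations, pre/post volumes, percentage
#' volume change, and pre/post metrics with their deltas.
#'
#' @param results list of `case_result`s (>= 1).
#' @return A `cohort_table` data frame.
#' @export
cohort_table <- function(results) {
  if (length(results) < 1) stop("at least one case result is required")
  rows <- lapply(results, function(r) {
    data.frame(id = as.character(r$id), n_sites = r$n_sites,
               ablation_times_s = paste(r$durations, collapse = "/"),
               pre_volume_cm3 = r$pre_volume, post_volume_cm3 = r$post_volume,
               pct_volume_change = r$pct_volume_change,
               pre_d_avg = r$pre_metrics$d_avg, post_d_avg = r$post_metrics$d_avg,
               pre_d_max = r$pre_metrics$d_max, post_d_max = r$post_metrics$d_max,
               pre_d50 = r$pre_metrics$d50, post_d50 = r$post_metrics$d50,
               pre_d70 = r$pre_metrics$d70, post_d70 = r$post_metrics$d70,
               pre_d90 = r$pre_metrics$d90, post_d90 = r$post_metrics$d90,
               pre_v100 = r$pre_metrics$v100, post_v100 = r$post_metrics$v100)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Cohort-level summary
#'
#' Works on any data frame with `n_sites`, `pre_volume_cm3` and
#' `post_volume_cm3` columns (e.g. a [cohort_table()] or the bundled
#' [example_cohort()]): total number of simulations (sum of site counts),
#' mean volume difference `mean(pre - post)`, and mean/SD of the percentage
#' volume change; plus mean/SD of each dose metric, delta and percent
#' change when metric columns are present.
#'
#' @param tab a data frame as above.
#' @return A list of summary statistics.
#' @export
cohort_summary <- function(tab) {
  pre <- tab$pre_volume_cm3
  post <- tab$post_volume_cm3
  pv <- pct_volume_change(pre, post)
  out <- list(n_tumors = nrow(tab),
              total_simulations = sum(tab$n_sites),
              mean_pre_volume = mean(pre), sd_pre_volume = stats::sd(pre),
              mean_post_volume = mean(post), sd_post_volume = stats::sd(post),
              mean_volume_difference = mean(pre - post),
              mean_pct_volume_change = mean(pv),
              sd_pct_volume_change = stats::sd(pv))
  for (m in c("d_avg", "d_max", "d50", "d70", "d90", "v100")) {
    pm <- tab[[paste0("pre_", m)]]
    qm <- tab[[paste0("post_", m)]]
    if (is.null(pm) || is.null(qm)) next
    delta <- qm - pm
    out[[paste0("mean_pre_", m)]] <- mean(pm)
    out[[paste0("mean_post_", m)]] <- mean(qm)
    out[[paste0("mean_delta_", m)]] <- mean(delta)
    out[[paste0("sd_delta_", m)]] <- stats::sd(delta)
    out[[paste0("mean_pct_change_", m)]] <-
      mean(ifelse(pm != 0, 100 * delta / pm, 0))
  }
  out
}

#' Bundled example cohort: per-tumor ablation and volume table
#'
#' The per-tumor table of a 14-patient / 15-tumor radioembolization cohort
#' treated with simulated adjuvant RF ablation (patient 2 carried two
#' independent tumor foci, analysed as separate rows): number of ablation
#' sites, per-site ablation times, and pre-/post-ablation tumor volumes,
#' together with the infused activity and microsphere device.  Useful as a
#' worked example for [cohort_summary()], [pct_volume_change()] and the
#' cohort statistics.
#'
#' @return A data frame with columns `patient`, `disease`, `device`,
#'   `activity_gbq`, `n_sites`, `ablation_times_s`, `pre_volume_cm3`,
#'   `post_volume_cm3`.
#' @export
example_cohort <- function() {
  data.frame(
    patient = c("1", "2a", "2b", "3", "4", "5", "6", "7", "8", "9", "10",
                "11", "12", "13", "14"),
    disease = c("HCC", "HCC", "HCC", "HCC", "Cholangio", "HCC", "Cholangio",
                "Endometrial", "HCC", "HCC", "HCC", "Breast", "HCC", "HCC",
                "HCC"),
    device = c(rep("resin", 12), rep("glass", 3)),
    activity_gbq = c(1.30, 1.39, 1.39, 1.67, 0.62, 1.24, 0.92, 1.14, 1.01,
                     1.83, 1.54, 1.17, 2.51, 4.13, 3.23),
    n_sites = c(1, 3, 2, 2, 2, 2, 1, 2, 2, 3, 1, 2, 4, 4, 2),
    ablation_times_s = c("600", "600/600/600", "600/600", "600/420",
                         "600/600", "600/360", "600", "600/600", "220/220",
                         "600/360/360", "600", "260/260",
                         "600/600/600/600", "600/600/600/600", "600/600"),
    pre_volume_cm3 = c(124.1, 270.4, 241.3, 276.4, 100.7, 374.6, 44.4,
                       203.2, 220.9, 213.4, 42.5, 60.2, 104.7, 323.4, 258.2),
    post_volume_cm3 = c(112.9, 239.7, 217.0, 253.9, 78.1, 352.9, 32.5,
                        177.7, 212.2, 192.7, 29.9, 54.1, 82.4, 299.1, 240.1))
}

#' Export a cohort table or per-case report
#'
#' @param x a [cohort_table()] (written as CSV) or `case_result` (JSON).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_cohort <- function(x, path) {
  if (inherits(x, "case_result")) {
    rec <- list(id = x$id, device = x$device,
                pre_metrics = as.data.frame(x$pre_metrics),
                post_metrics = as.data.frame(x$post_metrics),
                pre_volume_cm3 = x$pre_volume,
                post_volume_cm3 = x$post_volume,
                ablated_in_tumor_volume_cm3 = x$ablated_in_tumor_volume,
                pct_volume_change = x$pct_volume_change,
                n_sites = x$n_sites, durations_s = x$durations,
                deltas = as.list(x$deltas), pct_changes = as.list(x$pct_changes))
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}
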