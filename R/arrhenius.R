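#' Arrhenius damage parameters
#'
#' First-order thermal damage kinetics: the damage integral is
#' `Omega(t) = integral A exp(-Ea / (R T(t))) dt` with `T` in kelvin.  Two
#' presets are shipped: `"cell_death"` (A = 2.984e80 1/s, Ea = 5.06e5 J/mol),
#' used for the ablation kill boundary, and `"vascular"` (A = 1.98e106 1/s,
#' Ea = 6.67e5 J/mol), used for capillary coagulation and perfusion
#' shutdown.  The pre-exponential factors overflow double precision if
#' evaluated naively, so all rate evaluations are done in log space as
#' `exp(log(A) - Ea/(R T))`; the parameters are therefore stored as `log_A`.
#'
#' @param preset `"cell_death"` or `"vascular"`, or `NULL` when giving `A`
#'   and `Ea` directly.
#' @param A pre-exponential factor, 1/s (ignored when `preset` given).
#' @param Ea activation energy, J/mol.
#' @param log_A optionally, `log(A)` directly (for magnitudes beyond double
#'   range).
#' @return An object of class `arrhenius_params` with fields `log_A`, `Ea`
#'   and `R` (8.314 J/mol/K).
#' @export
arrhenius_params <- function(preset = NULL, A = NULL, Ea = NULL,
                             log_A = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("cell_death", "vascular"))
    if (preset == "cell_death") {
      log_A <- log(2.984) + 80 * log(10)
      Ea <- 5.06e5
    } else {
      log_A <- log(1.98) + 106 * log(10)
      Ea <- 6.67e5
    }
  } else {
    if (is.null(log_A)) {
      if (is.null(A) || A <= 0) stop("A must be > 0")
      log_A <- log(A)
    }
    if (is.null(Ea) || Ea <= 0) stop("Ea must be > 0")
  }
  structure(list(log_A = log_A, Ea = Ea, R = 8.314),
            class = "arrhenius_params")
}

arrhenius_rate <- function(temp_k, params) {
  exp(params$log_A - params$Ea / (params$R * temp_k))
}

#' Arrhenius damage integral over a temperature history
#'
#' Trapezoidal approximation of `integral A exp(-Ea/(R T(t))) dt` over
#' sampled `(time, temperature)` pairs.  Additive over concatenated
#' intervals and monotone in temperature.
#'
#' @param time_s strictly increasing sample times, seconds.
#' @param temp_k temperatures at the sample times, kelvin (>= 0).
#' @param params an [arrhenius_params()] object.
#' @return The dimensionless damage integral Omega (>= 0).
#' @export
omega_integral <- function(time_s, temp_k, params) {
  if (length(time_s) != length(temp_k))
    stop("time and temperature series must have equal length")
  if (length(time_s) < 2) return(0)
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  if (any(temp_k < 0)) stop("temperatures must be >= 0 K")
  rate <- arrhenius_rate(temp_k, params)
  sum(0.5 * (rate[-1] + rate[-length(rate)]) * diff(time_s))
}

#' Surviving fraction from a damage integral
#'
#' `SF = exp(-Omega)`; Omega = 6.9 corresponds to SF = 0.001, i.e. 99.9%
#' cell kill, the boundary used for ablation zones.
#'
#' @param omega damage integral (>= 0).
#' @return Surviving fraction in `(0, 1]`.
#' @export
surviving_fraction <- function(omega) {
  if (any(omega < 0)) stop("omega must be >= 0")
  exp(-omega)
}

#' Fractional vascular coagulation over a temperature history
#'
#' `C_f = 1 - exp(-Omega_vascular)`, the fraction of capillary flow occluded
#' by heating; bounded in `[0, 1)` and non-decreasing along any history.
#'
#' @inheritParams omega_integral
#' @param params vascular [arrhenius_params()] (default the `"vascular"`
#'   preset).
#' @return Coagulated fraction in `[0, 1)`.
#' @export
coagulation_fraction <- function(time_s, temp_k,
                                 params = arrhenius_params("vascular")) {
  1 - exp(-omega_integral(time_s, temp_k, params))
}

#' Kill mask from a damage map
#'
#' Voxels whose cell-death damage integral reaches the threshold (default
#' Omega = 6.9, surviving fraction 0.001) form the predicted ablation zone.
#'
#' @param omega_map a non-negative [scalar_map()] of Omega values.
#' @param threshold inclusive Omega threshold (default 6.9).
#' @return A [label_mask()].
#' @export
kill_mask <- function(omega_map, threshold = 6.9) {
  if (any(omega_map$values < 0)) stop("omega map must be non-negative")
  label_mask(omega_map$values >= threshold, omega_map$grid)
}

#' Time to reach a damage threshold at constant temperature
#'
#' Closed form `t = Omega* / (A exp(-Ea/(R T)))`, the holding time at a
#' constant temperature needed to reach a target damage integral.
#'
#' @param temp_k constant temperature, kelvin.
#' @param params an [arrhenius_params()] object.
#' @param threshold target Omega (default 6.9).
#' @return Time in seconds.
#' @export
time_to_threshold <- function(temp_k, params, threshold = 6.9) {
  threshold / arrhenius_rate(temp_k, params)
}
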