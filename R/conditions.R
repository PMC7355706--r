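# Package-level calibration constants.
#
# .gisim_z_unit_scale: dimensionless multiplier applied uniformly to the
#   tabulated per-compartment dissolution coefficients (which are reported on
#   a scale too small to dissolve a 10 mg dose within the experiment); chosen
#   once so that the fast-release cola/fast-emptying scenario reaches
#   near-complete gastric dissolution by ~10 min.  See the methods vignette.
# .gisim_s0_default: intrinsic solubility (ug/mL) of the shipped weak-base
#   presets; a calibration constant fixed once against the reference fasted
#   water scenario's plasma exposure.  See the methods vignette.
.gisim_z_unit_scale <- 2e6
.gisim_s0_default <- 3.3

#' Piecewise-linear pH profile
#'
#' @param time_min Numeric vector of times (min), strictly increasing.
#' @param ph Numeric vector of pH values, same length.
#' @return A tibble with columns `time_min`, `ph`.
#' @examples
#' ph_profile(c(0, 15, 60), c(6.5, 3.27, 6.5))
#' @export
ph_profile <- function(time_min, ph) {
  if (length(time_min) != length(ph)) {
    abort("`time_min` and `ph` must have the same length.")
  }
  if (length(time_min) < 1L || is.unsorted(time_min, strictly = TRUE)) {
    abort("`time_min` must be non-empty and strictly increasing.")
  }
  if (any(ph < 0 | ph > 14)) abort("`ph` must lie within [0, 14].")
  tibble(time_min = as.numeric(time_min), ph = as.numeric(ph))
}

#' Evaluate a pH profile at arbitrary times
#'
#' Linear interpolation between the profile's anchor points, constant
#' extrapolation beyond them.
#'
#' @param profile A [ph_profile()] tibble.
#' @param time_min Times (min) at which to evaluate.
#' @return Numeric vector of pH values.
#' @export
ph_at <- function(profile, time_min) {
  if (nrow(profile) == 1L) return(rep(profile$ph, length(time_min)))
  approx(profile$time_min, profile$ph, xout = time_min, rule = 2)$y
}

#' Physiological scenario of the gastrointestinal simulator
#'
#' Describes one test condition of the three-chamber simulator: initial
#' volumes, secretion rates, the first-order gastric-emptying half-life, and
#' the per-chamber pH time-courses.  The duodenal chamber is held at constant
#' volume by matching its outflow to its inflow; the jejunal chamber starts
#' empty and only accumulates.
#'
#' @param label Scenario label.
#' @param gastric_initial_volume Initial gastric volume (mL); the default 300
#'   corresponds to 50 mL simulated gastric fluid plus a 250 mL beverage.
#' @param gastric_residual_floor Residual gastric volume (mL) below which the
#'   emptying pump only passes on the secreted fluid.
#' @param duodenal_volume Constant duodenal volume (mL).
#' @param jejunal_initial_volume Initial jejunal volume (mL).
#' @param k_sec_s,k_sec_d Gastric and duodenal secretion rates (mL/min).
#' @param t_half_gastric Gastric-emptying half-life (min).
#' @param gastric_ph_profile,duodenal_ph_profile,jejunal_ph_profile
#'   [ph_profile()] tibbles covering `[0, duration]`.
#' @param duration Experiment duration (min).
#' @return An object of class `condition_config`.
#' @examples
#' condition_config("fasted water", t_half_gastric = 15)
#' @export
condition_config <- function(label,
                             gastric_initial_volume = 300,
                             gastric_residual_floor = 5,
                             duodenal_volume = 50,
                             jejunal_initial_volume = 0,
                             k_sec_s = 1,
                             k_sec_d = 1,
                             t_half_gastric = 15,
                             gastric_ph_profile = ph_profile(0, 2.0),
                             duodenal_ph_profile = ph_profile(0, 6.5),
                             jejunal_ph_profile = ph_profile(0, 6.5),
                             duration = 60) {
  vols <- c(gastric_initial_volume, gastric_residual_floor, duodenal_volume,
            jejunal_initial_volume)
  if (any(vols < 0)) abort("all volumes must be non-negative.")
  if (t_half_gastric <= 0) abort("`t_half_gastric` must be positive.")
  if (k_sec_s < 0 || k_sec_d < 0) abort("secretion rates must be non-negative.")
  if (duration <= 0) abort("`duration` must be positive.")
  structure(
    list(label = label,
         gastric_initial_volume = gastric_initial_volume,
         gastric_residual_floor = gastric_residual_floor,
         duodenal_volume = duodenal_volume,
         jejunal_initial_volume = jejunal_initial_volume,
         k_sec_s = k_sec_s, k_sec_d = k_sec_d,
         t_half_gastric = t_half_gastric,
         gastric_ph_profile = as_tibble(gastric_ph_profile),
         duodenal_ph_profile = as_tibble(duodenal_ph_profile),
         jejunal_ph_profile = as_tibble(jejunal_ph_profile),
         duration = duration),
    class = "condition_config"
  )
}

#' @export
print.condition_config <- function(x, ...) {
  cat("<condition_config> ", x$label, "\n",
      "  V_s(0) ", x$gastric_initial_volume, " mL (floor ",
      x$gastric_residual_floor, " mL) | V_d ", x$duodenal_volume,
      " mL | V_j(0) ", x$jejunal_initial_volume, " mL\n",
      "  k_sec_s ", x$k_sec_s, " mL/min | k_sec_d ", x$k_sec_d,
      " mL/min | t1/2,G ", x$t_half_gastric, " min | duration ",
      x$duration, " min\n", sep = "")
  invisible(x)
}

#' Transit kinetic parameters
#'
#' The fitted kinetic coefficients of the mass-transport model: Z-factor
#' dissolution coefficients for stomach/duodenum/jejunum, the fraction of
#' undissolved particles carried along with fluid transfer, and first-order
#' precipitation rate constants acting on the supersaturated excess in the
#' intestinal chambers.  `z_unit_scale` is a dimensionless multiplier applied
#' uniformly to all three dissolution coefficients (the shipped presets keep
#' the coefficients on their tabulated scale and carry the package's
#' calibrated multiplier).
#'
#' @param z_s,z_d,z_j Dissolution coefficients (mL/ug/min), >= 0.
#' @param frac Fraction of particles transferred between chambers, in \[0, 1\].
#' @param k_pre_d,k_pre_j First-order precipitation rate constants (1/min).
#' @param z_unit_scale Multiplier applied to all Z coefficients.
#' @return An object of class `transit_parameters`.
#' @examples
#' transit_parameters(z_s = 1.43e-11, z_d = 3.63e-11, z_j = 5.05e-12,
#'                    frac = 0.282, k_pre_d = 0.489, k_pre_j = 1.73e-3)
#' @export
transit_parameters <- function(z_s, z_d, z_j, frac, k_pre_d, k_pre_j,
                               z_unit_scale = .gisim_z_unit_scale) {
  vals <- c(z_s = z_s, z_d = z_d, z_j = z_j,
            k_pre_d = k_pre_d, k_pre_j = k_pre_j,
            z_unit_scale = z_unit_scale)
  if (any(vals < 0)) abort("all transit rate parameters must be non-negative.")
  if (frac < 0 || frac > 1) abort("`frac` must lie within [0, 1].")
  structure(
    list(z_s = z_s, z_d = z_d, z_j = z_j, frac = frac,
         k_pre_d = k_pre_d, k_pre_j = k_pre_j, z_unit_scale = z_unit_scale),
    class = "transit_parameters"
  )
}

#' @export
print.transit_parameters <- function(x, ...) {
  cat("<transit_parameters>\n",
      sprintf("  Z_s %.3g  Z_d %.3g  Z_j %.3g (mL/ug/min, x %.3g)\n",
              x$z_s, x$z_d, x$z_j, x$z_unit_scale),
      sprintf("  Frac %.3g | k_pre_d %.3g  k_pre_j %.3g (1/min)\n",
              x$frac, x$k_pre_d, x$k_pre_j), sep = "")
  invisible(x)
}

#' Coerce transit parameters to a one-row tibble
#' @param x A `transit_parameters` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
as_tibble.transit_parameters <- function(x, ...) {
  tibble(z_s = x$z_s, z_d = x$z_d, z_j = x$z_j, frac = x$frac,
         k_pre_d = x$k_pre_d, k_pre_j = x$k_pre_j,
         z_unit_scale = x$z_unit_scale)
}

#' Shipped test-condition presets
#'
#' The four fasted-state scenarios of the study, combining the co-administered
#' beverage (tap water, conditions 1-2, versus an acidic cola beverage,
#' conditions 3-4) with a gastric-emptying half-life of 15 min (conditions
#' 1 and 3) or 30 min (conditions 2 and 4), together with the fitted transit
#' parameters reported for each condition.
#'
#' Default pH time-courses: gastric pH constant at the initial mixture value
#' (2.0 for the water conditions, 2.48 for the cola conditions); duodenal pH
#' constant at 6.5 for the water conditions and, for the cola conditions, a
#' piecewise-linear dip from 6.5 to the observed minimum (3.27 for condition
#' 3, 4.25 for condition 4) at `dip_time_min` with recovery to 6.5 by 60 min;
#' jejunal pH fixed at 6.5.
#'
#' @param n Condition number, 1-4.
#' @param dip_time_min Time (min) of the duodenal pH minimum for the cola
#'   conditions.
#' @return A list with elements `condition` ([condition_config()]) and
#'   `params` ([transit_parameters()]).
#' @examples
#' condition_preset(1)$condition
#' condition_preset(3)$params
#' @export
condition_preset <- function(n, dip_time_min = 15) {
  if (!length(n) == 1L || !n %in% 1:4) {
    abort("`n` must be one of 1, 2, 3, 4.")
  }
  n <- as.integer(n)
  water <- n %in% 1:2
  t_half <- if (n %in% c(1L, 3L)) 15 else 30
  gastric_ph <- if (water) ph_profile(0, 2.0) else ph_profile(0, 2.48)
  duodenal_ph <- if (water) {
    ph_profile(0, 6.5)
  } else {
    dip <- if (n == 3L) 3.27 else 4.25
    ph_profile(c(0, dip_time_min, 60), c(6.5, dip, 6.5))
  }
  condition <- condition_config(
    label = sprintf("condition %d (%s, t1/2,G %d min)", n,
                    if (water) "water" else "cola", as.integer(t_half)),
    t_half_gastric = t_half,
    gastric_ph_profile = gastric_ph,
    duodenal_ph_profile = duodenal_ph,
    jejunal_ph_profile = ph_profile(0, 6.5)
  )
  params <- switch(n,
    transit_parameters(z_s = 1.43e-11, z_d = 3.63e-11, z_j = 5.05e-12,
                       frac = 0.282, k_pre_d = 0.489, k_pre_j = 1.73e-3),
    transit_parameters(z_s = 1.72e-11, z_d = 3.63e-11, z_j = 6.11e-12,
                       frac = 0.844, k_pre_d = 0.155, k_pre_j = 2.73e-3),
    transit_parameters(z_s = 1.51e-10, z_d = 3.63e-11, z_j = 6.11e-12,
                       frac = 0.296, k_pre_d = 1.38e-5, k_pre_j = 1.90e-5),
    transit_parameters(z_s = 7.41e-11, z_d = 5.31e-11, z_j = 6.11e-12,
                       frac = 0.628, k_pre_d = 5.75e-10, k_pre_j = 1.90e-5)
  )
  list(condition = condition, params = params)
}

#' First-order gastric emptying rate constant
#'
#' @param t_half Gastric-emptying half-life (min), > 0.
#' @return Rate constant `log(2) / t_half` (1/min).
#' @examples
#' gastric_emptying_rate(15)
#' @export
gastric_emptying_rate <- function(t_half) {
  if (any(t_half <= 0)) abort("`t_half` must be positive.")
  log(2) / t_half
}
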