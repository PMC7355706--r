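#' Z-factor dissolution flux
#'
#' Dissolution rate of solid drug under the Z-factor model:
#' `z * x_solid * max(0, solubility - concentration)`.  The flux vanishes
#' when the solution is at (or above) saturation or no solid remains.
#'
#' @param z Dissolution coefficient (mL/ug/min), >= 0.
#' @param x_solid Solid amount (ug), >= 0.
#' @param solubility Solubility (ug/mL), >= 0.
#' @param concentration Dissolved concentration (ug/mL), >= 0.
#' @return Dissolution flux (ug/min), vectorised.
#' @examples
#' dissolution_flux(1e-3, 1e4, 60, 10)
#' @export
dissolution_flux <- function(z, x_solid, solubility, concentration) {
  if (any(c(z, x_solid, solubility, concentration) < 0)) {
    abort("all inputs to `dissolution_flux()` must be non-negative.")
  }
  z * x_solid * pmax(0, solubility - concentration)
}

#' First-order precipitation flux of the supersaturated excess
#'
#' `k_pre * max(0, x_dissolved - solubility * volume)`: precipitation acts
#' only on dissolved drug in excess of saturation, so sub-saturated solutions
#' never precipitate.
#'
#' @param k_pre Precipitation rate constant (1/min), >= 0.
#' @param x_dissolved Dissolved amount (ug), >= 0.
#' @param solubility Solubility (ug/mL), >= 0.
#' @param volume Fluid volume (mL), > 0.
#' @return Precipitation flux (ug/min), vectorised.
#' @examples
#' precipitation_flux(0.1, 2200, 40, 50)
#' @export
precipitation_flux <- function(k_pre, x_dissolved, solubility, volume) {
  if (any(c(k_pre, x_dissolved, solubility) < 0)) {
    abort("all inputs to `precipitation_flux()` must be non-negative.")
  }
  if (any(volume <= 0)) abort("`volume` must be positive.")
  k_pre * pmax(0, x_dissolved - solubility * volume)
}

#' Simulate drug transit through the gastrointestinal simulator
#'
#' Integrates the coupled mass-transport system across the three chambers.
#' The stomach empties by a first-order process (`Q_s = k_GE * V_s`) until its
#' residual floor is reached, after which the pump only passes on the secreted
#' fluid; dissolved drug empties with the fluid and solid particles empty with
#' the fluid scaled by `frac`, the complement remaining in the chamber as
#' undisintegrated residue.  The duodenal chamber is held at constant volume
#' (outflow = inflow), the jejunal chamber only accumulates.  Each chamber
#' dissolves solid drug by the Z-factor law with a time-varying solubility
#' from its pH profile; the supersaturated excess precipitates at a
#' first-order rate in the duodenum and jejunum into an inert pool.
#'
#' @param drug A [drug_properties()] object.
#' @param condition A [condition_config()] object.
#' @param params A [transit_parameters()] object.
#' @param times Output time grid (min) within `[0, condition$duration]`.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return A `gis_trajectory`: a tibble with columns `time_min`,
#'   `compartment` (`"stomach"`, `"duodenum"`, `"jejunum"`), `volume_ml`,
#'   `solid_ug`, `dissolved_ug`, `precipitated_ug`, `conc_ug_per_ml`,
#'   `solubility_ug_per_ml` and `ds`, with the cumulative transfer ledgers,
#'   the inputs and the dose stored as attributes.
#' @examples
#' pre <- condition_preset(1)
#' traj <- simulate_gis(drug_preset(), pre$condition, pre$params,
#'                      times = seq(0, 60, by = 5))
#' @export
simulate_gis <- function(drug, condition, params,
                         times = seq(0, condition$duration, by = 0.5),
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(drug, "drug_properties"),
            inherits(condition, "condition_config"),
            inherits(params, "transit_parameters"))
  if (any(times < 0) || any(times > condition$duration)) {
    abort("`times` must lie within [0, condition$duration].")
  }
  times <- sort(unique(as.numeric(times)))
  solve_times <- if (times[1] > 0) c(0, times) else times

  kge <- gastric_emptying_rate(condition$t_half_gastric)
  veps <- 0.1
  parms <- c(kge = kge,
             ksec_s = condition$k_sec_s, ksec_d = condition$k_sec_d,
             vfloor = condition$gastric_residual_floor,
             vd = condition$duodenal_volume,
             frac = params$frac,
             zs = params$z_s * params$z_unit_scale,
             zd = params$z_d * params$z_unit_scale,
             zj = params$z_j * params$z_unit_scale,
             kpre_d = params$k_pre_d, kpre_j = params$k_pre_j,
             veps = veps)

  # solubility forcings on a grid refined with the pH-profile anchors
  fgrid <- sort(unique(c(seq(0, condition$duration, by = 0.5),
                         condition$gastric_ph_profile$time_min,
                         condition$duodenal_ph_profile$time_min,
                         condition$jejunal_ph_profile$time_min)))
  fgrid <- fgrid[fgrid >= 0 & fgrid <= condition$duration]
  sol_s <- solubility_at_ph(drug, ph_at(condition$gastric_ph_profile, fgrid))
  sol_d <- solubility_at_ph(drug, ph_at(condition$duodenal_ph_profile, fgrid))
  sol_j <- solubility_at_ph(drug, ph_at(condition$jejunal_ph_profile, fgrid))
  forcings <- list(cbind(fgrid, sol_s), cbind(fgrid, sol_d),
                   cbind(fgrid, sol_j))

  y0 <- c(Vs = condition$gastric_initial_volume,
          Vj = condition$jejunal_initial_volume,
          Xs_s = drug$dose_ug, Xd_s = 0,
          Xs_d = 0, Xd_d = 0, Xp_d = 0,
          Xs_j = 0, Xd_j = 0, Xp_j = 0,
          cum_emptied_dis = 0, cum_emptied_sol = 0,
          cum_dj_dis = 0, cum_dj_sol = 0)

  out <- tryCatch(
    deSolve::lsoda(y = y0, times = solve_times, func = "gis_derivs",
                   parms = parms, dllname = "gisim",
                   initfunc = "gis_initmod", initforc = "gis_initforc",
                   forcings = forcings, rtol = rtol, atol = atol,
                   maxsteps = 50000),
    warning = function(w) {
      abort(paste0("transit ODE integration failed for '", condition$label,
                   "': ", conditionMessage(w)))
    }
  )
  out <- as.data.frame(out)
  out <- out[out$time %in% times, , drop = FALSE]

  conc_of <- function(x, v) ifelse(v > veps, x / v, 0)
  sol_at <- function(profile) {
    solubility_at_ph(drug, ph_at(profile, out$time))
  }
  per_comp <- list(
    stomach = tibble(
      time_min = out$time, compartment = "stomach",
      volume_ml = out$Vs, solid_ug = out$Xs_s, dissolved_ug = out$Xd_s,
      precipitated_ug = 0,
      solubility_ug_per_ml = sol_at(condition$gastric_ph_profile)),
    duodenum = tibble(
      time_min = out$time, compartment = "duodenum",
      volume_ml = condition$duodenal_volume, solid_ug = out$Xs_d,
      dissolved_ug = out$Xd_d, precipitated_ug = out$Xp_d,
      solubility_ug_per_ml = sol_at(condition$duodenal_ph_profile)),
    jejunum = tibble(
      time_min = out$time, compartment = "jejunum",
      volume_ml = out$Vj, solid_ug = out$Xs_j, dissolved_ug = out$Xd_j,
      precipitated_ug = out$Xp_j,
      solubility_ug_per_ml = sol_at(condition$jejunal_ph_profile))
  )
  traj <- bind_rows(per_comp)
  traj <- mutate(traj,
                 conc_ug_per_ml = conc_of(.data$dissolved_ug, .data$volume_ml),
                 ds = .data$conc_ug_per_ml / .data$solubility_ug_per_ml)
  traj <- arrange(traj, .data$time_min, .data$compartment)

  ledgers <- tibble(
    time_min = out$time,
    emptied_dissolved_ug = out$cum_emptied_dis,
    emptied_solid_ug = out$cum_emptied_sol,
    dj_dissolved_ug = out$cum_dj_dis,
    dj_solid_ug = out$cum_dj_sol)

  structure(traj,
            class = c("gis_trajectory", class(traj)),
            ledgers = ledgers,
            drug = drug, condition = condition, params = params,
            dose_ug = drug$dose_ug, volume_eps_ml = veps)
}

#' @export
print.gis_trajectory <- function(x, ...) {
  cond <- attr(x, "condition")
  cat("<gis_trajectory> ", cond$label, " | dose ", attr(x, "dose_ug"),
      " ug | ", length(unique(x$time_min)), " time points\n", sep = "")
  NextMethod()
}

#' Cumulative transfer ledgers of a trajectory
#'
#' @param traj A `gis_trajectory`.
#' @return A tibble of cumulative gastric-emptied and duodenum-to-jejunum
#'   dissolved/solid amounts per output time.
#' @export
transfer_ledgers <- function(traj) {
  stopifnot(inherits(traj, "gis_trajectory"))
  attr(traj, "ledgers")
}

.check_compartment <- function(compartment) {
  if (!length(compartment) == 1L ||
      !compartment %in% c("stomach", "duodenum", "jejunum")) {
    abort("`compartment` must be one of \"stomach\", \"duodenum\", \"jejunum\".")
  }
  compartment
}

#' Concentration-time series of one chamber
#'
#' `C(t) = dissolved / volume`, defined as 0 while the chamber volume is at or
#' below the solver's volume epsilon (the initially empty jejunum).
#'
#' @param traj A `gis_trajectory`.
#' @param compartment `"stomach"`, `"duodenum"` or `"jejunum"`.
#' @return A tibble with columns `time_min`, `conc_ug_per_ml`.
#' @export
concentration_series <- function(traj, compartment) {
  stopifnot(inherits(traj, "gis_trajectory"))
  .check_compartment(compartment)
  out <- filter(as_tibble(traj), .data$compartment == !!compartment)
  select(out, "time_min", "conc_ug_per_ml")
}

#' Degree-of-supersaturation time series of one chamber
#'
#' Applies [degree_of_supersaturation()] pointwise with the chamber's
#' time-varying solubility.
#'
#' @inheritParams concentration_series
#' @return A tibble with columns `time_min`, `ds`.
#' @export
ds_series <- function(traj, compartment) {
  stopifnot(inherits(traj, "gis_trajectory"))
  .check_compartment(compartment)
  out <- filter(as_tibble(traj), .data$compartment == !!compartment)
  if (any(out$solubility_ug_per_ml <= 0)) {
    abort("solubility must be positive at every grid point to compute DS.")
  }
  mutate(select(out, "time_min", "conc_ug_per_ml", "solubility_ug_per_ml"),
         ds = degree_of_supersaturation(.data$conc_ug_per_ml,
                                        .data$solubility_ug_per_ml))[
    , c("time_min", "ds")]
}

#' Absorbable luminal dissolved amount over time
#'
#' The dissolved duodenal plus jejunal amounts, the exogenous forcing of the
#' plasma disposition model.  Beyond the simulated horizon the series is
#' extended with a closed-form washout: drug still dissolved in the stomach
#' keeps emptying into the absorbable pool at the gastric emptying rate, and
#' the absorbable pool itself decays first-order at the jejunal precipitation
#' rate constant plus `absorption_rate_per_min`.  In vitro the simulator has
#' no absorptive sink, but past the experiment's window the in vivo lumen it
#' stands for is emptied by absorption; holding the pool constant instead
#' would absorb several times more drug than ever dissolved.  Set
#' `absorption_rate_per_min = 0` to hold the pool with precipitation-only
#' decay.
#'
#' @param traj A `gis_trajectory`.
#' @param horizon Optional horizon (min) to extend the series to.
#' @param absorption_rate_per_min First-order absorption rate constant
#'   (1/min) depleting the absorbable pool beyond the simulated horizon;
#'   typically the disposition model's `ka` converted to 1/min.
#' @param by Output grid spacing (min).
#' @return A tibble with columns `time_min`, `duodenum_ug`, `jejunum_ug`,
#'   `amount_ug` (beyond the simulated horizon the washed-out pool is
#'   reported under `jejunum_ug`).
#' @export
luminal_dissolved <- function(traj, horizon = NULL,
                              absorption_rate_per_min = 0, by = 1) {
  stopifnot(inherits(traj, "gis_trajectory"))
  wide <- as_tibble(traj)
  duod <- filter(wide, .data$compartment == "duodenum")
  jej <- filter(wide, .data$compartment == "jejunum")
  stom <- filter(wide, .data$compartment == "stomach")
  t_end <- max(duod$time_min)
  grid <- seq(min(duod$time_min), t_end, by = by)
  base <- tibble(
    time_min = grid,
    duodenum_ug = approx(duod$time_min, duod$dissolved_ug, grid, rule = 2)$y,
    jejunum_ug = approx(jej$time_min, jej$dissolved_ug, grid, rule = 2)$y)
  if (!is.null(horizon) && horizon > t_end) {
    cond <- attr(traj, "condition")
    kge <- gastric_emptying_rate(cond$t_half_gastric)
    lambda <- attr(traj, "params")$k_pre_j + absorption_rate_per_min
    t_ext <- seq(t_end + by, horizon, by = by)
    dt <- t_ext - t_end
    a0 <- base$duodenum_ug[nrow(base)] + base$jejunum_ug[nrow(base)]
    g0 <- stom$dissolved_ug[which.max(stom$time_min)]
    relay <- if (abs(lambda - kge) < 1e-12) {
      g0 * kge * dt * exp(-kge * dt)
    } else {
      g0 * kge / (lambda - kge) * (exp(-kge * dt) - exp(-lambda * dt))
    }
    base <- bind_rows(base, tibble(
      time_min = t_ext,
      duodenum_ug = 0,
      jejunum_ug = a0 * exp(-lambda * dt) + relay))
  }
  mutate(base, amount_ug = .data$duodenum_ug + .data$jejunum_ug)
}

#' Total drug mass per output time
#'
#' Sums solid, dissolved and precipitated drug over all chambers (the
#' undisintegrated gastric residue is part of the gastric solid pool), which
#' must equal the dose at every time.
#'
#' @param traj A `gis_trajectory`.
#' @return A tibble with columns `time_min`, `total_ug`.
#' @export
total_drug_mass <- function(traj) {
  stopifnot(inherits(traj, "gis_trajectory"))
  summarise(group_by(as_tibble(traj), .data$time_min),
            total_ug = sum(.data$solid_ug + .data$dissolved_ug +
                             .data$precipitated_ug),
            .groups = "drop")
}
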