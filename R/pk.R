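#' Two-compartment disposition parameters
#'
#' First-order absorption (`ka`), elimination from the central compartment
#' (`k10`) and central/peripheral exchange (`k12`, `k21`), all in 1/h as
#' conventionally tabulated, plus the apparent volume of distribution `V/F`
#' in litres.  Clearance follows as `CL = k10 * V/F`.
#'
#' @param ka,k10,k12,k21 First-order rate constants (1/h), >= 0.
#' @param v_over_f Apparent volume of distribution (L), > 0.
#' @return An object of class `pk_parameters`.
#' @examples
#' pk_parameters(ka = 0.846, k10 = 0.271, k12 = 0.546, k21 = 0.054,
#'               v_over_f = 1198)
#' @export
pk_parameters <- function(ka, k10, k12, k21, v_over_f) {
  if (any(c(ka, k10, k12, k21) < 0)) {
    abort("rate constants must be non-negative.")
  }
  if (v_over_f <= 0) abort("`v_over_f` must be positive.")
  structure(
    list(ka = ka, k10 = k10, k12 = k12, k21 = k21, v_over_f = v_over_f,
         cl = k10 * v_over_f),
    class = "pk_parameters"
  )
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf(paste0("<pk_parameters> Ka %.3g, K10 %.3g, K12 %.3g, ",
                     "K21 %.3g (1/h) | V/F %.4g L | CL %.4g L/h\n"),
              x$ka, x$k10, x$k12, x$k21, x$v_over_f, x$cl))
  invisible(x)
}

#' Convert a first-order rate constant between 1/h and 1/min
#'
#' @param k Rate constant(s).
#' @param from,to `"per_h"` or `"per_min"`.
#' @return Converted rate constant(s).
#' @examples
#' rate_convert(0.846, "per_h", "per_min")
#' @export
rate_convert <- function(k, from = c("per_h", "per_min"),
                         to = c("per_min", "per_h")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(k)
  if (from == "per_h") k / 60 else k * 60
}

#' Pool disposition parameters across studies
#'
#' Arithmetic mean of each parameter over a table of per-study estimates, the
#' convention used to obtain the simulation input from the published studies.
#'
#' @param studies Data frame with columns `ka_per_h`, `k10_per_h`,
#'   `k12_per_h`, `k21_per_h`, `v_over_f_L` (one row per study).
#' @return A [pk_parameters()] object of column means.
#' @examples
#' pool_pk_parameters(loratadine_pk_studies())
#' @export
pool_pk_parameters <- function(studies) {
  studies <- as_tibble(studies)
  if (nrow(studies) == 0L) abort("`studies` must contain at least one row.")
  required <- c("ka_per_h", "k10_per_h", "k12_per_h", "k21_per_h",
                "v_over_f_L")
  missing <- setdiff(required, names(studies))
  if (length(missing) > 0) {
    abort(paste0("`studies` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  pk_parameters(ka = mean(studies$ka_per_h),
                k10 = mean(studies$k10_per_h),
                k12 = mean(studies$k12_per_h),
                k21 = mean(studies$k21_per_h),
                v_over_f = mean(studies$v_over_f_L))
}

#' Shipped per-study disposition parameter table
#'
#' The twelve published loratadine study estimates used to derive the pooled
#' disposition parameters, as shipped in `extdata/pk_studies_loratadine.csv`.
#'
#' @return A 12-row tibble with columns `study_id`, `ka_per_h`, `k10_per_h`,
#'   `k12_per_h`, `k21_per_h`, `v_over_f_L`.
#' @examples
#' loratadine_pk_studies()
#' @export
loratadine_pk_studies <- function() {
  read_pk_studies(system.file("extdata", "pk_studies_loratadine.csv",
                              package = "gisim", mustWork = TRUE))
}

#' Simulate plasma concentrations from a luminal dissolved series
#'
#' Integrates the open two-compartment disposition system driven open-loop by
#' the dissolved intestinal amount `A(t)` (absorption does not deplete the
#' luminal series, which has no absorptive sink in vitro):
#' `dXc/dt = ka*A(t) - (k10 + k12)*Xc + k21*Xp`,
#' `dXp/dt = k12*Xc - k21*Xp`, with all rate constants converted to 1/min.
#' Plasma concentration is `Xc / (V/F)`.
#'
#' @param luminal Data frame with columns `time_min` and `amount_ug` (the
#'   dissolved duodenal + jejunal amount), e.g. from [luminal_dissolved()];
#'   linearly interpolated, held constant beyond its last point.
#' @param pk A [pk_parameters()] object.
#' @param horizon Simulation horizon (min); must not exceed the luminal
#'   series' span.
#' @param by Output grid spacing (min).
#' @param rtol,atol Solver tolerances.
#' @return A `plasma_profile`: a tibble with columns `time_min`,
#'   `conc_ug_per_ml`, `central_ug`, `peripheral_ug`, `cum_absorbed_ug`,
#'   `cum_eliminated_ug`.
#' @examples
#' lum <- data.frame(time_min = 0:60, amount_ug = 2000)
#' simulate_plasma(lum, pk_parameters(0.846, 0.271, 0.546, 0.054, 1198),
#'                 horizon = 60)
#' @export
simulate_plasma <- function(luminal, pk, horizon = 360, by = 1,
                            rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(pk, "pk_parameters"))
  luminal <- as_tibble(luminal)
  if (!all(c("time_min", "amount_ug") %in% names(luminal))) {
    abort("`luminal` must have columns `time_min` and `amount_ug`.")
  }
  if (horizon <= 0) abort("`horizon` must be positive.")
  if (horizon > max(luminal$time_min) + 1e-8) {
    abort(paste0("`horizon` (", horizon, " min) exceeds the luminal series ",
                 "(ends at ", max(luminal$time_min), " min); extend it ",
                 "first, e.g. with `luminal_dissolved(traj, horizon = ...)`."))
  }
  a_fun <- approxfun(luminal$time_min, luminal$amount_ug, rule = 2)
  ka_m <- rate_convert(pk$ka, "per_h", "per_min")
  k10_m <- rate_convert(pk$k10, "per_h", "per_min")
  k12_m <- rate_convert(pk$k12, "per_h", "per_min")
  k21_m <- rate_convert(pk$k21, "per_h", "per_min")

  rhs <- function(t, y, p) {
    a <- a_fun(t)
    absorbed <- ka_m * a
    list(c(absorbed - (k10_m + k12_m) * y[1] + k21_m * y[2],
           k12_m * y[1] - k21_m * y[2],
           absorbed,
           k10_m * y[1]))
  }
  times <- seq(0, horizon, by = by)
  out <- as.data.frame(deSolve::lsoda(
    y = c(xc = 0, xp = 0, cum_abs = 0, cum_elim = 0),
    times = times, func = rhs, parms = NULL, rtol = rtol, atol = atol))

  v_ml <- pk$v_over_f * 1000
  profile <- tibble(
    time_min = out$time,
    conc_ug_per_ml = out$xc / v_ml,
    central_ug = out$xc,
    peripheral_ug = out$xp,
    cum_absorbed_ug = out$cum_abs,
    cum_eliminated_ug = out$cum_elim)
  structure(profile,
            class = c("plasma_profile", class(profile)),
            pk = pk)
}

#' @export
print.plasma_profile <- function(x, ...) {
  cat("<plasma_profile> ", nrow(x), " time points, Cmax ",
      signif(max(x$conc_ug_per_ml), 3), " ug/mL\n", sep = "")
  NextMethod()
}

#' Non-compartmental exposure metrics
#'
#' `Cmax`/`Tmax` over the full profile and the linear-trapezoid AUC over the
#' window `[t_start, t_end]` (window ends interpolated onto the grid if
#' needed).
#'
#' @param profile A `plasma_profile` (or any data frame with `time_min` and
#'   `conc_ug_per_ml`).
#' @param t_start,t_end AUC window bounds (min), `t_start < t_end`, within
#'   the profile's time range.
#' @return A one-row tibble with columns `cmax_ug_per_ml`, `tmax_min`,
#'   `auc_ug_min_per_ml`, `auc_start_min`, `auc_end_min`.
#' @examples
#' prof <- data.frame(time_min = 0:10, conc_ug_per_ml = 2)
#' exposure_metrics(prof, 0, 10)
#' @export
exposure_metrics <- function(profile, t_start = 5, t_end = 360) {
  profile <- as_tibble(profile)
  if (!all(c("time_min", "conc_ug_per_ml") %in% names(profile))) {
    abort("`profile` must have columns `time_min` and `conc_ug_per_ml`.")
  }
  if (t_start >= t_end) abort("`t_start` must be smaller than `t_end`.")
  if (t_start < min(profile$time_min) || t_end > max(profile$time_min)) {
    abort("the AUC window must lie within the profile's time range.")
  }
  tt <- profile$time_min
  cc <- profile$conc_ug_per_ml
  grid <- sort(unique(c(t_start, t_end, tt[tt >= t_start & tt <= t_end])))
  cw <- approx(tt, cc, xout = grid)$y
  tibble(cmax_ug_per_ml = max(cc),
         tmax_min = tt[which.max(cc)],
         auc_ug_min_per_ml = pracma::trapz(grid, cw),
         auc_start_min = t_start, auc_end_min = t_end)
}

#' Compare exposure metrics of a test against a reference product
#'
#' Percent difference `100 * |test - reference| / reference` for Cmax and
#' AUC; the pair is flagged as equivalent when both differ by less than the
#' stated margin (20% by default).
#'
#' @param test,reference One-row data frames with columns `cmax_ug_per_ml`
#'   and `auc_ug_min_per_ml` (e.g. from [exposure_metrics()]).
#' @param margin_pct Equivalence margin in percent.
#' @return A tibble with one row per metric (`cmax`, `auc`): `test`,
#'   `reference`, `pct_diff`, `pass`, plus an attribute `equivalent` (all
#'   metrics pass).
#' @examples
#' a <- data.frame(cmax_ug_per_ml = 0.0017, auc_ug_min_per_ml = 0.35)
#' b <- data.frame(cmax_ug_per_ml = 0.0019, auc_ug_min_per_ml = 0.30)
#' bioequivalence_compare(a, b)
#' @export
bioequivalence_compare <- function(test, reference, margin_pct = 20) {
  vals <- function(x) {
    x <- as_tibble(x)
    if (!all(c("cmax_ug_per_ml", "auc_ug_min_per_ml") %in% names(x))) {
      abort("metrics must have columns `cmax_ug_per_ml` and `auc_ug_min_per_ml`.")
    }
    c(cmax = x$cmax_ug_per_ml[1], auc = x$auc_ug_min_per_ml[1])
  }
  tv <- vals(test)
  rv <- vals(reference)
  if (any(rv <= 0)) abort("reference metrics must be positive.")
  out <- tibble(metric = names(tv),
                test = unname(tv), reference = unname(rv),
                pct_diff = unname(100 * abs(tv - rv) / rv))
  out <- mutate(out, pass = .data$pct_diff < margin_pct)
  structure(out, equivalent = all(out$pass), margin_pct = margin_pct)
}

#' Fold change between two exposure-metric sets
#'
#' Ratios `a / b` for Cmax and AUC, e.g. a cola scenario against the fasted
#' water reference scenario.
#'
#' @param metric_a,metric_b One-row data frames with columns
#'   `cmax_ug_per_ml` and `auc_ug_min_per_ml`.
#' @return A tibble with one row per metric and column `fold_change`.
#' @examples
#' a <- data.frame(cmax_ug_per_ml = 0.005, auc_ug_min_per_ml = 1.05)
#' b <- data.frame(cmax_ug_per_ml = 0.0017, auc_ug_min_per_ml = 0.35)
#' scenario_fold_change(a, b)
#' @export
scenario_fold_change <- function(metric_a, metric_b) {
  a <- as_tibble(metric_a)
  b <- as_tibble(metric_b)
  need <- c("cmax_ug_per_ml", "auc_ug_min_per_ml")
  if (!all(need %in% names(a)) || !all(need %in% names(b))) {
    abort("metrics must have columns `cmax_ug_per_ml` and `auc_ug_min_per_ml`.")
  }
  aa <- c(a$cmax_ug_per_ml[1], a$auc_ug_min_per_ml[1])
  bb <- c(b$cmax_ug_per_ml[1], b$auc_ug_min_per_ml[1])
  if (any(bb <= 0)) abort("denominator metrics must be positive.")
  tibble(metric = c("cmax", "auc"), a = aa, b = bb, fold_change = aa / bb)
}
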