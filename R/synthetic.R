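# run code with a temporary RNG state, restoring the caller's stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Replicate noise model for synthetic observations
#'
#' Proportional (multiplicative) Gaussian noise: each replicate measurement
#' is `truth * (1 + cv * Z)` clipped at zero, emulating analytical error that
#' scales with concentration and triplicate mean/SD reporting.  Clipping
#' introduces a slight positive bias at near-zero concentrations.
#'
#' @param kind Only `"proportional_gaussian"` is implemented.
#' @param cv Coefficient of variation per replicate, >= 0.
#' @param replicates Number of replicates per time point, >= 1.
#' @param seed Optional default seed used by the generators.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(cv = 0.05, replicates = 3)
#' @export
noise_model <- function(kind = "proportional_gaussian", cv = 0.05,
                        replicates = 3, seed = NULL) {
  if (!identical(kind, "proportional_gaussian")) {
    abort("only `kind = \"proportional_gaussian\"` is implemented.")
  }
  if (cv < 0) abort("`cv` must be non-negative.")
  if (replicates < 1) abort("`replicates` must be at least 1.")
  structure(list(kind = kind, cv = cv, replicates = as.integer(replicates),
                 seed = seed),
            class = "noise_model")
}

#' Default sampling schedule for synthetic dissolution runs
#'
#' Every 2.5 min up to 20 min, then every 10 min up to 60 min — a plausible
#' bench schedule for a 1-h three-chamber dissolution experiment.
#'
#' @return Numeric vector of sampling times (min).
#' @export
default_sampling_times <- function() {
  c(seq(2.5, 20, by = 2.5), seq(30, 60, by = 10))
}

#' Generate a synthetic per-compartment observation dataset
#'
#' Simulates the ground truth with [simulate_gis()], then draws
#' `noise$replicates` noisy concentration realisations per sampling time and
#' chamber and reports their mean and SD, mimicking a triplicate bench
#' experiment.  Bit-reproducible for a fixed seed; the generating trajectory
#' and parameters are returned alongside so recovery experiments can compare
#' against truth.
#'
#' @param drug A [drug_properties()].
#' @param condition A [condition_config()].
#' @param params The generating [transit_parameters()].
#' @param sampling_times Sampling schedule (min) within the condition's
#'   duration.
#' @param noise A [noise_model()].
#' @param seed Integer seed (defaults to the noise model's seed).
#' @return A list of class `gis_dataset`: `observations` (tibble with
#'   `time_min`, `compartment`, `mean_conc_ug_per_ml`, `sd`, `n`),
#'   `replicates` (long tibble of individual draws), `truth` (the noise-free
#'   `gis_trajectory`), `params`, `seed`.
#' @examples
#' pre <- condition_preset(1)
#' ds <- generate_gis_dataset(drug_preset(), pre$condition, pre$params,
#'                            seed = 42)
#' head(ds$observations)
#' @export
generate_gis_dataset <- function(drug, condition, params,
                                 sampling_times = default_sampling_times(),
                                 noise = noise_model(), seed = noise$seed) {
  stopifnot(inherits(noise, "noise_model"))
  if (any(sampling_times < 0 | sampling_times > condition$duration)) {
    abort("`sampling_times` must lie within the condition's duration.")
  }
  truth <- simulate_gis(drug, condition, params,
                        times = sort(unique(sampling_times)))
  base <- as_tibble(truth)[, c("time_min", "compartment", "conc_ug_per_ml")]
  reps <- .with_seed(seed, {
    tidyr::crossing(base, replicate = seq_len(noise$replicates)) |>
      mutate(conc = pmax(0, .data$conc_ug_per_ml *
                           (1 + noise$cv * stats::rnorm(dplyr::n()))))
  })
  obs <- summarise(group_by(reps, .data$time_min, .data$compartment),
                   mean_conc_ug_per_ml = mean(.data$conc),
                   sd = stats::sd(.data$conc),
                   n = dplyr::n(), .groups = "drop")
  obs$sd[is.na(obs$sd)] <- 0
  structure(list(observations = arrange(obs, .data$time_min, .data$compartment),
                 replicates = reps[, c("time_min", "compartment",
                                       "replicate", "conc")],
                 truth = truth, params = params, seed = seed),
            class = "gis_dataset")
}

#' @export
print.gis_dataset <- function(x, ...) {
  cat("<gis_dataset> ", nrow(x$observations), " mean observations (",
      max(x$replicates$replicate), " replicates each), seed ",
      x$seed %||% "none", "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic titration dataset with known buffer capacity
#'
#' Constructs alternating base/acid titration records whose titrant volume is
#' `beta * |dpH| * V0 / c_titrant`, so that [buffer_capacity()] recovers
#' `true_beta` exactly in the noise-free case; optional proportional noise on
#' the titrant volume yields unbiased estimates in expectation.
#'
#' @param true_beta Target buffer capacity (mol/L per pH unit), > 0.
#' @param initial_volume Medium volume (L), > 0.
#' @param titrant_concentration Titrant strength (mol/L), > 0.
#' @param steps Number of records (0 gives an empty table).
#' @param delta_ph pH shift per record.
#' @param noise_cv Proportional noise CV on the titrant volume.
#' @param seed Integer seed.
#' @return A tibble of titration records (see [read_titration_records()]).
#' @examples
#' generate_titration_dataset(0.010, 0.300, 1, steps = 4, seed = 7)
#' @export
generate_titration_dataset <- function(true_beta, initial_volume,
                                       titrant_concentration, steps,
                                       delta_ph = 1, noise_cv = 0,
                                       seed = NULL) {
  if (true_beta <= 0 || initial_volume <= 0 || titrant_concentration <= 0 ||
      delta_ph <= 0 || noise_cv < 0) {
    abort("all generator inputs must be positive (noise_cv non-negative).")
  }
  if (steps < 1) {
    return(tibble(v0_L = numeric(0), c_titrant_M = numeric(0),
                  v_added_L = numeric(0), sign = numeric(0),
                  ph_before = numeric(0), ph_after = numeric(0)))
  }
  sign <- rep_len(c(1, -1), steps)
  v_added <- true_beta * delta_ph * initial_volume / titrant_concentration
  v_added <- .with_seed(seed,
    pmax(0, v_added * (1 + noise_cv * stats::rnorm(steps))))
  ph_before <- rep(2.5, steps)
  tibble(v0_L = initial_volume, c_titrant_M = titrant_concentration,
         v_added_L = v_added, sign = sign,
         ph_before = ph_before, ph_after = ph_before + sign * delta_ph)
}
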