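# Tabular I/O: comma-separated UTF-8 text with dot decimals throughout, JSON
# for reports, YAML for condition configs.  Readers validate their schema and
# report malformed rows with line numbers.

.read_validated_csv <- function(path, required, label) {
  if (!file.exists(path)) abort(paste0(label, " file not found: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         locale = readr::locale(decimal_mark = "."))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(paste0("malformed ", label, " file '", path, "': ",
                 nrow(probs), " parsing problem(s), first at row ",
                 probs$row[1], " (", probs$expected[1], " expected, got '",
                 probs$actual[1], "')."))
  }
  missing <- setdiff(names(required), names(out))
  if (length(missing) > 0) {
    abort(paste0(label, " file '", path, "' is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in names(required)) {
    if (required[[col]] == "numeric" && !is.numeric(out[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(out[[col]]))) &
                     !is.na(out[[col]]))
      abort(paste0("column `", col, "` of ", label, " file '", path,
                   "' must be numeric",
                   if (length(bad) > 0) {
                     paste0(" (first offending data row: ", bad[1], ")")
                   } else "", "."))
    }
  }
  out
}

#' Read / write per-compartment observation tables
#'
#' Tidy concentration-time observations: one row per sampling time and
#' chamber with the replicate mean, standard deviation and replicate count.
#'
#' @param path File path (CSV, dot decimal separator).
#' @return `read_observations()` returns a tibble with columns `time_min`,
#'   `compartment`, `mean_conc_ug_per_ml`, `sd`, `n`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' obs <- data.frame(time_min = 5, compartment = "stomach",
#'                   mean_conc_ug_per_ml = 20, sd = 1, n = 3)
#' write_observations(obs, tf)
#' read_observations(tf)
#' @export
read_observations <- function(path) {
  out <- .read_validated_csv(
    path,
    c(time_min = "numeric", compartment = "character",
      mean_conc_ug_per_ml = "numeric", sd = "numeric", n = "numeric"),
    "observation")
  bad <- !out$compartment %in% c("stomach", "duodenum", "jejunum")
  if (any(bad)) {
    abort(paste0("unknown compartment label(s) in '", path, "': ",
                 paste(unique(out$compartment[bad]), collapse = ", ")))
  }
  out
}

#' @rdname read_observations
#' @param observations Data frame of observations to write.
#' @export
write_observations <- function(observations, path) {
  readr::write_csv(as_tibble(observations), path)
  invisible(path)
}

#' Read / write per-study disposition parameter tables
#'
#' @param path File path (CSV); scientific notation such as `9.869E-06`
#'   parses locale-independently.
#' @return `read_pk_studies()` returns a tibble with columns `study_id`,
#'   `ka_per_h`, `k10_per_h`, `k12_per_h`, `k21_per_h`, `v_over_f_L`.
#' @examples
#' read_pk_studies(system.file("extdata", "pk_studies_loratadine.csv",
#'                             package = "gisim"))
#' @export
read_pk_studies <- function(path) {
  .read_validated_csv(
    path,
    c(study_id = "character", ka_per_h = "numeric", k10_per_h = "numeric",
      k12_per_h = "numeric", k21_per_h = "numeric", v_over_f_L = "numeric"),
    "PK study")
}

#' @rdname read_pk_studies
#' @param studies Data frame of per-study parameters to write.
#' @export
write_pk_studies <- function(studies, path) {
  readr::write_csv(as_tibble(studies), path)
  invisible(path)
}

#' Read / write titration record tables
#'
#' @param path File path (CSV) with columns `v0_L`, `c_titrant_M`,
#'   `v_added_L`, `sign`, `ph_before`, `ph_after`.
#' @return `read_titration_records()` returns the validated tibble.
#' @export
read_titration_records <- function(path) {
  .read_validated_csv(
    path,
    c(v0_L = "numeric", c_titrant_M = "numeric", v_added_L = "numeric",
      sign = "numeric", ph_before = "numeric", ph_after = "numeric"),
    "titration")
}

#' @rdname read_titration_records
#' @param records Data frame of titration records to write.
#' @export
write_titration_records <- function(records, path) {
  readr::write_csv(as_tibble(records), path)
  invisible(path)
}

#' Export / import a simulated trajectory as tidy delimited text
#'
#' @param traj A `gis_trajectory` (for writing) or file path (for reading).
#' @param path Output file path (CSV).
#' @return `read_gis_trajectory()` returns a plain tibble with the exported
#'   columns (it does not reconstruct the simulation attributes).
#' @export
write_gis_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "gis_trajectory"))
  readr::write_csv(
    as_tibble(traj)[, c("time_min", "compartment", "volume_ml",
                        "dissolved_ug", "solid_ug", "precipitated_ug",
                        "conc_ug_per_ml", "ds")],
    path)
  invisible(path)
}

#' @rdname write_gis_trajectory
#' @export
read_gis_trajectory <- function(path) {
  .read_validated_csv(
    path,
    c(time_min = "numeric", compartment = "character",
      volume_ml = "numeric", dissolved_ug = "numeric", solid_ug = "numeric",
      precipitated_ug = "numeric", conc_ug_per_ml = "numeric",
      ds = "numeric"),
    "trajectory")
}

#' Read / write a condition configuration as YAML
#'
#' The YAML mirrors the [condition_config()] fields; pH profiles are stored
#' as parallel `time_min` / `ph` lists.
#'
#' @param path YAML file path.
#' @return `read_condition_config()` returns a [condition_config()].
#' @examples
#' tf <- tempfile(fileext = ".yaml")
#' write_condition_config(condition_preset(1)$condition, tf)
#' read_condition_config(tf)
#' @export
read_condition_config <- function(path) {
  if (!file.exists(path)) abort(paste0("condition config not found: ", path))
  raw <- yaml::read_yaml(path)
  required <- c("label", "t_half_gastric")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("condition config '", path, "' is missing field(s): ",
                 paste(missing, collapse = ", ")))
  }
  prof <- function(x, default) {
    if (is.null(x)) return(default)
    ph_profile(unlist(x$time_min), unlist(x$ph))
  }
  condition_config(
    label = raw$label,
    gastric_initial_volume = raw$gastric_initial_volume %||% 300,
    gastric_residual_floor = raw$gastric_residual_floor %||% 5,
    duodenal_volume = raw$duodenal_volume %||% 50,
    jejunal_initial_volume = raw$jejunal_initial_volume %||% 0,
    k_sec_s = raw$k_sec_s %||% 1,
    k_sec_d = raw$k_sec_d %||% 1,
    t_half_gastric = raw$t_half_gastric,
    gastric_ph_profile = prof(raw$gastric_ph_profile, ph_profile(0, 2.0)),
    duodenal_ph_profile = prof(raw$duodenal_ph_profile, ph_profile(0, 6.5)),
    jejunal_ph_profile = prof(raw$jejunal_ph_profile, ph_profile(0, 6.5)),
    duration = raw$duration %||% 60)
}

#' @rdname read_condition_config
#' @param condition A [condition_config()] to write.
#' @export
write_condition_config <- function(condition, path) {
  stopifnot(inherits(condition, "condition_config"))
  as_prof <- function(p) list(time_min = p$time_min, ph = p$ph)
  yaml::write_yaml(list(
    label = condition$label,
    gastric_initial_volume = condition$gastric_initial_volume,
    gastric_residual_floor = condition$gastric_residual_floor,
    duodenal_volume = condition$duodenal_volume,
    jejunal_initial_volume = condition$jejunal_initial_volume,
    k_sec_s = condition$k_sec_s,
    k_sec_d = condition$k_sec_d,
    t_half_gastric = condition$t_half_gastric,
    gastric_ph_profile = as_prof(condition$gastric_ph_profile),
    duodenal_ph_profile = as_prof(condition$duodenal_ph_profile),
    jejunal_ph_profile = as_prof(condition$jejunal_ph_profile),
    duration = condition$duration), path)
  invisible(path)
}

#' Write / read an exposure report as JSON
#'
#' @param report A named list or one-row data frame of exposure results.
#' @param path JSON file path.
#' @return `read_exposure_report()` returns the parsed list.
#' @export
write_exposure_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_exposure_report
#' @export
read_exposure_report <- function(path) {
  if (!file.exists(path)) abort(paste0("exposure report not found: ", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
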