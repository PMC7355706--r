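#' Drug property set for a monobasic weak base
#'
#' Bundles the dose and the solubility model used throughout the transit
#' simulation.  Solubility follows the Henderson--Hasselbalch relation for a
#' monobasic weak base, `S(pH) = S0 * (1 + 10^(pKa - pH))`, where `S0` is the
#' intrinsic solubility of the neutral species; an optional table of measured
#' solubility--pH pairs overrides the analytic curve by linear interpolation.
#'
#' @param name Character label for the compound.
#' @param dose_ug Administered dose in micrograms. Must be positive.
#' @param pka Basic pKa (0 < pKa < 14).
#' @param s0_ug_per_ml Intrinsic solubility of the neutral species (ug/mL).
#' @param logp Informational octanol/water log partition coefficient.
#' @param mw Informational molecular weight (g/mol).
#' @param solubility_overrides Optional data frame with columns `ph` and
#'   `s_ug_per_ml`; when supplied, [solubility_at_ph()] linearly interpolates
#'   this table instead of evaluating the Henderson--Hasselbalch curve.
#' @return An object of class `drug_properties`.
#' @examples
#' drug_properties("example base", dose_ug = 1e4, pka = 5.3, s0_ug_per_ml = 4)
#' @export
drug_properties <- function(name, dose_ug, pka, s0_ug_per_ml,
                            logp = NA_real_, mw = NA_real_,
                            solubility_overrides = NULL) {
  if (!is.numeric(dose_ug) || length(dose_ug) != 1L || dose_ug <= 0) {
    abort("`dose_ug` must be a single positive number.")
  }
  if (!is.numeric(pka) || length(pka) != 1L || pka <= 0 || pka >= 14) {
    abort("`pka` must lie strictly within (0, 14).")
  }
  if (!is.numeric(s0_ug_per_ml) || length(s0_ug_per_ml) != 1L ||
      s0_ug_per_ml <= 0) {
    abort("`s0_ug_per_ml` must be a single positive number.")
  }
  if (!is.null(solubility_overrides)) {
    solubility_overrides <- as_tibble(solubility_overrides)
    required <- c("ph", "s_ug_per_ml")
    missing <- setdiff(required, names(solubility_overrides))
    if (length(missing) > 0) {
      abort(paste0("`solubility_overrides` is missing column(s): ",
                   paste(missing, collapse = ", ")))
    }
    if (any(solubility_overrides$ph < 0 | solubility_overrides$ph > 14)) {
      abort("override pH values must lie within [0, 14].")
    }
    solubility_overrides <- arrange(solubility_overrides, .data$ph)
  }
  structure(
    list(name = name, dose_ug = dose_ug, pka = pka,
         s0_ug_per_ml = s0_ug_per_ml, logp = logp, mw = mw,
         solubility_overrides = solubility_overrides),
    class = "drug_properties"
  )
}

#' @export
print.drug_properties <- function(x, ...) {
  cat("<drug_properties> ", x$name, "\n",
      "  dose: ", x$dose_ug, " ug | pKa(base): ", x$pka,
      " | S0: ", x$s0_ug_per_ml, " ug/mL\n", sep = "")
  if (!is.null(x$solubility_overrides)) {
    cat("  solubility overrides at", nrow(x$solubility_overrides),
        "pH points\n")
  }
  invisible(x)
}

#' Shipped drug presets
#'
#' Two property sets for loratadine (10 mg immediate-release tablet) are
#' shipped.  `"loratadine"` (the default throughout) uses the experimentally
#' grounded basic pKa 5.3 / logP 3.9 pair; `"loratadine_admet"` carries the
#' alternative computationally estimated pair (pKa 3.83, cLogP 4.54).  Both
#' share the same intrinsic solubility, a package-level calibration constant
#' (see the methods vignette for how it was fixed).
#'
#' @param name `"loratadine"` or `"loratadine_admet"`.
#' @return A [drug_properties()] object.
#' @examples
#' drug_preset("loratadine")
#' @export
drug_preset <- function(name = c("loratadine", "loratadine_admet")) {
  name <- match.arg(name)
  switch(name,
    loratadine = drug_properties(
      name = "loratadine", dose_ug = 10000, pka = 5.3,
      s0_ug_per_ml = .gisim_s0_default, logp = 3.9, mw = 382.89),
    loratadine_admet = drug_properties(
      name = "loratadine (in-silico property estimate)", dose_ug = 10000,
      pka = 3.83, s0_ug_per_ml = .gisim_s0_default, logp = 4.54, mw = 382.89)
  )
}

#' pH-dependent solubility of a weak base
#'
#' Evaluates `S(pH) = S0 * (1 + 10^(pKa - pH))` for a monobasic weak base, or
#' linearly interpolates the drug's measured override table when one is
#' present (constant extrapolation beyond its pH range).
#'
#' @param drug A [drug_properties()] object.
#' @param ph Numeric vector of pH values in \[0, 14\].
#' @return Numeric vector of solubilities (ug/mL), one per `ph`.
#' @examples
#' d <- drug_preset("loratadine")
#' solubility_at_ph(d, c(2, 6.5))
#' @export
solubility_at_ph <- function(drug, ph) {
  stopifnot(inherits(drug, "drug_properties"))
  if (any(!is.finite(ph)) || any(ph < 0 | ph > 14)) {
    abort("`ph` must lie within [0, 14].")
  }
  ov <- drug$solubility_overrides
  if (!is.null(ov) && nrow(ov) >= 1) {
    if (nrow(ov) == 1L) return(rep(ov$s_ug_per_ml, length(ph)))
    return(approx(ov$ph, ov$s_ug_per_ml, xout = ph, rule = 2)$y)
  }
  drug$s0_ug_per_ml * (1 + 10^(drug$pka - ph))
}

#' Degree of supersaturation
#'
#' The dissolved concentration divided by the thermodynamic solubility at the
#' same time point; values above 1 flag a supersaturated solution.
#'
#' @param c Dissolved concentration(s), >= 0.
#' @param ceq Thermodynamic solubility(ies), > 0.
#' @return `c / ceq`, vectorised.
#' @examples
#' degree_of_supersaturation(5, 2)
#' @export
degree_of_supersaturation <- function(c, ceq) {
  if (any(!is.finite(ceq)) || any(ceq <= 0)) {
    abort("`ceq` must be positive: degree of supersaturation is undefined otherwise.")
  }
  if (any(c < 0)) abort("`c` must be non-negative.")
  c / ceq
}

#' Buffer capacity from titration records
#'
#' For each titration record, computes the equivalents of strong acid or base
#' added per litre of medium, `dn = c_titrant * v_added / v0`, and the buffer
#' capacity `beta = dn / |dpH|`.  Acid and base titrations both yield a
#' positive beta.
#'
#' @param records Data frame with columns `v0_L` (initial volume, L),
#'   `c_titrant_M` (titrant concentration, mol/L), `v_added_L` (titrant volume
#'   added, L), `sign` (+1 base, -1 acid), `ph_before`, `ph_after`.
#' @return A tibble with the input columns plus `delta_ph`,
#'   `equivalents_per_liter` (mol/L) and `beta` (mol/L per pH unit).
#' @examples
#' buffer_capacity(data.frame(v0_L = 0.3, c_titrant_M = 1, v_added_L = 0.003,
#'                            sign = 1, ph_before = 2, ph_after = 3))
#' @export
buffer_capacity <- function(records) {
  records <- as_tibble(records)
  required <- c("v0_L", "c_titrant_M", "v_added_L", "sign",
                "ph_before", "ph_after")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(paste0("titration records are missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(records$v0_L <= 0) || any(records$c_titrant_M <= 0)) {
    abort("initial volumes and titrant concentrations must be positive.")
  }
  if (any(records$v_added_L < 0)) {
    abort("`v_added_L` must be non-negative.")
  }
  delta <- records$ph_after - records$ph_before
  if (any(delta == 0)) {
    abort("degenerate titration: `ph_after` equals `ph_before` in at least one record.")
  }
  mutate(records,
         delta_ph = delta,
         equivalents_per_liter =
           .data$c_titrant_M * .data$v_added_L / .data$v0_L,
         beta = .data$equivalents_per_liter / abs(delta))
}

#' Van Slyke buffer capacity of a monoprotic buffer
#'
#' Analytic buffer capacity `beta = ln(10) * C * Ka * [H+] / (Ka + [H+])^2`
#' of a monoprotic buffer of total concentration `C`, excluding the water
#' autoprotolysis terms.  Maximal (`ln(10) * C / 4`) at `ph == pka`.  Useful
#' as an independent cross-check for titration-based estimates.
#'
#' @param buffer_concentration Total buffer concentration (mol/L), >= 0.
#' @param pka Acid dissociation pKa of the buffer species.
#' @param ph pH value(s) at which to evaluate the capacity.
#' @return Buffer capacity in mol/L per pH unit, vectorised over `ph`.
#' @examples
#' van_slyke_buffer_capacity(0.0287, 7.21, 6.5)
#' @export
van_slyke_buffer_capacity <- function(buffer_concentration, pka, ph) {
  if (any(buffer_concentration < 0)) {
    abort("`buffer_concentration` must be non-negative.")
  }
  ka <- 10^(-pka)
  h <- 10^(-ph)
  log(10) * buffer_concentration * ka * h / (ka + h)^2
}
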