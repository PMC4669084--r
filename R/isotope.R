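#' Vienna Pee Dee Belemnite 13C/12C reference ratio
#'
#' The international carbon-isotope reference ratio used throughout the
#' delta-notation conversions.
#'
#' @format A length-one numeric, 0.0112372.
#' @export
R_VPDB <- 0.0112372

#' Convert delta-13C to an isotope ratio
#'
#' Converts per-mil delta-13C values (relative to VPDB) to 13C/12C isotope
#' ratios: `R = (delta/1000 + 1) * R_VPDB`.
#'
#' @param delta Numeric vector of delta-13C values in per mil vs VPDB.
#'   Must be strictly greater than -1000 (the ratio must stay positive).
#' @return Numeric vector of 13C/12C ratios.
#' @seealso [ratio_to_delta()], [delta_to_fraction()]
#' @examples
#' delta_to_ratio(0)    # R_VPDB
#' delta_to_ratio(-25)
#' @export
delta_to_ratio <- function(delta) {
  stopifnot(is.numeric(delta))
  bad <- !is.na(delta) & delta <= -1000
  if (any(bad)) {
    stop("delta-13C must be > -1000 per mil; offending value(s): ",
         paste(format(delta[bad][seq_len(min(5, sum(bad)))]), collapse = ", "))
  }
  (delta / 1000 + 1) * R_VPDB
}

#' Convert an isotope ratio to delta-13C
#'
#' Inverse of [delta_to_ratio()].
#'
#' @param ratio Numeric vector of 13C/12C ratios (>= 0).
#' @return Numeric vector of delta-13C values in per mil vs VPDB.
#' @export
ratio_to_delta <- function(ratio) {
  stopifnot(is.numeric(ratio))
  if (any(ratio < 0, na.rm = TRUE)) stop("isotope ratio must be non-negative")
  (ratio / R_VPDB - 1) * 1000
}

#' Convert an isotope ratio to an atom fraction
#'
#' `F = R / (R + 1)`, the fraction of carbon atoms that are 13C.
#'
#' @param ratio Numeric vector of 13C/12C ratios (>= 0).
#' @return Numeric vector of atom fractions in `[0, 1)`.
#' @export
ratio_to_fraction <- function(ratio) {
  stopifnot(is.numeric(ratio))
  if (any(ratio < 0, na.rm = TRUE)) stop("isotope ratio must be non-negative")
  ratio / (ratio + 1)
}

#' Convert an atom fraction to an isotope ratio
#'
#' Inverse of [ratio_to_fraction()]: `R = F / (1 - F)`.
#'
#' @param fraction Numeric vector of atom fractions in `[0, 1)`.
#' @return Numeric vector of 13C/12C ratios.
#' @export
fraction_to_ratio <- function(fraction) {
  stopifnot(is.numeric(fraction))
  if (any(fraction < 0 | fraction >= 1, na.rm = TRUE)) {
    stop("atom fraction must lie in [0, 1)")
  }
  fraction / (1 - fraction)
}

#' Convert delta-13C to an atom fraction
#'
#' Composition of [delta_to_ratio()] and [ratio_to_fraction()].
#'
#' @inheritParams delta_to_ratio
#' @return Numeric vector of atom fractions 13C/(13C + 12C).
#' @examples
#' delta_to_fraction(0)  # natural-abundance fraction, ~0.011112
#' @export
delta_to_fraction <- function(delta) {
  ratio_to_fraction(delta_to_ratio(delta))
}

#' Convert an atom fraction to delta-13C
#'
#' Inverse of [delta_to_fraction()]. Heavily labelled material maps to very
#' large deltas (an atom fraction of 0.97 corresponds to about 2.88e6 per mil).
#'
#' @inheritParams fraction_to_ratio
#' @return Numeric vector of delta-13C values in per mil vs VPDB.
#' @export
fraction_to_delta <- function(fraction) {
  ratio_to_delta(fraction_to_ratio(fraction))
}

#' Concentration-weighted combination of gas- and water-phase delta-13C
#'
#' Combines headspace CO2 and dissolved inorganic carbon into the delta-13C of
#' total CO2 in a vial, as the concentration-weighted average of the two
#' phases. A fractionation correction (default +1 per mil) is added to the
#' gas-phase delta before weighting; it is a signed, configurable offset
#' because gas-water CO2 equilibrium fractionation depends on which phase the
#' correction is referred to.
#'
#' @param gas_conc,water_conc Non-negative CO2 carbon quantities in the
#'   headspace and water phase, in a common unit (e.g. ug C per vial).
#' @param gas_delta,water_delta delta-13C (per mil) of each phase.
#' @param gas_correction Per-mil offset added to `gas_delta` before weighting.
#'   Default `1`.
#' @return Numeric vector of combined delta-13C values (per mil).
#' @examples
#' combine_phases(60, -20, 40, -18)  # -18.6
#' @export
combine_phases <- function(gas_conc, gas_delta, water_conc, water_delta,
                           gas_correction = 1) {
  stopifnot(is.numeric(gas_conc), is.numeric(water_conc))
  if (any(gas_conc < 0, na.rm = TRUE) || any(water_conc < 0, na.rm = TRUE)) {
    stop("phase concentrations must be non-negative")
  }
  total <- gas_conc + water_conc
  if (any(total <= 0, na.rm = TRUE)) {
    stop("no CO2 to combine: gas and water concentrations are both zero")
  }
  ((gas_delta + gas_correction) * gas_conc + water_delta * water_conc) / total
}

#' Excess 13C of a sample over a background control
#'
#' The tracer-attribution quantity: the difference in atom fraction 13C
#' between a labelled sample and a time-matched unlabelled background,
#' `E = F_sample - F_background`. Negative values (sample below background,
#' possible from measurement noise) are retained and flagged with a warning
#' rather than clipped, because clipping to zero would bias cumulative sums.
#'
#' @param delta_sample,delta_background delta-13C (per mil) of the sample and
#'   the background control.
#' @param quiet Suppress the negative-excess warning. Default `FALSE`.
#' @return Numeric vector of atom-fraction differences.
#' @export
excess_13c <- function(delta_sample, delta_background, quiet = FALSE) {
  e <- delta_to_fraction(delta_sample) - delta_to_fraction(delta_background)
  n_neg <- sum(e < 0, na.rm = TRUE)
  if (n_neg > 0 && !quiet) {
    warning(n_neg, " negative excess-13C value(s) retained (sample below ",
            "background); not clipped to zero", call. = FALSE)
  }
  e
}

#' Substrate-derived carbon from excess 13C
#'
#' Attributes carbon to the labelled substrate: the product of excess 13C and
#' the total carbon quantity, divided by the substrate's atom fraction 13C
#' (0.97 for the lignocellulose tracer).
#'
#' @param excess Atom-fraction excess 13C (from [excess_13c()]).
#' @param total_c Total carbon quantity (e.g. total CO2 as ug C per vial);
#'   the result carries the same unit.
#' @param substrate A [substrate_spec()], or a bare atom fraction in (0, 1).
#' @return Substrate-derived carbon, same unit as `total_c`.
#' @examples
#' tracer_carbon(0.001, 100, substrate_spec(0.97, 0.15))
#' @export
tracer_carbon <- function(excess, total_c, substrate) {
  f <- if (inherits(substrate, "substrate_spec")) {
    substrate$atom_fraction_13c
  } else {
    substrate
  }
  stopifnot(is.numeric(f), length(f) == 1L)
  if (!is.finite(f) || f <= 0) {
    stop("substrate atom fraction 13C must be positive")
  }
  if (any(total_c < 0, na.rm = TRUE)) stop("total carbon must be non-negative")
  excess * total_c / f
}

#' Specify a labelled or unlabelled substrate pool
#'
#' @param atom_fraction_13c Atom fraction 13C of the substrate, in (0, 1);
#'   0.97 for the labelled lignocellulose.
#' @param dose_mg_c_per_ml Dose as mg C per mL wet sediment (0.15 for
#'   lignocellulose; 0.23 / 0.47 for the low / high diatom amendments).
#' @param cn_ratio Molar C:N ratio of the substrate (107 for the
#'   lignocellulose); metadata only.
#' @return An object of class `substrate_spec`.
#' @export
substrate_spec <- function(atom_fraction_13c, dose_mg_c_per_ml,
                           cn_ratio = NA_real_) {
  stopifnot(is.numeric(atom_fraction_13c), length(atom_fraction_13c) == 1L,
            is.numeric(dose_mg_c_per_ml), length(dose_mg_c_per_ml) == 1L)
  if (atom_fraction_13c <= 0 || atom_fraction_13c >= 1) {
    stop("atom_fraction_13c must lie strictly in (0, 1)")
  }
  if (dose_mg_c_per_ml < 0) stop("dose must be non-negative")
  structure(
    list(atom_fraction_13c = atom_fraction_13c,
         dose_mg_c_per_ml = dose_mg_c_per_ml,
         cn_ratio = cn_ratio),
    class = "substrate_spec"
  )
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat(sprintf(
    "<substrate_spec> %.4g atom%% 13C, dose %.3g mg C/mL wet sediment%s\n",
    100 * x$atom_fraction_13c, x$dose_mg_c_per_ml,
    if (is.na(x$cn_ratio)) "" else sprintf(", C:N %.3g", x$cn_ratio)))
  invisible(x)
}
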