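#' Read a per-vial CO2 measurement table
#'
#' Reads a delimited text table with one row per vial, columns `vial_id`,
#' `treatment`, `day`, `gas_conc`, `gas_delta`, `water_conc`, `water_delta`
#' (header required; UTF-8; decimal point). Concentrations are CO2 carbon per
#' vial in a consistent unit (ug C per vial throughout this package); deltas
#' are per mil vs VPDB.
#'
#' @param path Path to the table.
#' @param sep Field separator; default tab.
#' @return A validated data.frame of vial measurements.
#' @export
read_vial_table <- function(path, sep = "\t") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_vial_table(x)
}

#' @rdname read_vial_table
#' @param x A data.frame of vial measurements.
#' @export
validate_vial_table <- function(x) {
  needed <- c("vial_id", "treatment", "day",
              "gas_conc", "gas_delta", "water_conc", "water_delta")
  miss <- setdiff(needed, names(x))
  if (length(miss)) {
    stop("vial table is missing column(s): ", paste(miss, collapse = ", "))
  }
  num <- c("day", "gas_conc", "gas_delta", "water_conc", "water_delta")
  for (v in num) x[[v]] <- as.numeric(x[[v]])
  if (any(x$gas_conc < 0 | x$water_conc < 0, na.rm = TRUE)) {
    stop("phase concentrations must be non-negative")
  }
  if (any(x$gas_conc + x$water_conc <= 0, na.rm = TRUE)) {
    bad <- x$vial_id[x$gas_conc + x$water_conc <= 0]
    stop("no CO2 to combine in vial(s): ", paste(bad, collapse = ", "))
  }
  x
}

#' Per-vial combined delta, total CO2 and atom fraction
#'
#' Applies the two-phase combination to every vial and converts the combined
#' delta to an atom fraction.
#'
#' @param vials Vial measurement table (see [read_vial_table()]).
#' @param gas_correction Per-mil fractionation correction added to the
#'   gas-phase delta (default +1).
#' @return The input with columns `total_c` (gas + water CO2 carbon),
#'   `delta_total` and `fraction_total` appended.
#' @export
vial_totals <- function(vials, gas_correction = 1) {
  vials <- validate_vial_table(vials)
  vials$total_c <- vials$gas_conc + vials$water_conc
  vials$delta_total <- combine_phases(vials$gas_conc, vials$gas_delta,
                                      vials$water_conc, vials$water_delta,
                                      gas_correction)
  vials$fraction_total <- delta_to_fraction(vials$delta_total)
  vials
}

#' Time-matched background atom fractions from the CTRL treatment
#'
#' The background at each sampling day is the mean of the per-vial CTRL
#' combined-phase atom fractions at that day (mean of fractions, not the
#' fraction of the mean delta; the difference is second order at these
#' enrichment levels).
#'
#' @inheritParams vial_totals
#' @return data.frame with columns `day`, `background_fraction`, `n_ctrl`.
#' @export
background_fractions <- function(vials, gas_correction = 1) {
  tot <- vial_totals(vials, gas_correction)
  ctrl <- tot[tot$treatment == "CTRL", , drop = FALSE]
  if (nrow(ctrl) == 0L) stop("no CTRL vials in the measurement table")
  agg <- stats::aggregate(fraction_total ~ day, data = ctrl, FUN = mean)
  n <- stats::aggregate(fraction_total ~ day, data = ctrl, FUN = length)
  data.frame(day = agg$day, background_fraction = agg$fraction_total,
             n_ctrl = n$fraction_total)
}

#' Per-vial excess 13C against time-matched CTRL backgrounds
#'
#' For every non-CTRL vial, computes the excess atom fraction against the mean
#' CTRL atom fraction at the same sampling day.
#'
#' @inheritParams vial_totals
#' @param quiet Suppress the negative-excess warning from [excess_13c()].
#' @return data.frame of labelled vials with columns `total_c`,
#'   `fraction_total`, `background_fraction` and `excess`.
#' @export
excess_table <- function(vials, gas_correction = 1, quiet = FALSE) {
  tot <- vial_totals(vials, gas_correction)
  bg <- background_fractions(vials, gas_correction)
  lab <- tot[tot$treatment != "CTRL", , drop = FALSE]
  missing_days <- setdiff(unique(lab$day), bg$day)
  if (length(missing_days)) {
    stop("no CTRL background at day(s): ",
         paste(sort(missing_days), collapse = ", "))
  }
  lab$background_fraction <- bg$background_fraction[match(lab$day, bg$day)]
  lab$excess <- lab$fraction_total - lab$background_fraction
  n_neg <- sum(lab$excess < 0, na.rm = TRUE)
  if (n_neg > 0 && !quiet) {
    warning(n_neg, " negative excess-13C value(s) retained (sample below ",
            "background); not clipped to zero", call. = FALSE)
  }
  lab
}

standard_error <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Treatment-by-time mineralisation series
#'
#' Assembles per-vial tracer results into the mineralisation summary: total
#' respiration, lignocellulose-derived CO2, per-interval mineralisation rates,
#' and the cumulative percentage of added substrate carbon. Because sampling
#' is destructive, the per-day treatment means of the (cumulative) per-vial
#' quantities form the cumulative series; replicate-level quantities are
#' computed first and means/standard errors taken last. Day-0 substrate-derived
#' CO2 is forced to zero (the substrate has just been added; day-0 vials serve
#' as initial-condition QC). The CTRL substrate series is identically zero by
#' construction.
#'
#' @param vials Vial measurement table; concentrations in ug C per vial.
#' @param design An [experiment_design()].
#' @param gas_correction Per-mil gas-phase fractionation correction.
#' @param quiet Suppress negative-excess warnings.
#' @return data.frame with one row per treatment x day: `total_co2_mean`,
#'   `total_co2_se`, `substrate_co2_mean`, `substrate_co2_se` (ug C per mL wet
#'   sediment), `interval_rate` (ug C per mL wet sediment per day, for the
#'   interval ending at `day`; `NA` at day 0) and `cumulative_fraction_pct`
#'   (% of added lignocellulose C).
#' @export
mineralisation_series <- function(vials, design = experiment_design(),
                                  gas_correction = 1, quiet = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  vol <- design$sediment_volume_ml
  lc <- lignocellulose_spec(design)
  tot <- vial_totals(vials, gas_correction)
  unknown <- setdiff(unique(tot$treatment), design$treatments)
  if (length(unknown)) {
    stop("unknown treatment(s) in measurement table: ",
         paste(unknown, collapse = ", "))
  }
  ex <- excess_table(vials, gas_correction, quiet = quiet)
  ex$substrate_c <- tracer_carbon(ex$excess, ex$total_c, lc)
  ex$substrate_c[ex$day == 0] <- 0

  # per-vial quantities on the per-mL-wet-sediment scale
  tot$total_ml <- tot$total_c / vol
  ex$substrate_ml <- ex$substrate_c / vol

  days <- sort(unique(tot$day))
  out <- do.call(rbind, lapply(design$treatments, function(tr) {
    do.call(rbind, lapply(days, function(d) {
      ti <- tot$total_ml[tot$treatment == tr & tot$day == d]
      if (!length(ti)) return(NULL)
      if (tr == "CTRL") {
        sub_mean <- 0; sub_se <- 0
      } else {
        si <- ex$substrate_ml[ex$treatment == tr & ex$day == d]
        sub_mean <- mean(si); sub_se <- standard_error(si)
        if (d == 0) sub_se <- 0
      }
      data.frame(treatment = tr, day = d,
                 total_co2_mean = mean(ti), total_co2_se = standard_error(ti),
                 substrate_co2_mean = sub_mean, substrate_co2_se = sub_se)
    }))
  }))
  rownames(out) <- NULL

  out$interval_rate <- NA_real_
  out$cumulative_fraction_pct <- NA_real_
  dose_ug_ml <- lc$dose_mg_c_per_ml * 1000
  for (tr in unique(out$treatment)) {
    sel <- which(out$treatment == tr)
    sel <- sel[order(out$day[sel])]
    cum <- out$substrate_co2_mean[sel]
    rates <- interval_rates(out$day[sel], cum)
    out$interval_rate[sel] <- c(NA_real_, rates$rate)
    if (tr == "CTRL") {
      out$cumulative_fraction_pct[sel] <- 0
    } else {
      frac <- 100 * cum / dose_ug_ml
      if (any(frac < 0 - 1e-9 | frac > 100 + 1e-9, na.rm = TRUE)) {
        warning("cumulative substrate fraction outside [0, 100]% for ",
                tr, call. = FALSE)
      }
      out$cumulative_fraction_pct[sel] <- frac
    }
  }
  out
}

#' Per-interval rates from a cumulative series
#'
#' `rate_i = (value_i - value_{i-1}) / (day_i - day_{i-1})` for each sampling
#' interval. The sum of rates times interval lengths reconstructs the final
#' cumulative value exactly.
#'
#' @param days Strictly increasing sampling days starting at 0.
#' @param values Cumulative values at `days`.
#' @return data.frame with `day_start`, `day_end`, `rate` (value unit per day).
#' @export
interval_rates <- function(days, values) {
  stopifnot(length(days) == length(values), length(days) >= 1)
  if (is.unsorted(days, strictly = TRUE)) {
    stop("days must be strictly increasing")
  }
  if (days[1] != 0) stop("cumulative series must start at day 0")
  if (length(days) == 1L) {
    return(data.frame(day_start = numeric(0), day_end = numeric(0),
                      rate = numeric(0)))
  }
  data.frame(day_start = days[-length(days)], day_end = days[-1],
             rate = diff(values) / diff(days))
}
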