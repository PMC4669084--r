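#' Slurry experiment design
#'
#' Describes the destructive-sampling incubation design: four treatments
#' (unamended control `CTRL`; labelled lignocellulose only `LC`, the
#' 13C-CTRL; lignocellulose plus one or two doses of unlabelled diatom
#' detritus, `LC1D` / `LC2D`), five sampling days, and three replicate vials
#' per treatment and day.
#'
#' @param treatments Character vector of treatment codes. `CTRL` must be
#'   present (it provides the isotopic background at every timepoint).
#' @param timepoints Sampling days, strictly increasing, starting at 0.
#' @param replicates Replicate vials per treatment x day.
#' @param sediment_volume_ml Wet-sediment volume per vial (mL); concentrations
#'   per mL wet sediment divide per-vial quantities by this.
#' @param water_volume_ml Overlying-water volume per vial (mL); metadata.
#' @param substrates Named list mapping each treatment to a list of
#'   [substrate_spec()]s added to it. All labelled treatments must carry the
#'   same lignocellulose spec.
#' @param temperature_c Incubation temperature (degrees C); metadata.
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design()
#' @export
experiment_design <- function(treatments = c("CTRL", "LC", "LC1D", "LC2D"),
                              timepoints = c(0, 7, 14, 21, 28),
                              replicates = 3,
                              sediment_volume_ml = 20,
                              water_volume_ml = 20,
                              substrates = default_substrates(),
                              temperature_c = 10) {
  stopifnot(is.character(treatments), length(treatments) >= 2,
            is.numeric(timepoints), length(timepoints) >= 2)
  if (!"CTRL" %in% treatments) stop("design must include a CTRL treatment")
  if (is.unsorted(timepoints, strictly = TRUE) || timepoints[1] != 0) {
    stop("timepoints must be strictly increasing and start at 0")
  }
  if (replicates < 1) stop("replicates must be >= 1")
  if (sediment_volume_ml <= 0) stop("sediment volume must be positive")
  labelled <- setdiff(treatments, "CTRL")
  missing_sub <- setdiff(labelled, names(substrates))
  if (length(missing_sub)) {
    stop("no substrate specification for treatment(s): ",
         paste(missing_sub, collapse = ", "))
  }
  if (length(intersect("CTRL", names(substrates))) &&
      length(substrates[["CTRL"]]) > 0) {
    stop("CTRL must not carry a labelled substrate")
  }
  structure(
    list(treatments = treatments, timepoints = timepoints,
         replicates = replicates,
         sediment_volume_ml = sediment_volume_ml,
         water_volume_ml = water_volume_ml,
         substrates = substrates, temperature_c = temperature_c),
    class = "experiment_design"
  )
}

#' Default substrate map for the four-treatment design
#'
#' Lignocellulose at 97 atom% 13C and 0.15 mg C per mL wet sediment (C:N 107)
#' in every labelled treatment; unlabelled diatom detritus at 0.23 (LC1D) and
#' 0.47 (LC2D) mg C per mL wet sediment (natural abundance, taken as 1.1
#' atom%).
#'
#' @return Named list of lists of [substrate_spec()].
#' @export
default_substrates <- function() {
  lc <- substrate_spec(0.97, 0.15, cn_ratio = 107)
  nat <- delta_to_fraction(-18)
  list(
    LC   = list(lignocellulose = lc),
    LC1D = list(lignocellulose = lc,
                diatom = substrate_spec(nat, 0.23)),
    LC2D = list(lignocellulose = lc,
                diatom = substrate_spec(nat, 0.47))
  )
}

#' Lignocellulose substrate of a design's labelled treatments
#'
#' @param design An [experiment_design()].
#' @return The shared lignocellulose [substrate_spec()].
#' @export
lignocellulose_spec <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  labelled <- setdiff(design$treatments, "CTRL")
  specs <- lapply(labelled, function(tr) design$substrates[[tr]][["lignocellulose"]])
  if (any(vapply(specs, is.null, logical(1)))) {
    stop("every labelled treatment must carry a 'lignocellulose' substrate")
  }
  af <- vapply(specs, `[[`, numeric(1), "atom_fraction_13c")
  dose <- vapply(specs, `[[`, numeric(1), "dose_mg_c_per_ml")
  if (length(unique(af)) != 1L || length(unique(dose)) != 1L) {
    stop("labelled treatments carry different lignocellulose specifications")
  }
  specs[[1]]
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>\n",
      "  treatments: ", paste(x$treatments, collapse = ", "), "\n",
      "  sampling days: ", paste(x$timepoints, collapse = ", "), "\n",
      sprintf("  %d replicates; %g mL sediment + %g mL water per vial; %g degC\n",
              x$replicates, x$sediment_volume_ml, x$water_volume_ml,
              x$temperature_c),
      sep = "")
  invisible(x)
}
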