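#' Canonical PLFA names used throughout the package
#'
#' The set of phospholipid fatty acids tracked by the simulator and the
#' isolate-profile fixture. Names follow the usual shorthand:
#' `i`/`a` prefixes for iso/anteiso branching, `cy` for cyclopropyl,
#' `10Me` for mid-chain methyl, and `wN` for the double-bond position
#' (omega notation, written with `w`).
#'
#' @return Character vector of 14 PLFA names.
#' @export
canonical_plfas <- function() {
  c("14:0", "i15:0", "a15:0", "15:0", "i16:0", "16:0", "16:1w7", "10Me16:0",
    "a17:0", "cy17:0", "17:1w8", "18:0", "18:1w7", "18:1w9")
}

#' Normalise PLFA names to the package's canonical dialect
#'
#' Lower-level IRMS exports write the same fatty acid in several dialects;
#' this normaliser maps them onto one spelling: the Greek omega becomes `w`,
#' `omega`/`n-` notations become `w`, whitespace is dropped, and
#' case conventions for `i`/`a`/`cy`/`Me` prefixes are preserved.
#'
#' @param x Character vector of PLFA names.
#' @param aliases Optional named character vector of extra input -> canonical
#'   mappings applied after the rule-based normalisation.
#' @return Character vector of normalised names.
#' @examples
#' normalise_plfa(c("18:1ω7", "i15:0 ", "18:1 omega 9"))
#' @export
normalise_plfa <- function(x, aliases = NULL) {
  y <- trimws(x)
  y <- gsub("ω", "w", y)
  y <- gsub("omega", "w", y, ignore.case = TRUE)
  y <- gsub("[[:space:]]+", "", y)
  y <- sub("n-([0-9]+)$", "w\\1", y)
  if (!is.null(aliases)) {
    hit <- match(y, names(aliases))
    y[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  y
}

#' Biomarker group map
#'
#' Default assignment of PLFAs to broad microbial groups: the branched and
#' monounsaturated bacterial biomarkers i15:0, a15:0, i16:0 and 18:1w7, and
#' the microeukaryote biomarkers (C18 polyunsaturated fatty acids plus
#' 18:1w9). The C18 PUFA set is configurable because its membership is a
#' convention, not a measurement.
#'
#' @param bacteria Character vector of bacterial biomarker PLFAs.
#' @param c18_pufa C18 polyunsaturated fatty acids counted as eukaryotic.
#' @param eukaryote_extra Additional eukaryote biomarkers (default 18:1w9).
#' @return Named list of disjoint character vectors, class `biomarker_map`.
#' @export
biomarker_map <- function(bacteria = c("i15:0", "a15:0", "i16:0", "18:1w7"),
                          c18_pufa = c("18:2w6", "18:3w3", "18:3w6"),
                          eukaryote_extra = "18:1w9") {
  m <- list(bacteria = normalise_plfa(bacteria),
            eukaryotes = normalise_plfa(c(c18_pufa, eukaryote_extra)))
  if (length(intersect(m$bacteria, m$eukaryotes))) {
    stop("biomarker groups must be disjoint")
  }
  structure(m, class = c("biomarker_map", "list"))
}

#' Read a per-vial PLFA table
#'
#' Delimited text with one row per vial x PLFA: columns `vial_id`,
#' `treatment`, `day`, `plfa`, `conc` (declared unit, e.g. ug C per vial) and
#' `delta` (per mil vs VPDB). PLFA names are normalised on read.
#'
#' @param path Path to the table.
#' @param sep Field separator; default tab.
#' @return A validated data.frame.
#' @export
read_plfa_table <- function(path, sep = "\t") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_plfa_table(x)
}

#' @rdname read_plfa_table
#' @param x data.frame of PLFA measurements.
#' @export
validate_plfa_table <- function(x) {
  needed <- c("vial_id", "treatment", "day", "plfa", "conc", "delta")
  miss <- setdiff(needed, names(x))
  if (length(miss)) {
    stop("PLFA table is missing column(s): ", paste(miss, collapse = ", "))
  }
  x$plfa <- normalise_plfa(x$plfa)
  x$conc <- as.numeric(x$conc)
  x$delta <- as.numeric(x$delta)
  if (any(x$conc < 0, na.rm = TRUE)) stop("PLFA concentrations must be >= 0")
  dup <- stats::aggregate(conc ~ vial_id + plfa, data = x, FUN = length)
  if (any(dup$conc > 1)) {
    bad <- dup[dup$conc > 1, ]
    stop("duplicated PLFA within a vial: ",
         paste(unique(bad$plfa), collapse = ", "))
  }
  x
}

#' 13C incorporation into individual PLFAs
#'
#' For each labelled vial and PLFA, the incorporated lignocellulosic carbon is
#' the excess 13C (against the time- and name-matched mean CTRL delta) times
#' the PLFA concentration, divided by the substrate atom fraction 13C.
#' PLFAs present in a sample but absent from the background at that day are
#' excluded with a warning.
#'
#' @param plfa PLFA measurement table (see [read_plfa_table()]).
#' @param substrate [substrate_spec()] of the labelled substrate, or a bare
#'   atom fraction.
#' @param quiet Suppress negative-excess and exclusion warnings.
#' @return data.frame of labelled-vial rows with columns `background_delta`,
#'   `excess` and `incorporation` (same unit as `conc`).
#' @export
plfa_incorporation <- function(plfa, substrate = substrate_spec(0.97, 0.15),
                               quiet = FALSE) {
  plfa <- validate_plfa_table(plfa)
  ctrl <- plfa[plfa$treatment == "CTRL", , drop = FALSE]
  if (nrow(ctrl) == 0L) stop("no CTRL vials in the PLFA table")
  bg <- stats::aggregate(delta ~ day + plfa, data = ctrl, FUN = mean)
  names(bg)[names(bg) == "delta"] <- "background_delta"
  lab <- plfa[plfa$treatment != "CTRL", , drop = FALSE]
  lab <- merge(lab, bg, by = c("day", "plfa"), all.x = TRUE, sort = FALSE)
  orphan <- is.na(lab$background_delta)
  if (any(orphan)) {
    if (!quiet) {
      warning("excluding PLFA(s) without a CTRL background: ",
              paste(unique(lab$plfa[orphan]), collapse = ", "), call. = FALSE)
    }
    lab <- lab[!orphan, , drop = FALSE]
  }
  lab$excess <- excess_13c(lab$delta, lab$background_delta, quiet = quiet)
  lab$incorporation <- tracer_carbon(lab$excess, lab$conc, substrate)
  lab[order(lab$vial_id, lab$plfa), ]
}

#' Biomarker-group incorporation and biomass totals
#'
#' Sums per-PLFA incorporation (lignocellulosic-carbon uptake) and per-PLFA
#' concentration (relative biomass) over each biomarker group's members, per
#' vial. A group with no member present yields 0 with a warning.
#'
#' @param incorporation Output of [plfa_incorporation()].
#' @param map A [biomarker_map()].
#' @param quiet Suppress empty-group warnings.
#' @return data.frame with one row per vial x group: `incorporation`,
#'   `biomass_conc`, `n_plfas`.
#' @export
group_incorporation <- function(incorporation, map = biomarker_map(),
                                quiet = FALSE) {
  stopifnot(inherits(map, "biomarker_map"))
  vials <- unique(incorporation[c("vial_id", "treatment", "day")])
  out <- do.call(rbind, lapply(names(map), function(g) {
    members <- map[[g]]
    sub <- incorporation[incorporation$plfa %in% members, , drop = FALSE]
    if (nrow(sub) == 0L && !quiet) {
      warning("no PLFAs present for group '", g, "'; totals are 0",
              call. = FALSE)
    }
    res <- vials
    res$group <- g
    idx <- split(seq_len(nrow(sub)), sub$vial_id)
    res$incorporation <- vapply(res$vial_id, function(v) {
      i <- idx[[as.character(v)]]
      if (is.null(i)) 0 else sum(sub$incorporation[i])
    }, numeric(1))
    res$biomass_conc <- vapply(res$vial_id, function(v) {
      i <- idx[[as.character(v)]]
      if (is.null(i)) 0 else sum(sub$conc[i])
    }, numeric(1))
    res$n_plfas <- vapply(res$vial_id, function(v) {
      length(idx[[as.character(v)]])
    }, integer(1))
    res
  }))
  rownames(out) <- NULL
  out
}

#' Proportional 13C enrichment of individual PLFAs
#'
#' Normalises per-PLFA incorporation within each vial to proportions
#' I_PLFA / I_total. Normalisation runs over all measured PLFAs, before any
#' low-enrichment filtering.
#'
#' @param incorporation Output of [plfa_incorporation()].
#' @return The input with a `proportion` column; proportions sum to 1 within
#'   each vial.
#' @export
relative_enrichment <- function(incorporation) {
  totals <- tapply(incorporation$incorporation, incorporation$vial_id, sum)
  bad <- names(totals)[!is.na(totals) & totals <= 0]
  if (length(bad)) {
    stop("total incorporation is not positive in vial(s): ",
         paste(bad, collapse = ", "))
  }
  incorporation$proportion <-
    incorporation$incorporation /
    as.numeric(totals[as.character(incorporation$vial_id)])
  incorporation
}

#' Assemble a profile matrix from long-format proportions
#'
#' @param enrichment Output of [relative_enrichment()].
#' @param value Column to spread (default `"proportion"`).
#' @return Numeric matrix, rows = vials (rownames `vial_id`), columns = PLFAs;
#'   attributes `treatment` and `day` give the row metadata.
#' @export
enrichment_matrix <- function(enrichment, value = "proportion") {
  vials <- unique(enrichment[c("vial_id", "treatment", "day")])
  plfas <- sort(unique(enrichment$plfa))
  m <- matrix(0, nrow(vials), length(plfas),
              dimnames = list(vials$vial_id, plfas))
  i <- match(enrichment$vial_id, vials$vial_id)
  j <- match(enrichment$plfa, plfas)
  m[cbind(i, j)] <- enrichment[[value]]
  attr(m, "treatment") <- vials$treatment
  attr(m, "day") <- vials$day
  m
}

#' Drop PLFAs with negligible mean relative enrichment
#'
#' Removes PLFA columns whose grand-mean proportion across all profiles is
#' below the threshold (strictly less than; a mean of exactly the threshold is
#' retained).
#'
#' @param profiles Matrix from [enrichment_matrix()] (rows = profiles,
#'   columns = PLFAs).
#' @param threshold Minimum mean relative enrichment; default 0.001.
#' @return List with `profiles` (filtered matrix, metadata attributes kept),
#'   `retained` and `dropped` (character vectors of PLFA names).
#' @export
filter_low_enrichment <- function(profiles, threshold = 0.001) {
  stopifnot(is.matrix(profiles))
  means <- colMeans(profiles)
  keep <- !(means < threshold)
  filtered <- profiles[, keep, drop = FALSE]
  attr(filtered, "treatment") <- attr(profiles, "treatment")
  attr(filtered, "day") <- attr(profiles, "day")
  list(profiles = filtered,
       retained = colnames(profiles)[keep],
       dropped = colnames(profiles)[!keep])
}

#' Empirical logit transform
#'
#' `ln((p + tol) / (1 - p + tol))`: finite at both endpoints, monotone
#' increasing, and antisymmetric about p = 0.5. Used to normalise
#' compositional enrichment proportions before PLS.
#'
#' @param p Proportions in `[0, 1]`.
#' @param tol Tolerance added to numerator and denominator; default 0.1.
#' @return Transformed values.
#' @examples
#' empirical_logit(c(0, 0.5, 1))
#' @export
empirical_logit <- function(p, tol = 0.1) {
  stopifnot(is.numeric(p), is.numeric(tol), tol > 0)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("proportions must lie in [0, 1]")
  }
  log((p + tol) / (1 - p + tol))
}

#' Average enrichment profiles over vials
#'
#' Collapses a profile matrix to group means, either per treatment x day or
#' per treatment (time-averaged, the layout used for the 3-column PLS
#' response).
#'
#' @param profiles Matrix from [enrichment_matrix()].
#' @param by `"treatment_day"` or `"treatment"`.
#' @return Matrix of group-mean profiles with `treatment` (and `day`)
#'   attributes.
#' @export
average_profiles <- function(profiles, by = c("treatment", "treatment_day")) {
  by <- match.arg(by)
  tr <- attr(profiles, "treatment")
  day <- attr(profiles, "day")
  key <- if (by == "treatment") tr else paste(tr, day, sep = ".d")
  groups <- unique(key)
  m <- t(vapply(groups, function(g) colMeans(profiles[key == g, , drop = FALSE]),
                numeric(ncol(profiles))))
  rownames(m) <- groups
  attr(m, "treatment") <- tr[match(groups, key)]
  if (by == "treatment_day") attr(m, "day") <- day[match(groups, key)]
  m
}
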