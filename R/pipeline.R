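#' Write and read the pipeline's delimited tables
#'
#' All pipeline outputs are UTF-8, tab-separated text with a header row;
#' `read_result_table()` round-trips anything `write_result_table()` wrote.
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return `read_result_table()` returns a data.frame; `write_result_table()`
#'   returns `path` invisibly.
#' @export
write_result_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Assemble a run configuration
#'
#' Either a named scenario (data are simulated) or paths to measurement
#' tables. All analysis thresholds default to the values used throughout the
#' package: +1 per mil gas correction, 0.1 logit tolerance, 0.001 enrichment
#' filter.
#'
#' @param scenario Name passed to [reference_scenario()], or `NULL` to read
#'   tables from `vials_path` / `plfa_path`.
#' @param vials_path,plfa_path Input tables (used when `scenario` is `NULL`).
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed for any simulation.
#' @param gas_correction Per-mil gas-phase fractionation correction.
#' @param logit_tol Empirical-logit tolerance.
#' @param enrichment_filter Mean-relative-enrichment threshold.
#' @param n_components PLS components.
#' @param average_time Time-average enrichment profiles for the PLS (the
#'   3-column response layout). Default `TRUE`.
#' @param isolate_db_path Isolate-database matrix (default: the packaged
#'   synthetic fixture).
#' @param design An [experiment_design()].
#' @return List of class `run_config`.
#' @export
run_config <- function(scenario = "rates", vials_path = NULL, plfa_path = NULL,
                       out_dir = tempfile("lignoprime_run_"), seed = 1,
                       gas_correction = 1, logit_tol = 0.1,
                       enrichment_filter = 0.001, n_components = 2,
                       average_time = TRUE, isolate_db_path = NULL,
                       design = experiment_design()) {
  if (is.null(scenario)) {
    for (p in c(vials_path, plfa_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("without a scenario, vials_path and plfa_path must exist")
      }
    }
  }
  stopifnot(gas_correction > -100, gas_correction < 100,
            logit_tol > 0, logit_tol <= 1,
            enrichment_filter >= 0, enrichment_filter < 1,
            n_components >= 1)
  structure(list(scenario = scenario, vials_path = vials_path,
                 plfa_path = plfa_path, out_dir = out_dir, seed = seed,
                 gas_correction = gas_correction, logit_tol = logit_tol,
                 enrichment_filter = enrichment_filter,
                 n_components = n_components, average_time = average_time,
                 isolate_db_path = isolate_db_path, design = design),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()]; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "design")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Executes simulation (when a scenario is configured) or table ingestion,
#' then the mineralisation series, PLFA incorporation and biomarker-group
#' totals, the sequential ANOVA with Tukey post-hocs, and the PLS analyses
#' (treatment/time predictors, plus the isolate-database comparison). All
#' stage tables, a run manifest and a summary of headline quantities are
#' written to `config$out_dir` as delimited text / YAML.
#'
#' @param config A [run_config()] or a path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, a list with every stage result (`vials`, `plfa`,
#'   `mineralisation`, `incorporation`, `groups`, `anova`, `tukey`, `pls`,
#'   `isolate_comparison`, `summary`, `truth` when simulated).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- config$design
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  truth <- NULL
  if (!is.null(config$scenario)) {
    sim <- stage("simulate", {
      simulate_experiment(reference_scenario(config$scenario, design),
                          seed = config$seed)
    })
    vials <- sim$vials
    plfa <- sim$plfa
    truth <- sim$truth
    note("simulated scenario '", config$scenario, "' with seed ", config$seed)
  } else {
    vials <- stage("read vials", read_vial_table(config$vials_path))
    plfa <- stage("read plfa", read_plfa_table(config$plfa_path))
  }
  write_result_table(vials, file.path(config$out_dir, "vials.tsv"))
  write_result_table(plfa, file.path(config$out_dir, "plfa.tsv"))

  withCallingHandlers({
    mineral <- stage("mineralisation", {
      mineralisation_series(vials, design,
                            gas_correction = config$gas_correction)
    })
    lc <- lignocellulose_spec(design)
    incorporation <- stage("plfa incorporation", {
      plfa_incorporation(plfa, substrate = lc)
    })
    groups <- stage("group incorporation", group_incorporation(incorporation))
  }, warning = function(w) {
    note("warning: ", conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  write_result_table(mineral, file.path(config$out_dir, "mineralisation.tsv"))
  write_result_table(incorporation,
                     file.path(config$out_dir, "plfa_incorporation.tsv"))
  write_result_table(groups, file.path(config$out_dir, "group_incorporation.tsv"))

  # inferential stage: per-vial substrate-derived CO2, labelled treatments
  ex <- suppressWarnings(excess_table(vials, config$gas_correction))
  ex$substrate_ml <- tracer_carbon(ex$excess, ex$total_c, lc) /
    design$sediment_volume_ml
  ex_lab <- ex[ex$day > 0, , drop = FALSE]
  withCallingHandlers({
    anova_fit <- stage("anova", {
      fit_two_way_lm(ex_lab, "substrate_ml")
    })
    tukey <- stage("tukey", tukey_hsd(anova_fit, "treatment"))
  }, warning = function(w) {
    note("warning: ", conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  note(sprintf("ANOVA residual df: %d", stats::df.residual(anova_fit$model)))
  write_result_table(anova_fit$anova,
                     file.path(config$out_dir, "anova_substrate.tsv"))
  write_result_table(as.data.frame(tukey),
                     file.path(config$out_dir, "tukey_treatment.tsv"))

  # multivariate stage; skipped when there is no enrichment signal
  pls <- NULL; iso <- NULL; dropped <- character(0)
  inc_pos <- incorporation[incorporation$day > 0, , drop = FALSE]
  totals <- tapply(inc_pos$incorporation, inc_pos$vial_id, sum)
  if (all(totals > 0)) {
    pls <- stage("pls", {
      enr <- relative_enrichment(
        incorporation[incorporation$day > 0, , drop = FALSE])
      m <- enrichment_matrix(enr)
      flt <- filter_low_enrichment(m, config$enrichment_filter)
      dropped <- flt$dropped
      pls_enrichment_analysis(flt$profiles,
                              n_components = config$n_components,
                              logit_tol = config$logit_tol,
                              average_time = config$average_time)
    })
    if (length(dropped)) {
      note("dropped low-enrichment PLFA(s): ", paste(dropped, collapse = ", "))
    }
    write_result_table(pls$observation_coords,
                       file.path(config$out_dir, "pls_observations.tsv"))
    write_result_table(pls$variable_coords,
                       file.path(config$out_dir, "pls_variables.tsv"))
    iso <- stage("isolate comparison", {
      db <- if (is.null(config$isolate_db_path)) {
        read_isolate_db(
          system.file("extdata", "synthetic_isolate_plfa_profiles.tsv",
                      package = "lignoprime"),
          system.file("extdata", "synthetic_isolate_phyla.tsv",
                      package = "lignoprime"))
      } else {
        read_isolate_db(config$isolate_db_path)
      }
      enr <- relative_enrichment(
        incorporation[incorporation$day > 0, , drop = FALSE])
      prof <- average_profiles(enrichment_matrix(enr), by = "treatment")
      compare_to_isolates(prof, db)
    })
    write_result_table(iso$genus_correlations,
                       file.path(config$out_dir, "isolate_genus_correlations.tsv"))
  } else {
    note("no positive PLFA enrichment signal; PLS stages skipped")
  }

  final_day <- max(mineral$day)
  headline <- mineral[mineral$day == final_day & mineral$treatment != "CTRL", ]
  summary <- list(
    cumulative_fraction_pct = stats::setNames(
      as.list(headline$cumulative_fraction_pct), headline$treatment),
    first_interval_rate = stats::setNames(
      as.list(mineral$interval_rate[mineral$day == sort(unique(mineral$day))[2] &
                                      mineral$treatment != "CTRL"]),
      mineral$treatment[mineral$day == sort(unique(mineral$day))[2] &
                          mineral$treatment != "CTRL"]),
    group_incorporation_final = {
      g <- groups[groups$day == final_day, ]
      agg <- stats::aggregate(incorporation ~ treatment + group, data = g,
                              FUN = mean)
      stats::setNames(as.list(agg$incorporation),
                      paste(agg$treatment, agg$group, sep = "."))
    },
    pls_explained_pct = if (!is.null(pls)) {
      list(axis1 = pls$model$r2y[1],
           axes12 = pls$model$r2y_cum[min(2, pls$model$n_components)])
    } else {
      NULL
    }
  )
  yaml::write_yaml(summary, file.path(config$out_dir, "summary.yaml"))

  tables <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("lignoprime")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config[setdiff(names(config), c("design", "out_dir"))],
    design = list(treatments = design$treatments,
                  timepoints = design$timepoints,
                  replicates = design$replicates,
                  sediment_volume_ml = design$sediment_volume_ml),
    table_md5 = as.list(tools::md5sum(tables)),
    log = log_lines
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(vials = vials, plfa = plfa, mineralisation = mineral,
                 incorporation = incorporation, groups = groups,
                 anova = anova_fit, tukey = tukey, pls = pls,
                 isolate_comparison = iso, summary = summary,
                 truth = truth, out_dir = config$out_dir, log = log_lines))
}
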