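#' Two-way categorical linear model with sequential (type 1) ANOVA
#'
#' Fits `response ~ time + treatment (+ time:treatment)` with both explanatory
#' variables treated as categorical, and decomposes the variance sequentially
#' (type 1, in entry order). With categorical time this regression model is a
#' type 1 ANOVA.
#'
#' @param data data.frame holding the response and factor columns.
#' @param response Name of the response column.
#' @param time,treatment Names of the factor columns (coerced to factor).
#'   A factor with a single observed level is dropped from the model, so a
#'   design with one varying factor reduces to a one-way ANOVA.
#' @param with_interaction Include the time:treatment interaction term.
#' @return An object of class `anova_fit`: list with the underlying `lm` fit
#'   (`model`) and the sequential ANOVA table (`anova`, a data.frame with
#'   columns term, df, sum_sq, mean_sq, f_value, p_value).
#' @export
fit_two_way_lm <- function(data, response, time = "day",
                           treatment = "treatment", with_interaction = TRUE) {
  stopifnot(is.data.frame(data),
            all(c(response, time, treatment) %in% names(data)))
  d <- data.frame(
    .y = as.numeric(data[[response]]),
    .time = factor(data[[time]]),
    .treatment = factor(data[[treatment]])
  )
  use_time <- nlevels(d$.time) >= 2
  use_treatment <- nlevels(d$.treatment) >= 2
  if (!use_time && !use_treatment) {
    stop("neither factor has 2 or more observed levels")
  }
  rhs <- c(if (use_time) ".time", if (use_treatment) ".treatment",
           if (with_interaction && use_time && use_treatment) ".time:.treatment")
  form <- stats::reformulate(rhs, response = ".y")
  fit <- stats::lm(form, data = d)
  if (stats::df.residual(fit) < 1) {
    stop("model is saturated: no residual degrees of freedom")
  }
  a <- stats::anova(fit)
  term_names <- rownames(a)
  term_names <- sub("^\\.time:\\.treatment$", paste0(time, ":", treatment),
                    term_names)
  term_names[term_names == ".time"] <- time
  term_names[term_names == ".treatment"] <- treatment
  tab <- data.frame(term = term_names, df = a$Df, sum_sq = a$`Sum Sq`,
                    mean_sq = a$`Mean Sq`, f_value = a$`F value`,
                    p_value = a$`Pr(>F)`, row.names = NULL)
  structure(list(model = fit, anova = tab, data = d,
                 labels = c(time = time, treatment = treatment)),
            class = "anova_fit")
}

#' @export
print.anova_fit <- function(x, ...) {
  cat("Sequential (type 1) ANOVA\n")
  print(x$anova, digits = 5)
  invisible(x)
}

#' Tukey honest-significant-difference post-hoc comparisons
#'
#' All-pairs comparisons of the levels of one factor of a fitted model, with
#' family-wise adjustment from the studentized range distribution
#' (Tukey-Kramer when group sizes are unbalanced).
#'
#' @param fit An `anova_fit` from [fit_two_way_lm()].
#' @param factor Which factor to compare: `"time"`, `"treatment"`, or
#'   `"interaction"` (all treatment x time cells).
#' @param conf_level Confidence level of the intervals.
#' @return An object of class `tukey_result`: data.frame with columns
#'   `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(fit, factor = c("treatment", "time", "interaction"),
                      conf_level = 0.95) {
  stopifnot(inherits(fit, "anova_fit"))
  factor <- match.arg(factor)
  term <- switch(factor, time = ".time", treatment = ".treatment",
                 interaction = ".time:.treatment")
  col <- switch(factor, time = ".time", treatment = ".treatment", NULL)
  if (!is.null(col) && nlevels(fit$data[[col]]) < 2) {
    stop("factor '", factor, "' has fewer than 2 levels")
  }
  av <- stats::aov(stats::formula(fit$model), data = fit$data)
  th <- stats::TukeyHSD(av, which = term, conf.level = conf_level)[[term]]
  out <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                    lwr = th[, "lwr"], upr = th[, "upr"],
                    p_adj = th[, "p adj"], row.names = NULL)
  structure(out, class = c("tukey_result", "data.frame"))
}

#' Residual diagnostics tables for model validation
#'
#' Plot-ready tables for the usual linear-model checks: residuals vs fitted
#' values (variance homogeneity), theoretical vs standardised residual
#' quantiles (normality), and residuals vs each explanatory variable
#' (independence). No rendering is performed.
#'
#' @param fit An `anova_fit` from [fit_two_way_lm()].
#' @return List with data.frames `residuals_vs_fitted`, `qq` (sorted ascending
#'   in both coordinates) and `residuals_vs_factor`.
#' @export
diagnostics <- function(fit) {
  stopifnot(inherits(fit, "anova_fit"))
  r <- stats::residuals(fit$model)
  f <- stats::fitted(fit$model)
  s <- stats::sd(r)
  std <- if (isTRUE(s > 0)) (r - mean(r)) / s else r * 0
  n <- length(r)
  qq <- data.frame(
    theoretical = stats::qnorm(stats::ppoints(n)),
    standardised = sort(std)
  )
  rvx <- data.frame(
    time = fit$data$.time, treatment = fit$data$.treatment, residual = r,
    row.names = NULL
  )
  names(rvx)[1:2] <- unname(fit$labels[c("time", "treatment")])
  list(
    residuals_vs_fitted = data.frame(fitted = f, residual = r,
                                     row.names = NULL),
    qq = qq,
    residuals_vs_factor = rvx
  )
}
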