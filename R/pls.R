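#' NIPALS partial least squares regression with a multivariate response (PLS2)
#'
#' Iterative NIPALS estimation of PLS components maximising the covariance
#' between a predictor block X and a response block Y, with deflation of both
#' blocks after each component. Columns are mean-centred, and unit-variance
#' scaled when `scale = TRUE`. The sign of each component is fixed by making
#' the largest-magnitude element of its X-weight vector positive, so output is
#' deterministic.
#'
#' @param x Predictor matrix (observations x variables), no missing values.
#' @param y Response matrix or vector (observations x responses).
#' @param n_components Number of components; at most `min(nrow(x) - 1, ncol(x))`.
#' @param scale Scale columns of both blocks to unit variance. Default `TRUE`.
#' @param tol Convergence tolerance on the change of the X-weight vector.
#' @param max_iter Maximum NIPALS iterations per component.
#' @return An object of class `pls_model`: list with `x_weights` (p x a),
#'   `x_scores` (n x a), `x_loadings` (p x a), `y_loadings` (q x a),
#'   `y_scores` (n x a), `r2y` / `r2y_cum` (percent response-block variance
#'   explained per component and cumulatively), `r2x` / `r2x_cum` (same for
#'   the predictor block), `variable_coords` (correlations of X and Y columns
#'   with the X-scores, for a correlation biplot) and bookkeeping (`means`,
#'   `sds`, `scale`, `n_components`).
#' @export
nipals_pls2 <- function(x, y, n_components = 2, scale = TRUE,
                        tol = 1e-10, max_iter = 500) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric")
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(p))
  if (is.null(colnames(y))) colnames(y) <- paste0("Y", seq_len(q))
  a_max <- min(n - 1L, p)
  if (n_components > a_max) {
    stop("n_components must be <= min(nrow(x) - 1, ncol(x)) = ", a_max)
  }

  centre_scale <- function(m, label) {
    mu <- colMeans(m)
    mc <- sweep(m, 2, mu)
    if (scale) {
      s <- apply(mc, 2, stats::sd)
      zero <- s <= .Machine$double.eps^0.5
      if (any(zero)) {
        stop("zero-variance column(s) under scaling in ", label, ": ",
             paste(colnames(m)[zero], collapse = ", "))
      }
      mc <- sweep(mc, 2, s, "/")
    } else {
      s <- rep(1, ncol(m))
    }
    list(m = mc, mu = mu, s = s)
  }
  xs <- centre_scale(x, "x")
  ys <- centre_scale(y, "y")
  X <- xs$m; Y <- ys$m
  ssx_total <- sum(X^2)
  ssy_total <- sum(Y^2)

  W <- matrix(0, p, n_components, dimnames = list(colnames(x), NULL))
  P <- matrix(0, p, n_components, dimnames = list(colnames(x), NULL))
  C <- matrix(0, q, n_components, dimnames = list(colnames(y), NULL))
  Tm <- matrix(0, n, n_components, dimnames = list(rownames(x), NULL))
  U <- matrix(0, n, n_components, dimnames = list(rownames(x), NULL))
  r2y <- numeric(n_components)
  r2x <- numeric(n_components)

  for (a in seq_len(n_components)) {
    u <- Y[, which.max(apply(Y, 2, stats::var)), drop = TRUE]
    if (sum(u^2) == 0) u <- stats::rnorm(n)  # fully deflated Y; direction free
    w_old <- rep(0, p)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u) / sum(u^2)
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("X block fully deflated at component ", a)
      w <- w / nw
      tt <- X %*% w
      cc <- crossprod(Y, tt) / sum(tt^2)
      if (q > 1L) u <- Y %*% cc / sum(cc^2)
      if (sqrt(sum((w - w_old)^2)) < tol) { converged <- TRUE; break }
      w_old <- w
    }
    if (!converged) {
      stop("NIPALS did not converge for component ", a,
           " within ", max_iter, " iterations")
    }
    # deterministic sign: largest-|w| element positive
    flip <- sign(w[which.max(abs(w))])
    if (flip < 0) { w <- -w; tt <- -tt; cc <- -cc; u <- -u }
    pp <- crossprod(X, tt) / sum(tt^2)
    X <- X - tt %*% t(pp)
    Y <- Y - tt %*% t(cc)
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc
    Tm[, a] <- tt; U[, a] <- u
    r2y[a] <- 100 * sum(tt^2) * sum(cc^2) / ssy_total
    r2x[a] <- 100 * sum(tt^2) * sum(pp^2) / ssx_total
  }
  comp <- paste0("comp", seq_len(n_components))
  colnames(W) <- colnames(P) <- colnames(C) <- colnames(Tm) <- colnames(U) <- comp
  # correlation coordinates for the biplot (guard constant columns)
  safe_cor <- function(m, scores) {
    out <- suppressWarnings(stats::cor(m, scores))
    out[!is.finite(out)] <- 0
    out
  }
  var_coords <- rbind(
    data.frame(block = "x", variable = colnames(x),
               safe_cor(xs$m, Tm), row.names = NULL, check.names = FALSE),
    data.frame(block = "y", variable = colnames(y),
               safe_cor(ys$m, Tm), row.names = NULL, check.names = FALSE)
  )
  structure(
    list(x_weights = W, x_scores = Tm, x_loadings = P,
         y_loadings = C, y_scores = U,
         r2y = r2y, r2y_cum = cumsum(r2y),
         r2x = r2x, r2x_cum = cumsum(r2x),
         variable_coords = var_coords,
         means = list(x = xs$mu, y = ys$mu),
         sds = list(x = xs$s, y = ys$s),
         scale = scale, n_components = n_components),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d predictors, %d responses\n",
              x$n_components, nrow(x$x_weights), nrow(x$y_loadings)))
  tab <- data.frame(component = seq_len(x$n_components),
                    r2y_pct = round(x$r2y, 2), r2y_cum_pct = round(x$r2y_cum, 2),
                    r2x_pct = round(x$r2x, 2), r2x_cum_pct = round(x$r2x_cum, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' PLS of PLFA enrichment profiles on treatment and time
#'
#' Runs the community-structure analysis: the filtered proportional-enrichment
#' matrix is empirical-logit transformed and regressed (as the response block)
#' on treatment and sampling-day indicator variables. Axis-1/2 observation and
#' variable coordinates for a biplot are returned alongside the model.
#'
#' @param profiles Filtered proportion matrix from [filter_low_enrichment()]
#'   (rows = profiles with `treatment` / `day` attributes, columns = PLFAs).
#' @param n_components Number of PLS components (default 2).
#' @param logit_tol Tolerance of the empirical logit transform (default 0.1).
#' @param average_time Average profiles over time within treatment before the
#'   analysis (the 3-column-response layout); time indicators are then
#'   dropped from the predictors. Default `FALSE`.
#' @param scale Passed to [nipals_pls2()]; applies to the response block and
#'   (when indicators vary) the predictor block.
#' @return List with `model` (a `pls_model`), `observation_coords`
#'   (scores on axes 1-2 with treatment/day metadata) and `variable_coords`
#'   (correlation coordinates of PLFAs and indicators).
#' @export
pls_enrichment_analysis <- function(profiles, n_components = 2,
                                    logit_tol = 0.1, average_time = FALSE,
                                    scale = TRUE) {
  stopifnot(is.matrix(profiles))
  if (average_time) profiles <- average_profiles(profiles, by = "treatment")
  tr <- attr(profiles, "treatment")
  day <- attr(profiles, "day")
  if (is.null(tr)) stop("profiles must carry a 'treatment' attribute")
  y <- empirical_logit(profiles, tol = logit_tol)
  dimnames(y) <- dimnames(profiles)
  xf <- data.frame(treatment = factor(tr))
  if (!is.null(day) && length(unique(day)) > 1L) xf$day <- factor(day)
  x <- stats::model.matrix(~ . - 1, data = xf)
  # full treatment indicators plus day indicators; drop any constant column
  keep <- apply(x, 2, function(v) stats::var(v) > 0)
  x <- x[, keep, drop = FALSE]
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  model <- nipals_pls2(x, y, n_components = n_components, scale = scale)
  obs <- data.frame(profile = rownames(profiles), treatment = tr,
                    model$x_scores[, seq_len(min(2, n_components)), drop = FALSE],
                    row.names = NULL, check.names = FALSE)
  if (!is.null(day) && !average_time) obs$day <- day
  list(model = model, observation_coords = obs,
       variable_coords = model$variable_coords)
}

#' Read an isolate PLFA-profile database
#'
#' A delimited matrix with PLFA names in the first column (`plfa`) and one
#' column of mean relative abundances per bacterial genus. An optional
#' two-column genus/phylum table attaches taxonomic metadata.
#'
#' @param path Path to the profile matrix.
#' @param phylum_path Optional path to a genus-to-phylum table (columns
#'   `genus`, `phylum`).
#' @param sep Field separator; default tab.
#' @return An `isolate_db`: list with `profiles` (matrix, rows = PLFAs,
#'   columns = genera) and `phylum` (named character or `NULL`).
#' @export
read_isolate_db <- function(path, phylum_path = NULL, sep = "\t") {
  x <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!"plfa" %in% names(x)) stop("isolate database needs a 'plfa' column")
  m <- as.matrix(x[setdiff(names(x), "plfa")])
  rownames(m) <- normalise_plfa(x$plfa)
  phylum <- NULL
  if (!is.null(phylum_path)) {
    ph <- utils::read.table(phylum_path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    phylum <- stats::setNames(ph$phylum, ph$genus)
  }
  isolate_db(m, phylum)
}

#' @rdname read_isolate_db
#' @param profiles Matrix of non-negative relative abundances, rows = PLFAs,
#'   columns = genera (unique names).
#' @param phylum Optional named character vector, genus -> phylum.
#' @export
isolate_db <- function(profiles, phylum = NULL) {
  stopifnot(is.matrix(profiles), is.numeric(profiles))
  if (any(profiles < 0)) stop("isolate profiles must be non-negative")
  if (anyDuplicated(colnames(profiles))) stop("genus names must be unique")
  structure(list(profiles = profiles, phylum = phylum), class = "isolate_db")
}

#' @export
print.isolate_db <- function(x, ...) {
  cat(sprintf("<isolate_db> %d PLFAs x %d genera\n",
              nrow(x$profiles), ncol(x$profiles)))
  invisible(x)
}

#' Compare enrichment profiles with an isolate PLFA database
#'
#' PLS with the genus mean PLFA profiles as the predictor block and the
#' experiment's (typically time-averaged, per-treatment) enrichment profiles as the
#' response block, over the PLFAs common to both. Reports each genus's
#' correlation with the first PLS axes, the basis for ranking candidate
#' degraders.
#'
#' @param profiles Enrichment profile matrix (rows = treatments or profiles,
#'   columns = PLFAs), e.g. from [average_profiles()].
#' @param db An `isolate_db`.
#' @param n_components Number of components (default 3).
#' @param scale Passed to [nipals_pls2()].
#' @return List with `model` (a `pls_model`), `common_plfas`, and
#'   `genus_correlations` (data.frame of per-genus correlations with each
#'   axis, plus phylum when available).
#' @export
compare_to_isolates <- function(profiles, db, n_components = 3, scale = TRUE) {
  stopifnot(is.matrix(profiles), inherits(db, "isolate_db"))
  common <- intersect(colnames(profiles), rownames(db$profiles))
  if (length(common) < 3) {
    stop("fewer than 3 PLFAs are common to the profiles and the database")
  }
  x <- db$profiles[common, , drop = FALSE]          # obs = PLFAs, vars = genera
  y <- t(profiles[, common, drop = FALSE])          # obs = PLFAs, vars = treatments
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  model <- nipals_pls2(x, y, n_components = n_components, scale = scale)
  vc <- model$variable_coords
  gc <- vc[vc$block == "x", setdiff(names(vc), "block"), drop = FALSE]
  names(gc)[names(gc) == "variable"] <- "genus"
  if (!is.null(db$phylum)) gc$phylum <- unname(db$phylum[gc$genus])
  rownames(gc) <- NULL
  list(model = model, common_plfas = common, genus_correlations = gc)
}
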