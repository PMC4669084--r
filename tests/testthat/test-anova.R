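toy_two_group <- function() {
  data.frame(y = c(1, 2, 3, 4, 5, 6),
             day = 1,
             treatment = rep(c("A", "B"), each = 3))
}

test_that("one-way toy ANOVA gives F = 13.5 on (1, 4) df", {
  d <- toy_two_group()
  fit <- fit_two_way_lm(d, "y", time = "treatment", treatment = "day",
                        with_interaction = FALSE)
  row <- fit$anova[fit$anova$term == "treatment", ]
  expect_equal(row$f_value, 13.5, tolerance = 1e-12)
  expect_identical(row$df, 1L)
  expect_identical(fit$anova$df[fit$anova$term == "Residuals"], 4L)
})

test_that("a constant response yields zero sums of squares", {
  d <- toy_two_group(); d$y <- 5
  fit <- suppressWarnings(
    fit_two_way_lm(d, "y", time = "treatment", treatment = "day",
                   with_interaction = FALSE))
  expect_equal(fit$anova$sum_sq[fit$anova$term == "treatment"], 0,
               tolerance = 1e-20)
})

test_that("sequential decomposition matches a nested least-squares oracle", {
  set.seed(11)
  d <- expand.grid(day = factor(c(7, 14, 21)),
                   treatment = factor(c("LC", "LC1D", "LC2D")),
                   rep = 1:3)
  d$y <- rnorm(nrow(d)) + as.numeric(d$day) + 0.5 * as.numeric(d$treatment) +
    0.3 * as.numeric(d$day) * as.numeric(d$treatment)
  d <- d[-1, ]  # unbalance the design so term order matters
  fit <- fit_two_way_lm(d, "y")
  mm_t <- stats::model.matrix(~day, d)[, -1, drop = FALSE]
  mm_tr <- stats::model.matrix(~treatment, d)[, -1, drop = FALSE]
  mm_int <- stats::model.matrix(~day:treatment, d)
  mm_int <- mm_int[, setdiff(colnames(mm_int), "(Intercept)"), drop = FALSE]
  oracle <- sequential_ss(d$y, list(mm_t, mm_tr, mm_int))
  expect_equal(fit$anova$sum_sq, unname(oracle), tolerance = 1e-8)
  # reversing term order changes term SS but never the total
  fit_rev <- fit_two_way_lm(d, "y", time = "treatment", treatment = "day")
  expect_false(isTRUE(all.equal(
    fit$anova$sum_sq[fit$anova$term == "day"],
    fit_rev$anova$sum_sq[fit_rev$anova$term == "day"])))
  expect_equal(sum(fit$anova$sum_sq), sum(fit_rev$anova$sum_sq),
               tolerance = 1e-10)
})

test_that("saturated models are refused", {
  d <- expand.grid(day = c(7, 14), treatment = c("LC", "LC1D"))
  d$y <- rnorm(4)
  expect_error(fit_two_way_lm(d, "y"), "saturated")
})

test_that("Tukey HSD with two groups equals the pooled t-test", {
  d <- toy_two_group()
  fit <- fit_two_way_lm(d, "y", time = "treatment", treatment = "day",
                        with_interaction = FALSE)
  tk <- tukey_hsd(fit, "time")
  tt <- t.test(y ~ treatment, data = d, var.equal = TRUE)
  # ptukey is itself evaluated by quadrature, accurate to ~1e-6 absolute
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-4)
  expect_equal(abs(tk$diff), unname(abs(diff(tapply(d$y, d$treatment, mean)))),
               tolerance = 1e-12)
})

test_that("identical group means give adjusted p of 1", {
  d <- data.frame(y = rep(c(1, 2, 3), 3) + rep(c(0, 0, 0), each = 3),
                  g = rep(c("A", "B", "C"), each = 3), day = 1)
  fit <- fit_two_way_lm(d, "y", time = "g", treatment = "day",
                        with_interaction = FALSE)
  tk <- tukey_hsd(fit, "time")
  expect_true(all(tk$p_adj > 1 - 1e-6))
})

test_that("Tukey p values match a studentized-range integration oracle", {
  set.seed(3)
  d <- data.frame(y = c(1.2, 0.8, 1.5, 2.9, 3.4, 2.7, 1.9, 2.2, 2.5),
                  g = rep(c("A", "B", "C"), each = 3), day = 1)
  fit <- fit_two_way_lm(d, "y", time = "g", treatment = "day",
                        with_interaction = FALSE)
  tk <- tukey_hsd(fit, "time")
  ms_res <- fit$anova$mean_sq[fit$anova$term == "Residuals"]
  df_res <- fit$anova$df[fit$anova$term == "Residuals"]
  means <- tapply(d$y, d$g, mean)
  pairs <- combn(names(means), 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    q_obs <- abs(means[b] - means[a]) / sqrt(ms_res / 3)
    p_oracle <- 1 - ptukey_integrate(q_obs, k = 3, nu = df_res)
    got <- tk$p_adj[tk$comparison %in% c(paste(b, a, sep = "-"),
                                         paste(a, b, sep = "-"))]
    expect_equal(got, p_oracle, tolerance = 1e-6)
  }
})

test_that("tukey_hsd validates its factor argument", {
  d <- toy_two_group()
  fit <- fit_two_way_lm(d, "y", time = "treatment", treatment = "day",
                        with_interaction = FALSE)
  expect_error(tukey_hsd(fit, "treatment"), "fewer than 2 levels")
})

test_that("diagnostics tables behave on perfect and noisy fits", {
  d <- expand.grid(day = c(7, 14, 21), treatment = c("LC", "LC2D"))
  d <- d[rep(seq_len(nrow(d)), 2), ]
  d$y <- as.numeric(factor(d$day)) + 2 * as.numeric(factor(d$treatment))
  fit <- suppressWarnings(fit_two_way_lm(d, "y", with_interaction = FALSE))
  dg <- diagnostics(fit)
  expect_true(all(abs(dg$residuals_vs_fitted$residual) < 1e-10))
  d$y <- d$y + rnorm(nrow(d))
  fit2 <- fit_two_way_lm(d, "y", with_interaction = FALSE)
  dg2 <- diagnostics(fit2)
  expect_false(is.unsorted(dg2$qq$theoretical))
  expect_false(is.unsorted(dg2$qq$standardised))
  r <- residuals(fit2$model)
  expect_equal(sort(dg2$qq$standardised), sort(unname((r - mean(r)) / sd(r))),
               tolerance = 1e-12)
  expect_equal(mean(dg2$qq$standardised), 0, tolerance = 1e-10)
  expect_named(dg2$residuals_vs_factor, c("day", "treatment", "residual"))
})
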