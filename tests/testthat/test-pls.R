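test_that("a response along a singular direction is fully explained by one component", {
  set.seed(5)
  x <- matrix(rnorm(40), 10, 4)
  xc <- scale(x, scale = FALSE)
  u1 <- svd(xc)$u[, 1]                       # zero-mean singular direction
  y <- u1 %*% t(c(1, 0.4))
  m <- nipals_pls2(x, y, n_components = 1, scale = FALSE)
  expect_equal(m$r2y[1], 100, tolerance = 1e-8)
  # any response in the column space of X is fully explained at full rank
  y2 <- xc %*% c(1, -2, 0.5, 3) %*% t(c(1, 0.4))
  m2 <- nipals_pls2(x, y2, n_components = 4, scale = FALSE)
  expect_equal(m2$r2y_cum[4], 100, tolerance = 1e-8)
})

test_that("with centred orthonormal predictors the first weight vector picks the active column", {
  x <- unclass(stats::poly(1:8, 4))          # zero-mean, orthonormal columns
  attributes(x) <- attributes(x)["dim"]
  y <- x[, 1, drop = FALSE]
  m <- nipals_pls2(x, y, n_components = 1, scale = FALSE)
  w <- m$x_weights[, 1]
  expect_equal(unname(abs(w[1])), 1, tolerance = 1e-10)
  expect_equal(unname(w[-1]), rep(0, 3), tolerance = 1e-10)
  expect_equal(m$r2y[1], 100, tolerance = 1e-8)
})

test_that("NIPALS agrees with an SVD-per-component oracle on random matrices", {
  for (seed in c(7, 21, 99)) {
    set.seed(seed)
    x <- matrix(rnorm(60), 10, 6)
    y <- matrix(rnorm(30), 10, 3)
    m <- nipals_pls2(x, y, n_components = 3, scale = TRUE)
    o <- svd_pls2(x, y, 3, scale = TRUE)
    for (a in 1:3) {
      s <- sign(sum(o$weights[, a] * m$x_weights[, a]))
      expect_equal(s * o$weights[, a], unname(m$x_weights[, a]),
                   tolerance = 1e-6)
      expect_equal(s * as.numeric(o$scores[, a]),
                   unname(m$x_scores[, a]), tolerance = 1e-6)
      expect_equal(s * as.numeric(o$y_loadings[, a]),
                   unname(m$y_loadings[, a]), tolerance = 1e-6)
    }
  }
})

test_that("NIPALS agrees with mixOmics up to per-component sign", {
  skip_if_not_installed("mixOmics")
  set.seed(13)
  x <- matrix(rnorm(60), 10, 6)
  y <- matrix(rnorm(30), 10, 3)
  m <- nipals_pls2(x, y, n_components = 3, scale = TRUE)
  mo <- mixOmics::pls(x, y, ncomp = 3, scale = TRUE, mode = "regression")
  for (a in 1:3) {
    wa <- mo$loadings$X[, a]
    s <- sign(sum(wa * m$x_weights[, a]))
    expect_equal(s * unname(wa), unname(m$x_weights[, a]), tolerance = 1e-6)
    expect_equal(s * unname(mo$variates$X[, a]), unname(m$x_scores[, a]),
                 tolerance = 1e-6)
  }
})

test_that("scores are orthogonal and full components reconstruct centred X", {
  set.seed(8)
  x <- matrix(rnorm(48), 12, 4)
  y <- matrix(rnorm(24), 12, 2)
  m <- nipals_pls2(x, y, n_components = 4, scale = FALSE)
  g <- crossprod(m$x_scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  xc <- scale(x, scale = FALSE)
  recon <- m$x_scores %*% t(m$x_loadings)
  expect_lt(max(abs(xc - recon)), 1e-8)
  expect_true(all(diff(m$r2y_cum) >= -1e-10))
  expect_lte(m$r2y_cum[4], 100 + 1e-8)
})

test_that("reordering response columns permutes loadings and nothing else", {
  set.seed(9)
  x <- matrix(rnorm(60), 10, 6)
  y <- matrix(rnorm(30), 10, 3); colnames(y) <- c("a", "b", "c")
  m1 <- nipals_pls2(x, y, n_components = 2)
  m2 <- nipals_pls2(x, y[, c(3, 1, 2)], n_components = 2)
  expect_equal(m1$x_scores, m2$x_scores, tolerance = 1e-8)
  expect_equal(m1$y_loadings[c(3, 1, 2), ], m2$y_loadings,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(m1$r2y, m2$r2y, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected with informative errors", {
  x <- cbind(v1 = rnorm(8), flat = rep(2, 8), v3 = rnorm(8))
  y <- matrix(rnorm(16), 8, 2)
  expect_error(nipals_pls2(x, y, 2, scale = TRUE), "flat")
  expect_error(nipals_pls2(x[, c(1, 3)], y, 5), "n_components")
  expect_error(nipals_pls2(x[1:4, ], y, 2), "same number of rows")
})

test_that("treatment-structured enrichment separates along axis 1", {
  sim <- cached_sim("rates")
  inc <- plfa_incorporation(sim$plfa)
  enr <- relative_enrichment(inc[inc$day > 0, ])
  flt <- filter_low_enrichment(enrichment_matrix(enr))
  res <- pls_enrichment_analysis(flt$profiles, average_time = TRUE)
  oc <- res$observation_coords
  lc <- oc$comp1[oc$treatment == "LC"]
  d2 <- oc$comp1[oc$treatment == "LC2D"]
  d1 <- oc$comp1[oc$treatment == "LC1D"]
  # extremes opposed, low-dose intermediate
  expect_lt(lc * d2, 0)
  expect_lt(abs(d1), min(abs(lc), abs(d2)))
  # generator-encoded contrast: branched vs monounsaturated PLFAs load at
  # opposite ends of axis 1
  vc <- res$variable_coords
  i15 <- vc$comp1[vc$block == "y" & vc$variable == "i15:0"]
  w7 <- vc$comp1[vc$block == "y" & vc$variable == "18:1w7"]
  expect_lt(i15 * w7, 0)
})

test_that("enrichment unrelated to treatment explains little response variance", {
  set.seed(17)
  sim <- cached_sim("rates")
  inc <- plfa_incorporation(sim$plfa)
  inc <- inc[inc$day > 0, ]
  # same expected profile everywhere: shuffle incorporation across vials
  inc$incorporation <- abs(rnorm(nrow(inc), mean = 1, sd = 0.05))
  enr <- relative_enrichment(inc)
  flt <- filter_low_enrichment(enrichment_matrix(enr))
  res <- pls_enrichment_analysis(flt$profiles, average_time = FALSE)
  expect_lt(res$model$r2y_cum[2], 25)
})

test_that("isolate comparison self-matches, intersects PLFAs, and validates", {
  sim <- cached_sim("rates")
  inc <- plfa_incorporation(sim$plfa)
  enr <- relative_enrichment(inc[inc$day > 0, ])
  prof <- average_profiles(enrichment_matrix(enr), by = "treatment")
  db <- simulate_isolate_db(seed = 4)
  # plant the LC profile itself as a genus: it must top axis-1 |correlation|
  planted <- db$profiles
  common0 <- intersect(colnames(prof), rownames(planted))
  planted <- cbind(planted, SelfMatch = 0)
  planted[common0, "SelfMatch"] <- prof["LC", common0] / sum(prof["LC", common0])
  db2 <- isolate_db(planted)
  res <- compare_to_isolates(prof, db2)
  gc <- res$genus_correlations
  expect_equal(gc$genus[which.max(abs(gc$comp1))], "SelfMatch")
  # intersection logic equals a brute-force set intersection
  expect_equal(sort(res$common_plfas),
               sort(intersect(colnames(prof), rownames(planted))))
  # too few shared PLFAs is an error
  tiny <- prof[, 1:2, drop = FALSE]
  expect_error(compare_to_isolates(tiny, db2), "fewer than 3")
})

test_that("a random database unrelated to the profiles correlates weakly", {
  sim <- cached_sim("rates")
  inc <- plfa_incorporation(sim$plfa)
  enr <- relative_enrichment(inc[inc$day > 0, ])
  prof <- average_profiles(enrichment_matrix(enr), by = "treatment")
  set.seed(31)
  rnd <- matrix(abs(rnorm(length(canonical_plfas()) * 24)),
                length(canonical_plfas()), 24,
                dimnames = list(canonical_plfas(), sprintf("G%02d", 1:24)))
  res <- compare_to_isolates(prof, isolate_db(sweep(rnd, 2, colSums(rnd), "/")))
  expect_lt(mean(abs(res$genus_correlations$comp1)), 0.5)
})
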