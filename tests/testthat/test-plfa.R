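toy_plfa <- function() {
  rbind(
    data.frame(vial_id = "C1", treatment = "CTRL", day = 7,
               plfa = c("i15:0", "16:0", "18:1w7"),
               conc = c(3, 8, 4), delta = -25),
    data.frame(vial_id = "L1", treatment = "LC", day = 7,
               plfa = c("i15:0", "16:0", "18:1w7"),
               conc = c(3, 8, 4),
               delta = fraction_to_delta(delta_to_fraction(-25) +
                                           c(0.002, 0.001, 0.004)))
  )
}

test_that("PLFA name normalisation handles common dialects", {
  expect_equal(normalise_plfa(c("18:1ω7", " i15:0 ", "18:1 omega 9", "cy17:0",
                                "10Me16:0", "16:1n-7")),
               c("18:1w7", "i15:0", "18:1w9", "cy17:0", "10Me16:0", "16:1w7"))
  expect_equal(normalise_plfa("18:1v7", aliases = c("18:1v7" = "18:1w7")),
               "18:1w7")
})

test_that("per-PLFA incorporation is excess times concentration over substrate fraction", {
  inc <- plfa_incorporation(toy_plfa(), substrate_spec(0.97, 0.15))
  expect_equal(inc$incorporation[inc$plfa == "i15:0"], 0.002 * 3 / 0.97,
               tolerance = 1e-9)
  # E = 0.002, conc 5 -> 0.010309...
  tp <- toy_plfa(); tp$conc[tp$vial_id == "L1"] <- 5
  inc5 <- plfa_incorporation(tp, substrate_spec(0.97, 0.15))
  expect_equal(inc5$incorporation[inc5$plfa == "i15:0"], 0.01 / 0.97,
               tolerance = 1e-9)
  # doubling concentration doubles incorporation
  expect_equal(inc5$incorporation[inc5$plfa == "i15:0"] / 5,
               inc$incorporation[inc$plfa == "i15:0"] / 3, tolerance = 1e-12)
  # sample delta equal to background -> zero everywhere
  tp0 <- toy_plfa(); tp0$delta <- -25
  inc0 <- plfa_incorporation(tp0)
  expect_equal(inc0$incorporation, rep(0, 3))
})

test_that("sample PLFAs missing from the background are excluded with a warning", {
  tp <- toy_plfa()
  extra <- tp[tp$vial_id == "L1", ][1, ]
  extra$plfa <- "cy17:0"
  expect_warning(inc <- plfa_incorporation(rbind(tp, extra)), "cy17:0")
  expect_false("cy17:0" %in% inc$plfa)
})

test_that("group totals equal a brute-force filter-and-sum and ignore row order", {
  sim <- cached_sim("rates")
  inc <- plfa_incorporation(sim$plfa)
  map <- biomarker_map()
  g <- group_incorporation(inc, map)
  one <- inc[inc$vial_id == inc$vial_id[1], ]
  brute <- sum(one$incorporation[one$plfa %in% map$bacteria])
  expect_equal(g$incorporation[g$vial_id == one$vial_id[1] &
                                 g$group == "bacteria"], brute,
               tolerance = 1e-12)
  shuffled <- inc[sample(nrow(inc)), ]
  g2 <- group_incorporation(shuffled, map)
  key <- paste(g$vial_id, g$group)
  expect_equal(g2$incorporation[match(key, paste(g2$vial_id, g2$group))],
               g$incorporation, tolerance = 1e-12)
  # a group with no members present yields zero with a warning
  only_bact <- inc[inc$plfa %in% map$bacteria, ]
  expect_warning(ge <- group_incorporation(only_bact, map), "eukaryotes")
  expect_true(all(ge$incorporation[ge$group == "eukaryotes"] == 0))
})

test_that("noise-free group totals match the generator's truth", {
  sim <- cached_sim("rates")
  inc <- plfa_incorporation(sim$plfa)
  g <- group_incorporation(inc)
  gm <- stats::aggregate(incorporation ~ treatment + day + group, data = g,
                         FUN = mean)
  truth <- sim$truth$group_incorporation
  truth <- truth[truth$group != "other" & truth$treatment != "CTRL", ]
  truth$per_vial <- truth$incorporation / 3  # truth sums over 3 replicates
  key <- paste(truth$treatment, truth$day, truth$group)
  got <- gm$incorporation[match(key, paste(gm$treatment, gm$day, gm$group))]
  expect_equal(got, truth$per_vial, tolerance = 1e-9)
})

test_that("relative enrichment sums to one per vial and rejects non-positive totals", {
  sim <- cached_sim("rates")
  inc <- plfa_incorporation(sim$plfa)
  enr <- relative_enrichment(inc[inc$day > 0, ])
  sums <- tapply(enr$proportion, enr$vial_id, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  # single nonzero PLFA carries proportion 1
  one <- inc[inc$vial_id == inc$vial_id[1], ]
  one$incorporation <- c(5, rep(0, nrow(one) - 1))
  expect_equal(relative_enrichment(one)$proportion,
               c(1, rep(0, nrow(one) - 1)))
  # equal incorporation -> equal shares; arbitrary vector -> divide-by-sum
  one$incorporation <- rep(2, nrow(one))
  expect_equal(relative_enrichment(one)$proportion,
               rep(1 / nrow(one), nrow(one)))
  v <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3)[seq_len(nrow(one))]
  one$incorporation <- v
  expect_equal(relative_enrichment(one)$proportion, v / sum(v))
  one$incorporation <- 0 * v
  expect_error(relative_enrichment(one), as.character(one$vial_id[1]))
})

test_that("the low-enrichment filter drops columns below the mean threshold", {
  m <- cbind(a = c(0, 0, 0), b = c(0.001, 0.001, 0.001),
             c = c(0.5, 0.6, 0.4), d = c(0.0005, 0.0015, 0.0009))
  flt <- filter_low_enrichment(m, threshold = 0.001)
  expect_equal(flt$dropped, c("a", "d"))         # means below 0.001 go
  expect_true("b" %in% flt$retained)             # mean exactly 0.001 stays
  # brute-force scan agrees
  expect_equal(flt$retained, colnames(m)[colMeans(m) >= 0.001])
})

test_that("empirical logit is finite, antisymmetric and monotone", {
  expect_equal(empirical_logit(0.5), 0)
  expect_equal(empirical_logit(0), log(0.1 / 1.1), tolerance = 1e-12)
  expect_equal(empirical_logit(1), -log(0.1 / 1.1), tolerance = 1e-12)
  p <- seq(0, 1, by = 0.01)
  expect_equal(empirical_logit(p) + empirical_logit(1 - p), rep(0, length(p)),
               tolerance = 1e-12)
  expect_true(all(diff(empirical_logit(p)) > 0))
  expect_error(empirical_logit(-0.01), "\\[0, 1\\]")
  expect_error(empirical_logit(1.01), "\\[0, 1\\]")
})

test_that("profile matrices and time averaging preserve group structure", {
  sim <- cached_sim("rates")
  inc <- plfa_incorporation(sim$plfa)
  enr <- relative_enrichment(inc[inc$day > 0, ])
  m <- enrichment_matrix(enr)
  expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-12)
  avg <- average_profiles(m, by = "treatment")
  expect_equal(sort(rownames(avg)), sort(unique(enr$treatment)))
  lc_rows <- m[attr(m, "treatment") == "LC", , drop = FALSE]
  expect_equal(unname(avg["LC", ]), unname(colMeans(lc_rows)),
               tolerance = 1e-12)
})
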