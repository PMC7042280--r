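test_that("summarize_wells aggregates sites with flags and warnings", {
  counts <- data.frame(
    well = c(rep("A01", 5), rep("A02", 2), "A03"),
    site = c(1:5, 1:2, 1),
    timepoint = "baseline", readout = "coloc",
    value = c(rep(10, 5), 8, 12, 7))
  ws <- suppressWarnings(summarize_wells(counts, expected_sites = 5))
  a1 <- ws[ws$well == "A01", ]
  expect_equal(a1$mean, 10); expect_equal(a1$sd, 0)
  a2 <- ws[ws$well == "A02", ]
  expect_equal(a2$mean, 10)
  expect_equal(a2$sd, 2.8284271, tolerance = 1e-6)   # sample sd of {8,12}
  expect_true(ws$flag_single_site[ws$well == "A03"])
  expect_warning(summarize_wells(counts, expected_sites = 5), "fewer")
  expect_error(summarize_wells(counts[, -5]), "columns")
})

test_that("percent_of_baseline reports survival and is scale-free", {
  expect_equal(percent_of_baseline(533, 533), 100)
  expect_equal(percent_of_baseline(100, 500), 20)   # i.e. 80% lost
  expect_error(percent_of_baseline(10, 0), "positive")
  expect_equal(percent_of_baseline(3 * 100, 3 * 500),
               percent_of_baseline(100, 500))
})

test_that("Dunnett reduces to the pooled t-test for one comparison", {
  set.seed(1)
  y <- c(rnorm(4, 10, 2), rnorm(4, 13, 2))
  g <- rep(c("NTC", "trt"), each = 4)
  dn <- dunnett_vs_control(y, g, "NTC")
  tt <- t.test(y[g == "trt"], y[g == "NTC"], var.equal = TRUE)
  expect_equal(dn$p_adj, tt$p.value, tolerance = 1e-3)
})

test_that("Dunnett adjusted p-values match multcomp on worked datasets", {
  skip_if_not_installed("multcomp")
  set.seed(11)
  d <- data.frame(
    y = c(rnorm(3, 100, 8), rnorm(3, 90, 8), rnorm(3, 80, 8),
          rnorm(3, 99, 8)),
    g = factor(rep(c("NTC", "a", "b", "c"), each = 3),
               levels = c("NTC", "a", "b", "c")))
  mine <- dunnett_vs_control(d$y, d$g, "NTC")
  ref <- summary(multcomp::glht(stats::aov(y ~ g, d),
                                linfct = multcomp::mcp(g = "Dunnett")),
                 test = multcomp::adjusted("single-step"))$test$pvalues
  expect_equal(mine$p_adj, as.numeric(ref), tolerance = 1e-3)

  # unbalanced groups
  set.seed(2)
  y <- c(rnorm(4, 10), rnorm(3, 11), rnorm(5, 12))
  g <- factor(rep(c("ctl", "A", "B"), c(4, 3, 5)),
              levels = c("ctl", "A", "B"))
  mine <- dunnett_vs_control(y, g, "ctl")
  ref <- summary(multcomp::glht(stats::aov(y ~ g),
                                linfct = multcomp::mcp(g = "Dunnett")),
                 test = multcomp::adjusted("single-step"))$test$pvalues
  expect_equal(mine$p_adj, as.numeric(ref), tolerance = 1e-3)
})

test_that("Dunnett validates input and adjusts upward", {
  y <- rnorm(9); g <- rep(c("a", "b", "c"), 3)
  expect_error(dunnett_vs_control(y, g, "NTC"), "control")
  expect_error(dunnett_vs_control(c(1, 2, 3), c("a", "b", "b"), "b"),
               "at least 2")
  set.seed(3)
  y <- rnorm(12, 50, 5); g <- rep(c("NTC", "a", "b", "c"), each = 3)
  dn <- dunnett_vs_control(y, g, "NTC")
  a <- synaptoscreen:::pooled_anova(y, g)
  for (i in seq_len(nrow(dn))) {
    praw <- 2 * pt(-abs(dn$t[i]), a$df)
    expect_gte(dn$p_adj[i] + 1e-9, praw)
  }
  expect_true(all(dn$p_adj >= 0 & dn$p_adj <= 1))
})

test_that("two-way Dunnett reduces to one-way with a constant factor", {
  set.seed(4)
  y <- rnorm(12, 100, 10)
  g <- rep(c("NTC", "a", "b", "c"), each = 3)
  one <- dunnett_vs_control(y, g, "NTC")
  two <- two_way_dunnett(y, rep("F1", 12), g, "NTC")
  expect_equal(sort(two$p_adj), sort(one$p_adj), tolerance = 1e-9)

  # full two-factor layout: one row per treated cell, valid p range
  set.seed(5)
  d <- expand.grid(rep = 1:3, frac = c("F10", "F20"),
                   grp = c("young", "old"))
  d$y <- rnorm(nrow(d), 100, 8)
  ctl <- data.frame(rep = 1:3, frac = "none", grp = "NTC",
                    y = rnorm(3, 100, 8))
  all <- rbind(d, ctl)
  res <- two_way_dunnett(all$y, all$frac, all$grp, "NTC")
  expect_identical(nrow(res), 4L)
  expect_true(all(res$p_adj >= 0 & res$p_adj <= 1))
  expect_error(two_way_dunnett(d$y, d$frac, d$grp, "NTC"), "control")
})

test_that("Tukey all-pairs matches the studentized range and TukeyHSD", {
  set.seed(6)
  y <- c(rnorm(4, 10, 1), rnorm(4, 10, 1))
  g <- rep(c("a", "b"), each = 4)
  p <- tukey_all_pairs(y, g)
  expect_equal(dim(p), c(2L, 2L))
  expect_equal(diag(p), c(1, 1), ignore_attr = TRUE)
  expect_equal(p[1, 2], p[2, 1])
  # two-group case equals the ordinary t-test (q = sqrt(2) |t|)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(p[1, 2], tt$p.value, tolerance = 1e-6)

  set.seed(7)
  y <- rnorm(12, 20, 3); g <- rep(c("a", "b", "c"), each = 4)
  p <- tukey_all_pairs(y, g)
  hsd <- TukeyHSD(aov(y ~ factor(g)))$`factor(g)`[, "p adj"]
  expect_equal(p["a", "b"], unname(hsd["b-a"]), tolerance = 1e-9)
  expect_equal(p["a", "c"], unname(hsd["c-a"]), tolerance = 1e-9)
  expect_equal(p["b", "c"], unname(hsd["c-b"]), tolerance = 1e-9)
})

test_that("variability metrics recover intra and inter-plate dispersion", {
  ws <- data.frame(mean = rep(500, 6), sd = rep(0, 6),
                   plate = rep(c("P1", "P2"), each = 3))
  vm <- variability_metrics(ws)
  expect_equal(vm$intra_mean_sd, 0)
  expect_equal(vm$intra_mean_cv, 0)
  expect_equal(vm$inter_cv, 0)

  # site noise at 30% of the mean is recovered as a CV near 0.3
  set.seed(8)
  wells <- replicate(200, {
    sites <- rnorm(5, 500, 150)
    c(mean(sites), sd(sites))
  })
  ws <- data.frame(mean = wells[1, ], sd = wells[2, ])
  vm <- variability_metrics(ws)
  expect_lt(abs(vm$intra_mean_cv - 0.3), 0.03)
  expect_true(is.na(vm$inter_cv))
})

test_that("automated vs manual agreement reports r and slope", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(automated_vs_manual_agreement(x, x)$r, 1)
  expect_equal(automated_vs_manual_agreement(x, -x)$r, -1)

  set.seed(9)
  rs <- replicate(5, {
    auto <- runif(30, 500, 2500)
    manual <- 0.9 * auto * rnorm(30, 1, 0.05)
    ag <- automated_vs_manual_agreement(auto, manual)
    c(ag$r, ag$slope)
  })
  expect_gte(mean(rs[1, ] >= 0.98), 0.8)
  expect_lt(mean(rs[2, ]), 1)     # automation counts higher than manual
  expect_error(automated_vs_manual_agreement(1:3, 1:4), "equal length")
})

test_that("significance stars follow the screening figure tiers", {
  expect_identical(p_stars(c(5e-5, 1e-4, 5e-3, 0.04, 0.2)),
                   c("****", "****", "**", "*", "ns"))
})
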