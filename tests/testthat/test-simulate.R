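test_that("config validation rejects bad worlds", {
  expect_error(simulation_config(n = 0), "positive")
  expect_error(simulation_config(group_proportions = c(
    "lowMKS/highERS" = 0.5, "lowMKS/lowERS" = 0.5,
    "highMKS/highERS" = 0.2, "highMKS/lowERS" = -0.2)), "sum to 1|nonnegative")
  expect_error(simulation_config(cutpoints = c(5, 2.5, 10)), "increasing")
  expect_error(simulation_config(score_sd = 0), "sd")
})

test_that("zero gene noise makes compute_score recover drawn scores exactly", {
  cfg <- simulation_config(n = 50, gene_noise_sd = 0)
  sim <- simulate_scores_and_expression(cfg, seed = 4)
  s <- compute_score(sim$expr, default_gene_sets("mks"))
  expect_equal(unname(s), sim$truth$mks, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("median-split agreement matches the two-normal misclassification oracle", {
  # per-score agreement for balanced normals split at the pooled midpoint is
  # 1 - pnorm(-delta/(2*sd)); defaults have delta = 2 sd, i.e. ~0.8413
  oracle <- 1 - pnorm(-1)
  sim <- simulate_scores_and_expression(simulation_config(n = 1000), seed = 6)
  s <- compute_score(sim$expr, default_gene_sets("mks"))
  lev <- dichotomize(s, compute_threshold(s))
  truth_lev <- ifelse(sim$truth$group %in% c("highMKS/highERS", "highMKS/lowERS"),
                      "high", "low")
  agree <- mean(as.character(lev) == truth_lev)
  # gene noise (sd 0.5 over 12 genes) adds ~0.144 sd; tolerance covers MC error
  expect_equal(agree, oracle, tolerance = 0.04)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- simulation_config(n = 80)
  a <- simulate_cohort(cfg, seed = 10)
  b <- simulate_cohort(cfg, seed = 10)
  expect_identical(a$expr, b$expr)
  expect_identical(a$clinical, b$clinical)
  c2 <- simulate_cohort(cfg, seed = 11)
  expect_false(identical(unclass(a$expr), unclass(c2$expr)))
  arm1 <- simulate_letrozole_arm(cfg, seed = 10)
  arm2 <- simulate_letrozole_arm(cfg, seed = 10)
  expect_identical(arm1$truth, arm2$truth)
})

test_that("piecewise-exponential draws honor the closed-form survival", {
  # single segment lambda = 0.1/yr, no dropout, far horizon: mean ~ 10 yr
  cfg1 <- simulation_config(n = 5000, dropout_rate = 0,
                            hazard_rates = matrix(0.1, 4, 3,
                              dimnames = list(biomarker_group_levels(), NULL)),
                            horizon = 1e6)
  g <- factor(rep(biomarker_group_levels(), length.out = 5000),
              levels = biomarker_group_levels())
  r1 <- simulate_survival(cfg1, g, seed = 30)
  expect_lt(abs(mean(r1$time_years) - 10), 3 * 10 / sqrt(5000))

  # two segments (0.3 then 0.05), cutpoint 2.5: S(5) = exp(-0.875)
  cfg2 <- simulation_config(n = 4000, dropout_rate = 0,
                            hazard_rates = matrix(rep(c(0.3, 0.05, 0.05), each = 4), 4, 3,
                              dimnames = list(biomarker_group_levels(), NULL)),
                            cutpoints = c(2.5, 5, 10), horizon = 1e6)
  g2 <- factor(rep(biomarker_group_levels(), length.out = 4000),
               levels = biomarker_group_levels())
  r2 <- simulate_survival(cfg2, g2, seed = 31)
  s5 <- mean(r2$time_years > 5)
  expect_equal(s5, exp(-0.875), tolerance = 4 * sqrt(0.417 * 0.583 / 4000) / exp(-0.875))

  # all rates zero: everyone horizon-censored
  cfg0 <- simulation_config(n = 40, dropout_rate = 0,
                            hazard_rates = matrix(0, 4, 3,
                              dimnames = list(biomarker_group_levels(), NULL)))
  r0 <- simulate_survival(cfg0, g[1:40], seed = 32)
  expect_true(all(r0$event == 0) && all(r0$time_years == 10))
  expect_true(all(r0$cens_reason == "horizon"))
})

test_that("event accounting is exact and empirical KM tracks the closed form", {
  cfg <- default_paper_like_config(n = 2000)
  r <- simulate_survival(cfg, simulate_scores_and_expression(cfg, 40)$truth$group,
                         seed = 40)
  expect_equal(sum(r$cens_reason == "event"), sum(r$event))
  expect_equal(table(factor(r$cens_reason, c("event", "dropout", "horizon"))) |>
                 sum(), nrow(r))

  # sup-distance of group KM from the piecewise closed form
  cfg2 <- simulation_config(n = 10000, dropout_rate = 0)
  g <- factor(rep("highMKS/lowERS", 10000), levels = biomarker_group_levels())
  r2 <- simulate_survival(cfg2, g, seed = 41)
  km <- km_estimate(r2)
  rates <- cfg2$hazard_rates["highMKS/lowERS", ]
  S_true <- function(t) exp(-(rates[1] * pmin(t, 2.5) +
                              rates[2] * pmax(0, pmin(t, 5) - 2.5) +
                              rates[3] * pmax(0, t - 5)))
  tt <- seq(0.1, 9.9, by = 0.1)
  expect_lt(max(abs(km_survival_at(km, tt) - S_true(tt))), 0.03)
})

test_that("default config encodes the stated hazard-ratio orderings", {
  cfg <- default_paper_like_config()
  rr <- cfg$hazard_rates
  hr <- sweep(rr[2:4, ], 2, rr[1, ], "/")
  expect_equal(rownames(rr)[1 + which.max(hr[, 1])], "highMKS/lowERS")
  expect_equal(rownames(rr)[1 + which.max(hr[, 3])], "highMKS/highERS")
  expect_true(all(apply(rr, 2, which.min) == 1))

  # built-in non-proportionality: four-group PH test rejects over (0,10)
  co <- simulate_cohort(default_paper_like_config(2000), seed = 1)
  z <- schoenfeld_ph_test(cox_fit(co$clinical, "group", time_window(0, 10)))
  expect_lt(z$global_p, 0.05)
})

test_that("letrozole arm: suppression off centers deltas at zero", {
  cfg <- simulation_config(n = 100, letrozole = list(
    n = 200L, delta_mean_14 = c(low = 0, high = 0),
    delta_mean_90 = c(low = 0, high = 0), delta_sd = 0.3,
    link_a = 40, link_b = -45, link_sd = 15))
  arm <- simulate_letrozole_arm(cfg, seed = 50)
  expect_lt(abs(mean(arm$truth$delta_14)), 3 * 0.3 / sqrt(200))
})
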