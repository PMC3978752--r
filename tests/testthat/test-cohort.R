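test_that("run_univariate recovers a constant HR and shapes its rows", {
  set.seed(41)
  d <- sim_exp_two_group(800, base_rate = 0.08, hr = 2)
  rows <- run_univariate(d, "x", windows = list(c(0, 10)))
  expect_equal(nrow(rows), 1)
  expect_true(rows$ci_lo <= 2 && 2 <= rows$ci_hi)
  expect_true(rows$ph_global_p >= 0)

  # four-group variable: exactly 3 contrast rows per window
  co <- simulate_cohort(simulation_config(n = 500), seed = 2)
  r4 <- run_univariate(co$clinical, "group", windows = list(c(0, 10), c(0, 5)))
  expect_equal(nrow(r4), 6)
  expect_equal(unique(table(r4$window)), 3L)

  # window with no events -> flagged NA row, not an exception
  tiny <- make_records(c(1, 2, 3, 6, 7), c(1, 1, 1, 0, 0), x = c(0, 1, 0, 1, 0))
  rna <- run_univariate(tiny, "x", windows = list(c(5, 10)))
  expect_true(is.na(rna$hr))
  expect_match(rna$note, "no events")
})

test_that("multivariate fit adjusts, flags collinearity, drops constants", {
  co <- simulate_cohort(simulation_config(n = 1500), seed = 8)
  rows <- run_multivariate(co$clinical,
                           c("age", "stage", "nodal", "grade2", "her2", "group"),
                           c(0, 10))
  expect_true(all(c("age", "stageT2/3", "grouphighMKS/lowERS") %in% rows$term))
  # generating model has group effects only: adjusted early-window group HR
  # for highMKS/lowERS should cover the generating rate ratio 6.5
  early <- run_multivariate(co$clinical,
                            c("age", "stage", "nodal", "grade2", "her2", "group"),
                            c(0, 2.5))
  g <- early[early$term == "grouphighMKS/lowERS", ]
  expect_true(g$ci_lo <= 6.5 && 6.5 <= g$ci_hi)

  dd <- co$clinical; dd$age2 <- dd$age
  col <- run_multivariate(dd, c("age", "age2"), c(0, 10))
  expect_match(col$note, "singular")

  nn <- co$clinical[co$clinical$nodal == "negative", ]
  expect_message(
    rows_nn <- run_multivariate(nn, c("age", "nodal", "group"), c(0, 10)),
    "constant covariate")
  expect_false(any(grepl("nodal", rows_nn$term)))
})

test_that("interaction model is centering-invariant in the product term", {
  co <- simulate_cohort(simulation_config(n = 600), seed = 12)
  f1 <- run_interaction(co$clinical, "mks", "ers", c(0, 10))
  shifted <- co$clinical
  shifted$mks <- shifted$mks + 5
  shifted$ers <- shifted$ers - 2
  f2 <- run_interaction(shifted, "mks", "ers", c(0, 10))
  expect_equal(f1$coefficients$beta, f2$coefficients$beta, tolerance = 1e-8)
  expect_equal(f1$coefficients$term[3], "mks_x_ers")
})

test_that("interaction power in the late window under a qualitative interaction", {
  # hazard after year 5 multiplies by exp(0.4 a + 0.4 b + 0.5 ab); flat before
  set.seed(55)
  sim_one <- function(n = 1200) {
    a <- rnorm(n); b <- rnorm(n)
    lam1 <- 0.04
    lam2 <- 0.05 * exp(0.4 * a + 0.4 * b + 0.5 * a * b)
    u <- -log(runif(n))
    t <- ifelse(u < lam1 * 5, u / lam1, 5 + (u - lam1 * 5) / lam2)
    d <- make_records(pmin(t, 10), as.integer(t <= 10), mks = a, ers = b)
    fit <- run_interaction(d, "mks", "ers", c(5, 10))
    fit$coefficients$p[fit$coefficients$term == "mks_x_ers"]
  }
  rej <- mean(replicate(60, sim_one()) < 0.05)
  expect_gte(rej, 0.7)

  # and under a null product term the interaction p is not anti-conservative
  set.seed(56)
  pnull <- replicate(40, {
    d <- sim_exp_two_group(300, hr = 1)
    d$mks <- rnorm(300); d$ers <- rnorm(300)
    fit <- run_interaction(d, "mks", "ers", c(0, Inf))
    fit$coefficients$p[3]
  })
  expect_lte(mean(pnull < 0.05), 0.15)
})

test_that("the suite is complete, deterministic and stratifiable", {
  co <- simulate_cohort(simulation_config(n = 400), seed = 3)
  plan1 <- analysis_plan(windows = list(c(0, 10)), univariate = "group",
                         multivariate = c("age", "group"),
                         mv_windows = list(c(0, 10)))
  rep1 <- run_time_cohort_suite(co$clinical, plan1)
  expect_equal(length(rep1$km), 1L)
  expect_named(rep1$km, "0-10 yr")
  expect_equal(sort(unique(rep1$cox$model)), c("multivariate", "univariate:group"))
  # pure function of inputs
  rep2 <- run_time_cohort_suite(co$clinical, plan1)
  expect_identical(rep1$cox, rep2$cox)
  expect_identical(rep1$hazard, rep2$hazard)

  # risk sets at t = 0 identical for (0,5) and (0,10)
  planw <- analysis_plan(windows = list(c(0, 5), c(0, 10)), univariate = "group",
                         multivariate = c("age", "group"), mv_windows = list())
  repw <- run_time_cohort_suite(co$clinical, planw)
  uni <- repw$cox[repw$cox$model == "univariate:group", ]
  expect_equal(unique(uni$n[uni$window == "0-5 yr"]),
               unique(uni$n[uni$window == "0-10 yr"]))

  plan_s <- analysis_plan(windows = list(c(0, 10)), univariate = "group",
                          multivariate = c("age", "group"),
                          mv_windows = list(), strata = "nodal")
  rep_s <- run_time_cohort_suite(co$clinical, plan_s)
  expect_setequal(names(rep_s$strata), c("negative", "positive"))
  expect_equal(sum(vapply(rep_s$strata, function(s) s$n, 0)),
               sum(!is.na(co$clinical$nodal)))
})

test_that("tertile analysis is directionally sane on the generator", {
  # low ERS is harmful early by construction: lowest-vs-highest ERS tertile
  # HR over (0,5) should exceed 1
  co <- simulate_cohort(simulation_config(n = 1500), seed = 21)
  scored <- score_cohort(co$expr)
  th <- compute_threshold(setNames(scored$ers, scored$sample_id), kind = "tertile")
  cl <- co$clinical
  cl$ers_t <- factor(tertile_assign(setNames(scored$ers, scored$sample_id), th),
                     levels = c("T3", "T2", "T1"))   # reference = highest
  fit <- cox_fit(cl, "ers_t", time_window(0, 5))
  hr_t1 <- fit$coefficients$hr[fit$coefficients$term == "ers_tT1"]
  expect_gt(hr_t1, 1)
})
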