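test_that("compute_score is the mean over matched genes, robust to order", {
  m <- matrix(c(1, 3, 5, 2, 4, 6), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  s <- compute_score(expression_matrix(m), gene_set("toy", c("A", "B", "C")))
  expect_equal(unname(s), c(3, 4), ignore_attr = TRUE)

  one <- expression_matrix(matrix(5.2, 1, 1, dimnames = list("A", "s1")))
  expect_equal(unname(compute_score(one, gene_set("g1", "A"))), 5.2,
               ignore_attr = TRUE)

  # 12-gene random matrix vs brute-force column-mean oracle
  expr <- make_expr(genes = 20, samples = 7, seed = 42)
  gs <- gene_set("sig", rownames(expr)[c(2, 5, 7, 9:16, 19)])
  s <- compute_score(expr, gs)
  oracle <- apply(unclass(expr)[gs$gene_ids, ], 2, mean)
  expect_equal(s, oracle, ignore_attr = TRUE)

  # permutation invariance of rows and columns
  perm <- expression_matrix(unclass(expr)[sample(20), sample(7)])
  expect_equal(compute_score(perm, gs)[names(s)], s, ignore_attr = TRUE)

  # missing genes dropped with warning; all-missing is an error
  expect_warning(s2 <- compute_score(expr, gene_set("part", c("G02", "NOPE"))),
                 "dropped")
  expect_equal(unname(s2), unname(unclass(expr)["G02", ]), ignore_attr = TRUE)
  expect_error(compute_score(expr, gene_set("none", c("X", "Y"))), "no gene")
})

test_that("probe-set rows sharing a gene id are averaged before scoring", {
  m <- matrix(c(1, 3, 2, 4), 2, 2, dimnames = list(c("A", "A"), c("s1", "s2")))
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(expr <- read_expression(f), "duplicated")
  expect_equal(unname(unclass(expr)["A", ]), c(2, 3))
})

test_that("thresholds: medians and tertiles match order-statistic oracle", {
  s <- setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  expect_equal(compute_threshold(s)$cutpoints, 2.5)
  expect_equal(compute_threshold(s[1:3])$cutpoints, 2)

  set.seed(9)
  u <- setNames(runif(300), sprintf("u%03d", 1:300))
  th <- compute_threshold(u, kind = "tertile")
  expect_equal(th$cutpoints, quantile7_oracle(u, c(1, 2) / 3), tolerance = 1e-12)
  expect_true(all(diff(th$cutpoints) > 0))
  expect_identical(th$reference_samples, names(u))

  # reference subset actually restricts the computation
  th2 <- compute_threshold(u, names(u)[1:100], "median")
  expect_equal(th2$cutpoints, quantile7_oracle(u[1:100], 0.5))
  expect_error(compute_threshold(u, character(0)), "empty")
  expect_error(compute_threshold(u, "nope"), "absent")
})

test_that("dichotomize uses the tie-to-low rule and matches comparison oracle", {
  s <- setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  th <- compute_threshold(s)
  expect_equal(as.character(dichotomize(s, th)),
               c("low", "low", "high", "high"))
  # tie exactly at cutpoint is low
  s2 <- setNames(c(1, 2.5, 4), paste0("t", 1:3))
  expect_equal(as.character(dichotomize(s2, th)), c("low", "low", "high"))

  set.seed(3)
  z <- setNames(rnorm(200), sprintf("z%03d", 1:200))
  thz <- compute_threshold(z)
  expect_identical(as.character(dichotomize(z, thz)),
                   unname(ifelse(z > thz$cutpoints, "high", "low")))
  # median split balances up to ties
  lev <- dichotomize(z, thz)
  expect_lte(abs(sum(lev == "high") - sum(lev == "low")),
             sum(z == thz$cutpoints))
})

test_that("tertile assignment respects boundaries and degenerate input", {
  s <- setNames(as.numeric(1:9), paste0("s", 1:9))
  th <- compute_threshold(s, kind = "tertile")
  expect_equal(th$cutpoints, c(11, 19) / 3, tolerance = 1e-9)
  expect_equal(as.character(tertile_assign(s, th)),
               rep(c("T1", "T2", "T3"), each = 3))

  set.seed(5)
  z <- setNames(rnorm(150), sprintf("z%03d", 1:150))
  thz <- compute_threshold(z, kind = "tertile")
  oracle <- cut(z, c(-Inf, thz$cutpoints, Inf), labels = c("T1", "T2", "T3"))
  expect_identical(as.character(tertile_assign(z, thz)), as.character(oracle))

  flat <- setNames(rep(1, 5), paste0("f", 1:5))
  thf <- compute_threshold(flat, kind = "tertile")
  expect_warning(tf <- tertile_assign(flat, thf), "degenerate")
  expect_true(all(tf == "T1"))
})

test_that("assign_group enumerates the 2x2 with lowMKS/highERS as reference", {
  expect_equal(as.character(assign_group("high", "low")), "highMKS/lowERS")
  expect_equal(as.character(assign_group("low", "high")), "lowMKS/highERS")
  grid <- expand.grid(m = c("low", "high"), e = c("low", "high"),
                      stringsAsFactors = FALSE)
  g <- assign_group(grid$m, grid$e)
  expect_equal(length(unique(g)), 4L)
  expect_identical(levels(g)[1], "lowMKS/highERS")
  expect_error(assign_group("mid", "high"), "low")
})

test_that("adding a constant shifts scores but not median-split labels", {
  expr <- make_expr(genes = 10, samples = 30, seed = 7)
  gs <- gene_set("sig", rownames(expr)[1:6])
  s1 <- compute_score(expr, gs)
  s2 <- compute_score(expression_matrix(unclass(expr) + 3.7), gs)
  expect_equal(unname(s2), unname(s1) + 3.7, tolerance = 1e-12)
  expect_identical(dichotomize(s1, compute_threshold(s1)),
                   dichotomize(s2, compute_threshold(s2)))
})

test_that("score_cohort wires scores, thresholds and groups together", {
  co <- simulate_cohort(simulation_config(n = 120), seed = 5)
  scored <- score_cohort(co$expr)
  expect_equal(nrow(scored), 120)
  expect_true(all(!is.na(scored$group)))
  expect_identical(as.character(scored$group),
                   as.character(assign_group(scored$mks_level, scored$ers_level)))
  th <- attr(scored, "thresholds")
  expect_s3_class(th$MKS, "score_threshold")
})
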