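toy_plots <- function(lt, m, method = "m1") {
  d <- data.frame(lt = lt)
  d[[method]] <- m
  d
}

test_that("the Spearman matrix matches the rank-formula oracle", {
  # rank formula: d = (-1, 1, -1, 1, 0), sum d^2 = 4, 1 - 24/120 = 0.8
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  sm <- spearman_matrix(data.frame(lt = x, m1 = y), c("lt", "m1"))
  expect_equal(sm$rho["lt", "m1"], 0.8)
  expect_equal(sm$rho["lt", "m1"], spearman_rank_formula(x, y))
  expect_equal(sm$rho["lt", "lt"], 1)
  sm_neg <- spearman_matrix(data.frame(lt = x, m1 = -x), c("lt", "m1"))
  expect_equal(sm_neg$rho["lt", "m1"], -1)
  # exhaustive tie-free check on permutations of 1..6
  perms <- matrix(unlist(combinat_perms(1:6)), nrow = 6)
  base <- 1:6
  for (j in seq_len(ncol(perms))) {
    p <- perms[, j]
    sm <- spearman_matrix(data.frame(lt = base, m1 = p), c("lt", "m1"))
    expect_equal(sm$rho["lt", "m1"], spearman_rank_formula(base, p))
  }
})

test_that("pairwise-complete counts and tie flags behave", {
  svy <- simulate_survey(generator_config(seed = 2))
  sm <- spearman_matrix(svy$plots)
  expect_identical(sm$n["lt", "m5"], 182L)
  expect_identical(sm$n["lt", "m6"], 251L)
  expect_identical(sm$n["lt", "m1"], 314L)
  expect_equal(sm$rho, t(sm$rho))
  expect_equal(unname(diag(sm$rho)), rep(1, 7))
  # an all-tied vector has no defined correlation
  sm2 <- spearman_matrix(data.frame(lt = c(1, 2, 3, 4),
                                    m1 = c(5, 5, 5, 5)), c("lt", "m1"))
  expect_true(is.na(sm2$rho["lt", "m1"]))
  expect_false(sm2$significant["lt", "m1"])
})

test_that("distribution summaries report quartiles and benchmark gaps", {
  d <- data.frame(lt = rep(60, 5), m1 = c(10, 20, 30, 40, 50))
  s <- summarize_distributions(d, c("lt", "m1"))
  expect_equal(s$median, c(60, 30))
  expect_equal(s$median_diff_vs_benchmark, c(0, -30))
  expect_equal(unlist(s[1, c("min", "q1", "median", "q3", "max")],
                      use.names = FALSE), rep(60, 5))
  expect_error(summarize_distributions(data.frame(lt = 1, m1 = NA),
                                       c("lt", "m1")),
               "entirely missing")
})

test_that("adoption is classified inclusively at the threshold", {
  expect_identical(classify_adoption(c(29.9, 30, 100, 0)),
                   c(FALSE, TRUE, TRUE, FALSE))
  expect_error(classify_adoption(101))
})

test_that("AQUASTAT categories use lower-inclusive bins", {
  expect_identical(as.character(aquastat_category(c(0, 29.9, 30, 59.9, 60,
                                                    89.9, 90, 95, 100))),
                   c("<30", "<30", "30-60", "30-60", "60-90", "60-90",
                     ">90", ">90", ">90"))
})

test_that("threshold confusion counts the four cells and accuracy", {
  # method identical to the benchmark: no errors
  d <- toy_plots(c(10, 40, 70, 20), c(10, 40, 70, 20))
  cf <- confusion_30(d, "m1")
  expect_equal(cf$accuracy, 100)
  expect_identical(unname(cf$counts[c("false_positive", "false_negative")]),
                   c(0L, 0L))
  # both plots misclassified
  cf0 <- confusion_30(toy_plots(c(45, 20), c(25, 35)), "m1")
  expect_equal(cf0$accuracy, 0)
  expect_identical(unname(cf0$counts[c("false_positive", "false_negative")]),
                   c(1L, 1L))
  # hand-enumerated four-plot case: accuracy 50%
  cf50 <- confusion_30(toy_plots(c(60, 60, 10, 10), c(70, 20, 5, 40)), "m1")
  expect_equal(cf50$accuracy, 50)
  expect_identical(unname(cf50$counts),
                   c(1L, 1L, 1L, 1L))
  # counts always sum to n; accuracy + error rate = 100 exactly
  svy <- simulate_survey(small_config(seed = 31))
  for (m in c("m1", "m4", "m5")) {
    cf <- confusion_30(svy$plots, m)
    expect_identical(sum(cf$counts), cf$n)
    err_rate <- 100 * (cf$counts[["false_positive"]] +
                         cf$counts[["false_negative"]]) / cf$n
    expect_equal(cf$accuracy + err_rate, 100, tolerance = 1e-12)
  }
})

test_that("category false reporting tabulates over/under placement", {
  d <- toy_plots(c(35, 65, 95), c(10, 65, 80))
  ct <- category_false_reporting(d, "m1")
  expect_equal(ct$rates$under, c(NA, 1, 0, 1))
  expect_equal(ct$rates$correct, c(NA, 0, 1, 0))
  # identity method gives a diagonal table
  d2 <- toy_plots(c(10, 40, 70, 95), c(10, 40, 70, 95))
  ct2 <- category_false_reporting(d2, "m1")
  expect_identical(sum(diag(ct2$table)), 4L)
  # an all-zero method under-reports every positive benchmark category
  d3 <- toy_plots(c(40, 70, 95), c(0, 0, 0))
  ct3 <- category_false_reporting(d3, "m1")
  expect_equal(ct3$rates$under[2:4], c(1, 1, 1))
  # margins conserved under record permutation
  svy <- simulate_survey(small_config(seed = 32))
  ct_a <- category_false_reporting(svy$plots, "m2")
  ct_b <- category_false_reporting(svy$plots[sample(nrow(svy$plots)), ], "m2")
  expect_identical(rowSums(ct_a$table), rowSums(ct_b$table))
  expect_identical(colSums(ct_a$table), colSums(ct_b$table))
})

test_that("the error outcome encodes threshold disagreement with missingness", {
  d <- toy_plots(c(45, 45, 29, 50), c(25, 50, 31, NA))
  out <- measurement_error_outcome(d, "m1")
  expect_identical(out, c(1L, 0L, 1L, NA_integer_))
})

test_that("the linear probability model equals explicit least squares", {
  # outcome identical to a 0/1 covariate
  x <- c(0, 1, 0, 1, 1, 0)
  f <- suppressWarnings(lpm(x, data.frame(x = x)))
  expect_equal(unname(f$coefficients[, 1]), c(0, 1))
  expect_equal(f$r_squared, 1)
  # intercept-only model: the mean
  f0 <- lpm(c(0, 1, 1, 0, 1))
  expect_equal(unname(f0$coefficients[1, 1]), 0.6)
  # six-row toy design against the normal equations
  set.seed(9)
  X <- cbind(1, a = stats::rnorm(6), b = stats::rnorm(6))
  y <- c(1, 0, 1, 1, 0, 0)
  f6 <- lpm(y, data.frame(a = X[, "a"], b = X[, "b"]))
  expect_equal(unname(f6$coefficients[, 1]),
               unname(ols_normal_equations(X, y)), tolerance = 1e-10)
  # adjusted R2 identity
  n <- 6; p <- 2
  expect_equal(f6$adj_r_squared,
               1 - (1 - f6$r_squared) * (n - 1) / (n - p - 1))
  expect_error(lpm(c(0, 1, 2)))
  expect_error(lpm(c(0, 1, 0, 1), data.frame(a = c(1, 2, 3, 4),
                                             b = c(2, 4, 6, 8))),
               "rank-deficient")
})

test_that("survey error regressions use the documented design per method", {
  svy <- simulate_survey(generator_config(seed = 3))
  f1 <- fit_lpm(svy$plots, svy$households, "m1")
  expect_identical(f1$n, 314L)
  expect_true(any(grepl("head_age", rownames(f1$coefficients))))
  expect_true(any(grepl("soilvertisol", rownames(f1$coefficients))))
  # reference levels absent from the dummy coding
  expect_false(any(grepl("soilleptosol|residue_typeteff|slopeflat|head_sexmale",
                         rownames(f1$coefficients))))
  f5 <- fit_lpm(svy$plots, svy$households, "m5")
  expect_identical(f5$n, 182L)
  expect_false(any(grepl("head_age|farm_size|phones", rownames(f5$coefficients))))
  f6 <- fit_lpm(svy$plots, svy$households, "m6")
  expect_identical(f6$n, 251L)
  expect_true(f1$adj_r_squared <= f1$r_squared)
})
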