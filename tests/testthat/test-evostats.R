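test_that("rate tables assemble with shared tRNA rates and validate", {
  aars <- data.frame(specificity = c("L", "L"), lineage = c("mt", "cy"),
                     rate = c(0.8, 0.4))
  tab <- assemble_rate_table(aars, c(L = 0.3))
  expect_equal(nrow(tab), 2L)
  expect_equal(unique(tab$X), 0.3)
  expect_error(assemble_rate_table(
    data.frame(specificity = "W", lineage = "mt", rate = 0.5), c(L = 0.3)),
    "W")
  empty <- assemble_rate_table(aars[0, ], c(L = 0.3))
  expect_equal(nrow(empty), 0L)
  expect_error(rate_table(data.frame(specificity = c("L", "L"),
                                     delta_mt = c(1L, 1L),
                                     X = c(0.3, 0.3), Y = c(1, 2))),
               "duplicate")
})

test_that("noiseless tables recover the generating coefficients exactly", {
  betas <- c(0.10, 0.39, 0.38, 0.07)
  tab <- simulate_rate_table(betas, n_specificities = 10, sigma = 0, seed = 2)
  fit <- fit_compensatory_model(tab, "full")
  expect_equal(unname(coef(fit)), betas, tolerance = 1e-12)
  expect_lt(fit$sse, 1e-20)
  # constant Y collapses onto the intercept
  tabc <- tab; tabc$Y <- 0.5
  fitc <- fit_compensatory_model(rate_table(tabc), "full")
  expect_equal(unname(coef(fitc)), c(0.5, 0, 0, 0), tolerance = 1e-10)
})

test_that("OLS agrees with a pseudo-inverse oracle and residuals are orthogonal", {
  set.seed(61)
  for (i in 1:10) {
    tab <- simulate_rate_table(runif(4, -0.2, 0.6), n_specificities = 15,
                               sigma = 0.1, seed = 500 + i)
    fit <- fit_compensatory_model(tab, "full")
    D <- model.matrix(~ delta_mt + X + delta_mt:X, tab)
    expect_equal(unname(coef(fit)), oracle_ols_pinv(D, tab$Y), tolerance = 1e-8)
    r <- residuals(fit)
    expect_lt(max(abs(crossprod(D, r))), 1e-8 * nrow(tab))
  }
})

test_that("SSE is non-increasing with model complexity and F-tests behave", {
  tab <- simulate_rate_table(c(0.1, 0.3, 0.4, 0.1), 30, 0.05, seed = 9)
  f0 <- fit_compensatory_model(tab, "intercepts_only")
  f1 <- fit_compensatory_model(tab, "no_interaction")
  f2 <- fit_compensatory_model(tab, "full")
  expect_gte(f0$sse, f1$sse)
  expect_gte(f1$sse, f2$sse)
  cmp <- nested_f_test(f1, f2)
  expect_gte(cmp$f_statistic, 0)
  expect_equal(cmp$df_num, 1L)
  expect_error(nested_f_test(f2, f1), "not nested")
  # identical SSE gives F = 0, p = 1
  fake <- f2; fake$sse <- f1$sse; fake$model_tag <- "full"
  cmp0 <- nested_f_test(f1, fake)
  expect_equal(cmp0$f_statistic, 0)
  expect_equal(cmp0$p_value, 1)
})

test_that("the slope test has power when beta2 is strong", {
  hits <- 0L
  for (i in 1:50) {
    tab <- simulate_rate_table(c(0.10, 0.39, 0.38, 0), n_specificities = 25,
                               sigma = 0.01, seed = 7000 + i)
    sel <- select_parsimonious_model(tab)
    if (sel$comparisons$slope$p_value < 0.001) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})

test_that("parallel-lines structure emerges when beta1 > 0 and beta3 = 0", {
  tab <- simulate_rate_table(c(0.10, 0.39, 0.38, 0), 100, 0.02, seed = 15)
  sel <- select_parsimonious_model(tab)
  expect_identical(sel$selected_tag, "no_interaction")
  co <- coef(sel$selected)
  # shared slope, distinct intercepts
  expect_equal(unname(co["beta2"]), 0.38, tolerance = 0.1)
  expect_gt(unname(co["beta1"]), 0.3)
})

test_that("mt/cy rate correlation computes Pearson r with guards", {
  tab <- data.frame(specificity = rep(c("L", "K", "F", "S"), each = 2),
                    delta_mt = rep(c(1L, 0L), 4),
                    X = rep(c(0.2, 0.3, 0.4, 0.5), each = 2),
                    Y = c(0.4, 0.2, 0.6, 0.3, 0.8, 0.4, 1.0, 0.5))
  ct <- mt_cy_rate_correlation(rate_table(tab))
  expect_equal(ct$r, 1.0)            # Y_cy = Y_mt / 2 exactly
  expect_equal(ct$n, 4L)
  expect_error(mt_cy_rate_correlation(rate_table(tab[1:2, ])), ">= 3")
})

test_that("rate tables round-trip through TSV", {
  tab <- simulate_rate_table(c(0.1, 0.4, 0.4, 0.05), 8, 0.03, seed = 77)
  f <- tempfile()
  write_rate_table(tab, f, comment = "seed 77")
  back <- read_rate_table(f)
  expect_equal(back$Y, tab$Y, tolerance = 1e-10)
  expect_identical(back$specificity, tab$specificity)
})
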