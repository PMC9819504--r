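test_that("OLS line matches the normal-equations closed form", {
  # exact degenerate case
  fit <- fit_qsar(c(0, 1, 2), c(1, 2, 3))
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  # random instances against the independent oracle
  set.seed(21)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    x <- runif(n, -10, 10)
    y <- runif(n, -10, 10)
    f <- fit_qsar(x, y)
    o <- ols_oracle(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    # absolute scale: R2 can sit arbitrarily close to 0 on random data
    expect_lt(abs(f$r_squared - o$r_squared), 1e-10)
    expect_lt(abs(f$sdep - o$sdep), 1e-10)
  }
})

test_that("fit summaries satisfy the OLS identities", {
  set.seed(22)
  x <- runif(20, 0, 8)
  y <- 2 - 0.5 * x + rnorm(20, 0, 0.3)
  f <- fit_qsar(x, y)
  # residuals sum to zero with an intercept
  expect_lt(abs(sum(f$residuals)), 1e-9)
  # R2 = squared Pearson correlation of y with fitted values
  expect_equal(f$r_squared, cor(y, f$fitted)^2, tolerance = 1e-10)
  # SDEP is the population RMS of residuals
  expect_equal(f$sdep, sqrt(sum(f$residuals^2) / f$n), tolerance = 1e-12)
  # shifting the response shifts only the intercept
  g <- fit_qsar(x, y + 3)
  expect_equal(g$intercept, f$intercept + 3, tolerance = 1e-10)
  expect_equal(g$slope, f$slope, tolerance = 1e-10)
  expect_equal(g$r_squared, f$r_squared, tolerance = 1e-10)
  expect_equal(g$sdep, f$sdep, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected or defined deliberately", {
  expect_error(fit_qsar(1, 1), "at least 2")
  expect_error(fit_qsar(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(fit_qsar(c(1, 2), c(1, 2, 3)), "lengths differ")
  expect_error(fit_qsar(c(1, NA), c(1, 2)), "finite")
  # zero-variance response: slope 0, R2 defined as 0, with a warning
  expect_warning(f0 <- fit_qsar(c(0, 1), c(5, 5)), "zero variance")
  expect_equal(f0$slope, 0)
  expect_equal(f0$r_squared, 0)
  # small samples are fit but flagged
  expect_true("SMALL_SAMPLE" %in% fit_qsar(c(0, 1, 2), c(1, 2.1, 2.9))$flags)
  expect_false("SMALL_SAMPLE" %in%
                 fit_qsar(runif(6), rnorm(6))$flags)
})

test_that("the organophosphate narcosis fit equals the oracle", {
  # the 10 unique reported-narcosis records: duplicate DEP dropped,
  # transition TPP excluded
  d <- organophosphate_esters()
  d <- d[!duplicated(d$cas), ]
  d <- d[d$reported_type == "N", ]
  expect_equal(nrow(d), 10)
  f <- fit_qsar(d$log_kow, d$log_lc50)
  o <- ols_oracle(d$log_kow, d$log_lc50)
  expect_equal(f$slope, o$slope, tolerance = 1e-12)
  expect_equal(f$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(f$r_squared, o$r_squared, tolerance = 1e-12)
  # frozen oracle values for this dataset
  expect_equal(f$slope, -0.5714991, tolerance = 1e-6)
  expect_equal(f$intercept, 2.6080104, tolerance = 1e-6)
  expect_equal(f$r_squared, 0.8795567, tolerance = 1e-6)
  # prediction applies the line; OLS passes through the centroid
  expect_equal(predict(f, 4.70), f$intercept + f$slope * 4.70)
  expect_equal(predict(f, mean(d$log_kow)), mean(d$log_lc50),
               tolerance = 1e-9)
})

test_that("fit methods behave as a classed model object", {
  set.seed(23)
  x <- runif(10, 0, 8)
  f <- fit_qsar(x, 2 - 0.5 * x + rnorm(10, 0, 0.2))
  expect_named(coef(f), c("intercept", "slope"))
  expect_length(residuals(f), 10)
  expect_equal(predict(f, data.frame(log_kow = c(1, 2))),
               f$intercept + f$slope * c(1, 2))
  sims <- simulate(f, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(10L, 3L))
  expect_identical(sims, simulate(f, nsim = 3, seed = 5))
  expect_output(print(f), "QSAR line")
})

test_that("improvement percentages follow both denominator conventions", {
  imp <- improvement_percent(0.74, 0.81)
  expect_equal(round(imp$as_reported_pct, 2), 8.64)
  expect_equal(round(imp$as_defined_pct, 2), 9.46)
  expect_equal(imp$as_defined_pct, (0.81 - 0.74) / 0.74 * 100,
               tolerance = 1e-9)
  expect_equal(imp$as_reported_pct, (0.81 - 0.74) / 0.81 * 100,
               tolerance = 1e-9)
  # equal inputs: zero under both; sign tracks the direction of change
  eq <- improvement_percent(0.8, 0.8)
  expect_equal(eq$as_defined_pct, 0)
  expect_equal(eq$as_reported_pct, 0)
  dn <- improvement_percent(0.9, 0.85)
  expect_lt(dn$as_defined_pct, 0)
  expect_lt(dn$as_reported_pct, 0)
  expect_error(improvement_percent(0, 0.5), "r2_initial")
  expect_error(improvement_percent(1.2, 0.5), "r2_initial")
  expect_error(improvement_percent(0.5, 0), "r2_improved")
})
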