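test_that("screening partitions the organophosphate table with reasons", {
  d <- organophosphate_esters()
  s <- screen_compounds(d)
  # recomputed TRO keeps 9: duplicate DEP out, transition TPP out, and
  # tricresyl phosphate out because its recomputed log TRO (7.31) is reactive
  expect_equal(nrow(s$retained), 9)
  expect_equal(nrow(s$excluded), 3)
  expect_equal(nrow(s$retained) + nrow(s$excluded), nrow(d))
  reasons <- setNames(s$excluded$exclusion_reason, s$excluded$abbreviation)
  expect_equal(unname(reasons["TPP"]), "MOA_CLASS_NOT_RETAINED")
  expect_equal(unname(reasons["TCP"]), "MOA_CLASS_NOT_RETAINED")
  expect_equal(unname(reasons["DEP"]), "DUPLICATE")
  # all retained are narcosis, input order preserved
  expect_true(all(s$retained$moa == "NARCOSIS"))
  expect_equal(s$retained$name,
               d$name[d$name %in% s$retained$name & !duplicated(d$name)])
})

test_that("retain set, dedupe flag and unclassified rows are honoured", {
  d <- organophosphate_esters()
  # retaining all classes leaves only the duplicate excluded
  s_all <- screen_compounds(d, retain = c("NARCOSIS", "TRANSITION", "REACTIVE"))
  expect_equal(s_all$excluded$exclusion_reason, "DUPLICATE")
  # dedupe off: both DEP rows retained
  s_nodedupe <- screen_compounds(d, retain = c("NARCOSIS", "TRANSITION",
                                               "REACTIVE"), dedupe = FALSE)
  expect_equal(nrow(s_nodedupe$excluded), 0)
  # retaining transition keeps tripropyl phosphate
  s_t <- screen_compounds(d, retain = c("NARCOSIS", "TRANSITION"))
  expect_true("TPP" %in% s_t$retained$abbreviation)
  # records without endpoints are excluded as UNCLASSIFIED
  miss <- make_compounds(c(2, 3), c(1, 2), c(NA, NA))
  sm <- screen_compounds(miss)
  expect_equal(sm$excluded$exclusion_reason, c("UNCLASSIFIED", "UNCLASSIFIED"))
  expect_equal(nrow(sm$retained), 0)
  expect_error(screen_compounds(d[0, ]), "empty")
})

test_that("screening is idempotent, deterministic and never grows the set", {
  d <- organophosphate_esters()
  s1 <- screen_compounds(d)
  s2 <- screen_compounds(s1$retained)
  expect_equal(nrow(s2$excluded), 0)
  expect_equal(s2$retained$name, s1$retained$name)
  expect_identical(screen_compounds(d), s1)
  fit <- tro_qsar(data = d)
  expect_lte(fit$model_screened$n, fit$model_initial$n)
})

test_that("screen-and-fit improves the organophosphate regression", {
  fit <- tro_qsar(data = organophosphate_esters())
  expect_gt(fit$model_screened$r_squared, fit$model_initial$r_squared)
  # both fits agree with the independent closed form on their own subsets
  d <- organophosphate_esters()
  dd <- d[!duplicated(d$cas), ]
  o_init <- ols_oracle(dd$log_kow, dd$log_lc50)
  expect_equal(fit$model_initial$r_squared, o_init$r_squared,
               tolerance = 1e-12)
  expect_equal(fit$model_initial$n, 11)
  ev <- evaluate_tro(dd)
  narc <- ev[ev$moa == "NARCOSIS", ]
  o_scr <- ols_oracle(narc$log_kow, narc$log_lc50)
  expect_equal(fit$model_screened$slope, o_scr$slope, tolerance = 1e-12)
  expect_equal(fit$model_screened$r_squared, o_scr$r_squared,
               tolerance = 1e-12)
  # improvement is wired through from the two fits
  expect_equal(fit$improvement$r2_initial, fit$model_initial$r_squared)
  expect_equal(fit$improvement$r2_improved, fit$model_screened$r_squared)
})

test_that("a purely narcotic dataset yields identical fits", {
  d <- simulate_compounds(synthetic_config(n_narcosis = 25, n_reactive = 0,
                                           seed = 3))
  fit <- tro_qsar(data = d)
  expect_equal(fit$model_screened$slope, fit$model_initial$slope,
               tolerance = 1e-12)
  expect_equal(fit$model_screened$intercept, fit$model_initial$intercept,
               tolerance = 1e-12)
  expect_equal(fit$model_screened$r_squared, fit$model_initial$r_squared,
               tolerance = 1e-12)
})

test_that("screening pulls the slope toward the generating value", {
  cfg <- synthetic_config(seed = 1)
  d <- simulate_compounds(cfg)
  fit <- tro_qsar(data = d)
  expect_lt(abs(fit$model_screened$slope - cfg$slope),
            abs(fit$model_initial$slope - cfg$slope))
})

test_that("descriptor tiers follow the mode of action", {
  expect_equal(select_descriptor_tier("NARCOSIS"), "2D: log KOW")
  expect_match(select_descriptor_tier("REACTIVE"), "quantum")
  expect_match(select_descriptor_tier("TRANSITION"), "caution")
  expect_match(select_descriptor_tier("UNCLASSIFIED"), "insufficient")
  expect_length(select_descriptor_tier(factor(c("NARCOSIS", "REACTIVE"))), 2)
  expect_error(select_descriptor_tier("BASELINE"), "unknown")
})

test_that("tro_qsar model methods expose both fits", {
  fit <- tro_qsar(data = organophosphate_esters())
  cf <- coef(fit)
  expect_equal(rownames(cf), c("initial", "screened"))
  expect_equal(unname(cf["screened", "slope"]), fit$model_screened$slope)
  expect_equal(predict(fit, 4.70),
               fit$model_screened$intercept + fit$model_screened$slope * 4.70)
  expect_equal(predict(fit, 4.70, model = "initial"),
               fit$model_initial$intercept + fit$model_initial$slope * 4.70)
  expect_length(residuals(fit), fit$model_screened$n)
  expect_output(print(fit), "retained")
  expect_output(print(summary(fit)), "Excluded records")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
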