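# Fit indices and model comparison.

test_that("fit indices reproduce their defining formulas", {
  fi <- fit_indices(50, 10, 100, 20, 500, 45)
  expect_equal(fi$CFI, 1 - 40 / 455, tolerance = 1e-12)
  expect_equal(fi$MFI, exp(-0.2), tolerance = 1e-12)
  expect_equal(fi$ECVI, 0.90, tolerance = 1e-12)
})

test_that("index boundary behaviour matches definitions", {
  expect_equal(fit_indices(10, 10, 50, 5, 100, 9)$MFI, 1)
  S <- diag(2); dimnames(S) <- list(c("a", "b"), c("a", "b"))
  perfect <- fit_indices(0, 3, 100, 2, 80, 1, S = S, Sigma_hat = S)
  expect_equal(perfect$SRMR, 0)
  expect_equal(perfect$CFI, 1)
  # a worse-than-baseline model cannot push CFI above 1 or below 0
  expect_gte(fit_indices(900, 5, 100, 3, 50, 10)$CFI, 0)
})

test_that("SRMR measures correlation-metric residuals", {
  S <- matrix(c(4, 1, 1, 1), 2); dimnames(S) <- list(c("a", "b"), c("a", "b"))
  Sh <- S; Sh["a", "b"] <- Sh["b", "a"] <- 0
  fi <- fit_indices(1, 1, 100, 2, 10, 1, S = S, Sigma_hat = Sh)
  expect_equal(fi$SRMR, sqrt(mean(c(0, 0.5, 0)^2)))
})

test_that("model comparison flags directions and nested differences", {
  dat <- generate_cohort(clean_config(1000, factor_scheme = "one_factor"),
                         seed = 21)
  proc <- preprocess_cohort(dat$cohort)
  m1 <- build_model(model_variant("one_factor", "hormones_saliva_only",
                                  sameday_saliva = FALSE))
  m2 <- build_model(model_variant("one_factor", "hormones_saliva_only",
                                  sameday_saliva = TRUE))
  f1 <- ml_fit(m1, data = proc)
  f2 <- ml_fit(m2, data = proc)
  cmp <- compare_models(without = f1, with_sameday = f2)
  expect_equal(cmp$delta_df[2], 12)
  expect_gt(cmp$delta_chisq[2], 100)
  expect_lt(cmp$delta_p[2], 0.001)
  expect_true(all(attr(cmp, "favoured") == "with_sameday"))
  # identical model twice: zero differences
  cmp2 <- compare_models(a = f1, b = f1)
  expect_equal(cmp2$delta_chisq[2], 0)
  expect_equal(cmp2$delta_df[2], 0)
})

test_that("comparison refuses fits on different sample sizes", {
  d1 <- generate_cohort(clean_config(300), seed = 1)
  d2 <- generate_cohort(clean_config(301), seed = 1)
  m <- parse_model("sal_t =~ saliva_t_1 + saliva_t_2 + saliva_t_3")
  f1 <- ml_fit(m, data = preprocess_cohort(d1$cohort))
  f2 <- ml_fit(m, data = preprocess_cohort(d2$cohort))
  expect_error(compare_models(f1, f2), "different sample sizes")
})

test_that("saturated versus independence difference equals the baseline statistic", {
  dat <- generate_cohort(clean_config(500), seed = 33)
  proc <- preprocess_cohort(dat$cohort)
  vars <- c("saliva_t_1", "saliva_t_2", "saliva_t_3")
  sat_syntax <- c(paste(vars, "~~", vars),
                  utils::combn(vars, 2, function(p) paste(p[1], "~~", p[2])))
  indep_syntax <- paste(vars, "~~", vars)
  fs <- ml_fit(parse_model(sat_syntax), data = proc)
  fi <- quiet_ml_fit(parse_model(indep_syntax), data = proc, check_id = TRUE)
  expect_lt(fs$chisq, 1e-6)
  expect_equal(fi$chisq - fs$chisq, fs$baseline$chisq, tolerance = 1e-4)
})
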