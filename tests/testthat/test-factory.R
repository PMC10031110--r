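# Model factory: variant topologies, shared variance, series, strata.

test_that("the full two-factor model has the published topology counts", {
  m <- build_model(model_variant("two_factor", "full_multimethod"))
  expect_length(m$obs, 19)       # 7 self-report + 12 saliva
  expect_length(m$latents, 7)    # 3 saliva + 2 self-report + ADR + GON
  m1 <- build_model(model_variant("one_factor", "full_multimethod"))
  expect_setequal(m1$obs, m$obs) # identical observed sets across schemes
})

test_that("correlated-uniqueness toggling only adds questionnaire residual covariances", {
  off <- build_model(model_variant("two_factor", "selfreport_only",
                                   correlated_uniqueness_questionnaire = FALSE))
  on <- build_model(model_variant("two_factor", "selfreport_only",
                                  correlated_uniqueness_questionnaire = TRUE))
  extra <- setdiff(on$labels, off$labels)
  expect_length(extra, 7)   # 6 cross-process PDS pairs + the LD pair
  expect_true(all(grepl("~~", extra)))
  expect_equal(model_df(off) - model_df(on), 7)
})

test_that("the hair-DHEA loading can be pinned to zero", {
  m <- build_model(model_variant("two_factor", "hormones_saliva_hair",
                                 hair_dhea_constrained_zero = TRUE))
  tab <- m$params
  row <- tab[tab$mat == "A" & tab$row == "hair_dhea", ]
  expect_false(row$free)
  expect_equal(row$value, 0)
})

test_that("same-day covariances change the df by exactly 12", {
  with_cov <- build_model(model_variant("one_factor", "hormones_saliva_only",
                                        sameday_saliva = TRUE))
  without <- build_model(model_variant("one_factor", "hormones_saliva_only",
                                       sameday_saliva = FALSE))
  expect_equal(model_df(without) - model_df(with_cov), 12)
})

test_that("an unidentifiable variant raises the equivalence diagnostic", {
  expect_error(build_model(model_variant("two_factor", "hormones_saliva_only")),
               "not identified")
})

test_that("shared variance squares and rounds the correlation", {
  expect_equal(shared_variance(0), 0)
  expect_equal(shared_variance(1), 100)
  expect_equal(shared_variance(-0.5), 25)
  expect_equal(shared_variance(c(0.953, 0.554)), 28)  # path product
  expect_error(shared_variance(1.2), "> 1")
})

test_that("the model series applies the estimator ladder and compares fits", {
  dat <- generate_cohort(clean_config(700, factor_scheme = "one_factor"),
                         seed = 51)
  proc <- preprocess_cohort(dat$cohort)
  series <- run_model_series(proc, list(
    saliva = model_variant("one_factor", "hormones_saliva_only"),
    saliva_nocov = model_variant("one_factor", "hormones_saliva_only",
                                 sameday_saliva = FALSE)))
  expect_s3_class(series$fits$saliva, "pubsem_fit")
  expect_equal(series$fits$saliva$estimator, "ML")
  expect_s3_class(series$comparison, "pubsem_comparison")
  expect_true(all(c("lhs", "rhs", "std") %in% names(series$loadings$saliva)))
  # a failing variant is annotated, not fatal
  series2 <- run_model_series(proc, list(
    bad = model_variant("two_factor", "hormones_saliva_only")))
  expect_s3_class(series2$fits$bad, "pubsem_fit_error")
})

test_that("stratified fits mirror the unstratified fit for a constant stratifier", {
  dat <- generate_cohort(clean_config(600), seed = 52)
  proc <- preprocess_cohort(dat$cohort)
  m <- parse_model("sal_t =~ saliva_t_1 + saliva_t_2 + saliva_t_3 + saliva_t_4")
  res <- stratified_fit(proc, m, rep("all", nrow(proc)))
  flat <- ml_fit(m, data = proc)
  expect_equal(res$fits$all$theta, flat$theta, tolerance = 1e-8)
  expect_error(stratified_fit(proc[0, ], m, character(0)), "empty stratum")
})

test_that("identical truth in both strata yields similar loadings", {
  dat <- generate_cohort(clean_config(1600), seed = 53)
  proc <- preprocess_cohort(dat$cohort)
  m <- parse_model("sal_dhea =~ saliva_dhea_1 + saliva_dhea_2 + saliva_dhea_3 + saliva_dhea_4")
  strat <- rep(c("lo", "hi"), length.out = nrow(proc))
  res <- stratified_fit(proc, m, strat)
  expect_lt(max(abs(res$loadings$std_lo - res$loadings$std_hi)), 0.12)
  expect_error(
    stratified_fit(proc[1:8, ], m, rep("x", 8)), "fewer cases")
})

test_that("tanner-stage strata route through pds_stage", {
  dat <- generate_cohort(clean_config(900), seed = 54)
  proc <- preprocess_cohort(dat$cohort)
  series <- run_model_series(proc, list(
    hi = model_variant("one_factor", "hormones_saliva_only",
                       stratum = "pds_stage_ge3"),
    lo = model_variant("one_factor", "hormones_saliva_only",
                       stratum = "pds_stage_lt3")))
  ns <- vapply(series$fits, `[[`, numeric(1), "n")
  expect_equal(sum(ns), sum(!is.na(proc$pds_stage)))
})
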