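# Region-wise thickness-factor associations.

test_that("effect bands classify with the documented boundary rule", {
  m <- classify_effects(data.frame(r = c(0, 0.05, 0.1, 0.15, 0.3, 0.43, 0.6, -0.35)))
  expect_equal(m$band,
               c("weak", "weak", "small", "small", "medium", "medium",
                 "large", "medium"))
  expect_error(classify_effects(data.frame(r = 0.2), bands = c(a = 0.3, b = 0.1)),
               "increasing")
})

test_that("a region simulated independent of the factor shows no association", {
  dat <- generate_cohort(clean_config(1500, factor_scheme = "one_factor"),
                         seed = 61)
  proc <- preprocess_cohort(dat$cohort)
  res <- fit_region(proc, dat$thickness, "lh_insula",
                    model_variant("one_factor", "full_multimethod"))
  expect_true(res$converged)
  expect_lt(abs(res$r), 0.08)
})

test_that("a planted negative effect is recovered by the region model", {
  dat <- generate_cohort(clean_config(2000, factor_scheme = "one_factor"),
                         seed = 62)
  proc <- preprocess_cohort(dat$cohort)
  res <- fit_region(proc, dat$thickness, "rh_lateraloccipital",
                    model_variant("one_factor", "full_multimethod"))
  expect_lt(abs(res$r - (-0.30)), 0.06)
})

test_that("fitting the exact implied covariance returns the configured effect", {
  cfg <- clean_config(50, factor_scheme = "one_factor")
  Sigma <- implied_population_covariance(cfg)
  v <- model_variant("one_factor", "full_multimethod")
  base <- build_model(v, check_id = FALSE)
  keep <- c(base$obs[base$obs != "cth"], "lh_cuneus")
  Ssub <- Sigma[c(base$obs, "lh_cuneus"), c(base$obs, "lh_cuneus")]
  rownames(Ssub)[nrow(Ssub)] <- colnames(Ssub)[ncol(Ssub)] <- "cth"
  model <- parse_model(c(base$syntax, "cth ~~ cth", "PUB ~~ cth"))
  fit <- ml_fit(model, sample_cov = Ssub, n = 10000)
  V <- implied_cov_all(model, fit$theta)$V
  r <- V["cth", "PUB"] / sqrt(V["cth", "cth"] * V["PUB", "PUB"])
  expect_equal(r, -0.30, tolerance = 1e-3)
  expect_lt(fit$chisq / 10000, 1e-6)
})

test_that("the sweep is deterministic and errors on missing regions", {
  dat <- generate_cohort(clean_config(400, factor_scheme = "one_factor"),
                         seed = 63)
  proc <- preprocess_cohort(dat$cohort)
  regions <- c("lh_cuneus", "lh_insula")
  v <- list(mm = model_variant("one_factor", "full_multimethod"))
  m1 <- brain_sweep(proc, dat$thickness, v, regions = regions)
  m2 <- brain_sweep(proc, dat$thickness, v, regions = regions)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 2)
  expect_true(all(c("r", "band", "age_mode") %in% names(m1)))
  expect_error(brain_sweep(proc, dat$thickness, v, regions = "lh_nowhere"),
               "lh_nowhere")
})

test_that("age-mediated thickness effects vanish when age is partialled out", {
  cfg <- clean_config(3000, factor_scheme = "one_factor",
                      thickness_age_mediated = TRUE)
  dat <- generate_cohort(cfg, seed = 64)
  proc <- preprocess_cohort(dat$cohort)
  un <- fit_region(proc, dat$thickness, "lh_cuneus",
                   model_variant("one_factor", "full_multimethod",
                                 age_mode = "none"))
  ad <- fit_region(proc, dat$thickness, "lh_cuneus",
                   model_variant("one_factor", "full_multimethod",
                                 age_mode = "regress"))
  expect_gt(abs(un$r), 0.15)     # carried by the factor-age correlation
  expect_lt(abs(ad$r), 0.05)     # partialled association collapses
})

test_that("two-factor sweeps report both factors per region", {
  dat <- generate_cohort(clean_config(900), seed = 65)
  proc <- preprocess_cohort(dat$cohort)
  res <- fit_region(proc, dat$thickness, "lh_cuneus",
                    model_variant("two_factor", "full_multimethod"))
  expect_equal(res$factor, c("ADR", "GON"))
  expect_equal(res$hemi, c("lh", "lh"))
})
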