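# Synthetic cohort generator: implied covariance, draws, missingness.

test_that("implied covariance is diagonal when every path is zero", {
  S <- implied_population_covariance(null_config())
  off <- S[upper.tri(S)]
  expect_lt(max(abs(off)), 1e-12)
  expect_equal(unname(S["pds1", "pds1"]), 1)        # latent item response
  expect_equal(unname(S["age", "age"]), 0.81^2)
})

test_that("a two-indicator factor reproduces the path-tracing product", {
  cfg <- null_config()
  # pds4 and ld1 both load on the self-report gonadal factor
  cfg$true_loadings[c("pds4", "ld1")] <- c(0.8, 0.5)
  S <- implied_population_covariance(cfg)
  expect_equal(unname(S["pds4", "ld1"]), 0.40, tolerance = 1e-12)
  expect_equal(unname(S["pds4", "pds4"]), 1)
})

test_that("configured structure matches the large-sample correlation matrix", {
  cfg <- clean_config(1e5)
  lat <- generate_cohort(cfg, seed = 99, raw_scale = FALSE)
  X <- cbind(as.matrix(lat$cohort[-1]), as.matrix(lat$thickness[-1]))
  implied <- stats::cov2cor(implied_population_covariance(cfg))
  emp <- cor(X)[rownames(implied), colnames(implied)]
  expect_lt(max(abs(emp - implied)), 0.02)
})

test_that("sample correlation of generated saliva samples matches the implied value", {
  cfg <- clean_config(2000)
  dat <- generate_cohort(cfg, seed = 7)
  implied <- stats::cov2cor(implied_population_covariance(cfg))
  r_emp <- cor(log(dat$cohort$saliva_dhea_1), log(dat$cohort$saliva_dhea_2))
  expect_lt(abs(r_emp - implied["saliva_dhea_1", "saliva_dhea_2"]), 0.05)
})

test_that("generation is deterministic given the seed and has the declared shape", {
  cfg <- cohort_config(n_participants = 174)
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a$cohort), 174)
  expect_equal(ncol(a$thickness), 69)   # id + 68 regions
  expect_false(identical(a, generate_cohort(cfg, seed = 6)))
})

test_that("generated indicators respect their declared ranges", {
  dat <- generate_cohort(cohort_config(n_participants = 500), seed = 3)
  co <- dat$cohort
  for (it in c("pds1", "pds2", "pds3", "pds4"))
    expect_true(all(co[[it]] %in% 1:4 | is.na(co[[it]])))
  expect_true(all(co$pds6 %in% 0:1 | is.na(co$pds6)))
  for (it in c("ld1", "ld2"))
    expect_true(all(co[[it]] %in% 1:5 | is.na(co[[it]])))
  sal <- unlist(co[grep("^saliva_(dhea|t|e2)_", names(co))])
  expect_true(all(sal > 0 | is.na(sal)))
  th <- unlist(dat$thickness[-1])
  expect_true(all(th > 0 | is.na(th)))
})

test_that("ordinal item frequencies match the threshold-implied probabilities", {
  cfg <- clean_config(2e4)
  dat <- generate_cohort(cfg, seed = 17)
  tau <- cfg$item_thresholds$pds2
  probs <- diff(c(0, pnorm(tau), 1))
  freq <- as.numeric(table(factor(dat$cohort$pds2, levels = 1:4))) / 2e4
  # binomial error at n = 2e4 is ~0.004; allow 3 sigma
  expect_lt(max(abs(freq - probs)), 3 * sqrt(max(probs * (1 - probs)) / 2e4) + 1e-3)
})

test_that("hormone marginals are log-normal on the descriptive-table scale", {
  cfg <- clean_config(1e5)
  dat <- generate_cohort(cfg, seed = 23)
  x <- dat$cohort$saliva_t_1
  expect_lt(abs(mean(x) - 40.4) / 40.4, 0.05)
  expect_lt(abs(sd(x) - 24.1) / 24.1, 0.10)
  expect_gt(mean((x - mean(x))^3) , 0)   # positive skew
})

test_that("outlier injection plants values beyond 3 SD on the log scale", {
  cfg <- clean_config(5e4)
  cfg$outlier_rate <- 0.01
  dat <- generate_cohort(cfg, seed = 31)
  z <- scale(log(dat$cohort$saliva_dhea_1))
  expect_gt(mean(z > 3), 0.004)   # about 1% planted high outliers
})

test_that("non-positive-semi-definite configurations are rejected with the eigenvalue", {
  expect_error(
    implied_population_covariance(
      clean_config(10, age_correlations = c(ADR = 0.10, GON = 0.99))),
    "eigenvalue")
  bad <- clean_config(10)
  bad$true_loadings["pds2"] <- 1.2
  expect_error(implied_population_covariance(bad), "communality")
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(factor_correlation = 1.5), "factor_correlation")
  expect_error(cohort_config(item_thresholds = modifyList(
    default_item_thresholds(), list(ld1 = c(0, 0, 1, 2)))), "increasing")
  expect_error(cohort_config(true_loadings = c(nope = 0.5)), "unknown indicator")
})

test_that("missingness injection is MCAR at the configured rate", {
  cfg <- clean_config(5000)
  dat <- generate_cohort(cfg, seed = 2)
  expect_identical(inject_missingness(dat$cohort, list(saliva = 0), seed = 1),
                   dat$cohort)
  allhair <- inject_missingness(dat$cohort, list(hair = 1), seed = 1)
  expect_true(all(is.na(allhair$hair_dhea)))
  expect_false(anyNA(allhair$saliva_dhea_1))
  some <- inject_missingness(dat$cohort, list(saliva = 0.1), seed = 1)
  frac <- mean(is.na(unlist(some[grep("^saliva_(dhea|t|e2)_", names(some))])))
  expect_gt(frac, 0.08); expect_lt(frac, 0.12)
  expect_error(inject_missingness(dat$cohort, list(saliva = 1.5)), "rates")
})
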