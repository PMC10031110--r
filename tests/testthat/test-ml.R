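# Maximum-likelihood estimation: closed forms, fixed points, baseline.

three_names <- c("x1", "x2", "x3")

test_that("a just-identified one-factor model is saturated and matches the closed form", {
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  dimnames(S) <- list(three_names, three_names)
  fit <- ml_fit(parse_model("f =~ x1 + x2 + x3"), sample_cov = S, n = 100)
  expect_equal(fit$df, 0)
  expect_lt(fit$chisq, 1e-6)
  # lambda_1 = sqrt(s12 * s13 / s23)
  expect_equal(unname(fit$theta[["f=~x1"]]), sqrt(0.5), tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("unequal covariances reproduce the spearman-style closed form", {
  S <- diag(3)
  S[1, 2] <- S[2, 1] <- 0.42
  S[1, 3] <- S[3, 1] <- 0.30
  S[2, 3] <- S[3, 2] <- 0.35
  dimnames(S) <- list(three_names, three_names)
  fit <- ml_fit(parse_model("f =~ x1 + x2 + x3"), sample_cov = S, n = 500)
  expect_equal(unname(fit$theta[["f=~x1"]]), sqrt(0.42 * 0.30 / 0.35),
               tolerance = 1e-4)
})

test_that("fitting to an exactly model-implied covariance recovers the parameters", {
  m <- build_model(model_variant("one_factor", "hormones_saliva_only",
                                 sameday_saliva = TRUE))
  theta0 <- start_values(m)
  theta0[] <- 0.6
  resid <- grepl("~~", names(theta0)) &
    sub("~~.*", "", names(theta0)) == sub(".*~~", "", names(theta0))
  theta0[resid] <- 0.8
  theta0[grepl("~~", names(theta0)) & !resid] <- 0.1
  Sigma0 <- implied_covariance(m, theta0)
  fit <- ml_fit(m, sample_cov = Sigma0, n = 5000)
  expect_lt(fit$chisq, 1e-4)
  expect_lt(max(abs(fit$theta - theta0)), 1e-3)
})

test_that("the independence baseline equals the closed form", {
  set.seed(21)
  X <- as.data.frame(matrix(rnorm(300 * 4), 300, 4))
  names(X) <- paste0("x", 1:4)
  fit <- quiet_ml_fit(parse_model("f =~ x1 + x2 + x3 + x4"), data = X)
  R <- stats::cov2cor(ml_sample_cov(X))
  expect_equal(fit$baseline$chisq,
               -300 * determinant(R, logarithm = TRUE)$modulus[1],
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(fit$baseline$df, 6)
})

test_that("Heywood solutions are flagged, not truncated", {
  S <- diag(3)
  S[1, 2] <- S[2, 1] <- 0.8
  S[1, 3] <- S[3, 1] <- 0.8
  S[2, 3] <- S[3, 2] <- 0.4   # lambda_1^2 = 0.8 * 0.8 / 0.4 = 1.6
  dimnames(S) <- list(three_names, three_names)
  expect_warning(fit <- ml_fit(parse_model("f =~ x1 + x2 + x3"),
                               sample_cov = S, n = 200),
                 "Heywood")
  expect_true(fit$heywood)
  expect_gt(abs(standardize(fit)$std[1]), 1)
})

test_that("input validation catches unusable samples", {
  S <- diag(3); dimnames(S) <- list(three_names, three_names)
  m <- parse_model("f =~ x1 + x2 + x3")
  expect_error(ml_fit(m, sample_cov = S, n = 3), "exceed")
  expect_error(ml_fit(m), "supply either")
  expect_error(ml_fit(m, data = data.frame(x1 = rnorm(10))), "lacks columns")
})

test_that("standardization maps the solution onto the correlation metric", {
  dat <- generate_cohort(clean_config(800), seed = 41)
  proc <- preprocess_cohort(dat$cohort)
  m <- parse_model(
    "sal_t =~ saliva_t_1 + saliva_t_2 + saliva_t_3 + saliva_t_4")
  fit <- ml_fit(m, data = proc)
  std <- standardize(fit)
  # standardized implied matrix is the correlation matrix of the raw one
  theta_std <- fit$theta
  lo <- std$mat == "A"
  # reconstruct: corr(x_i, x_j) = std_i * std_j for a one-factor model
  R <- stats::cov2cor(fit$Sigma)
  l <- std$std[lo]
  expect_equal(unname(R["saliva_t_1", "saliva_t_2"]), l[1] * l[2],
               tolerance = 1e-8)
  # a loading 2.0 with indicator variance 4 and unit factor variance
  m2 <- parse_model("f =~ 2*x\nx ~~ 0*x")
  V <- implied_cov_all(m2, numeric(0))$V
  expect_equal(V["x", "f"] / sqrt(V["x", "x"] * V["f", "f"]), 1)
})
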