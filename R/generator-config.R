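#' Synthetic cohort configuration
#'
#' Builds the configuration object that defines the population the synthetic
#' cohort is drawn from: a second-order latent structure (per-hormone saliva
#' factors and self-report factors under adrenarche/gonadarche, or a single
#' overall puberty factor), correlated with chronological age, with same-day
#' saliva residual covariance, log-normal hormone marginals on the scale of
#' the study's descriptive table, ordinal items cut from standard-normal
#' latent responses, planted region-wise cortical-thickness effects,
#' block-wise missingness and heavy upper-tail hormone outliers.
#'
#' Defaults encode the study conditions the package is designed around:
#' 174 participants aged 10.0-13.0 (mean 11.55, SD 0.81); saliva loadings in
#' the published ranges (DHEA 0.89-0.94, T 0.72-0.87, E2 0.71-0.90); hair
#' loadings at or below 0.4; an adrenarche-gonadarche correlation of 0.95;
#' age-factor correlations 0.58 (ADR) and 0.70 (GON); and a -0.30 thickness
#' correlation in posterior (occipital/parietal) regions, 0 elsewhere.
#'
#' @param n_participants number of participants (>= 1).
#' @param factor_scheme `"two_factor"` (ADR/GON) or `"one_factor"` (PUB).
#' @param true_loadings named numeric vector of indicator loadings on their
#'   first-order factor (items and saliva samples) or directly on the
#'   second-order factor (hair). Names must be cohort indicator columns.
#'   Values replace defaults entry-wise.
#' @param second_order_loadings named numeric vector of first-order factor
#'   loadings on the second-order factor(s). Names among
#'   `sal_dhea, sal_t, sal_e2, sr_adr, sr_gon` (two-factor) or
#'   `sal_dhea, sal_t, sal_e2, sr_pub` (one-factor).
#' @param factor_correlation ADR-GON correlation (two-factor scheme only).
#' @param age_correlations named vector of factor-age correlations.
#' @param sameday_residual_corr residual correlation among the three
#'   hormones' saliva samples collected on the same day.
#' @param hormone_marginals data frame with columns `hormone`, `mean`, `sd`
#'   on the raw (pre-log) concentration scale.
#' @param item_thresholds named list of strictly increasing cut points on
#'   the standard-normal latent response scale, one vector per ordinal item.
#' @param missing_rates named list of missing-completely-at-random rates per
#'   block (`selfreport`, `saliva`, `hair`, `thickness`), each in [0, 1].
#' @param outlier_rate per-cell probability of an injected hormone outlier.
#' @param outlier_magnitude location of injected outliers, in SDs on the
#'   log scale (> 3 so they exceed the winsorization cut).
#' @param thickness_effects named numeric vector over the 68 regions of
#'   [dk_regions()]: correlation between regional thickness and the overall
#'   pubertal composite (or, under `thickness_age_mediated`, with age).
#' @param thickness_marginals data frame `region`, `mean`, `sd` in mm.
#' @param thickness_age_mediated if `TRUE`, thickness correlates with age
#'   only, so any thickness-factor association is carried entirely by the
#'   factor-age correlation (pubertal "timing" null).
#' @param age_mean,age_sd age marginal in years.
#' @param seed default integer seed for [generate_cohort()].
#' @return an object of class `pubsem_config`.
#' @seealso [implied_population_covariance()], [generate_cohort()]
#' @export
cohort_config <- function(n_participants = 174,
                          factor_scheme = c("two_factor", "one_factor"),
                          true_loadings = NULL,
                          second_order_loadings = NULL,
                          factor_correlation = 0.95,
                          age_correlations = NULL,
                          sameday_residual_corr = 0.30,
                          hormone_marginals = default_hormone_marginals(),
                          item_thresholds = default_item_thresholds(),
                          missing_rates = list(selfreport = 0.02, saliva = 0.05,
                                               hair = 0.10, thickness = 0),
                          outlier_rate = 0.01,
                          outlier_magnitude = 4,
                          thickness_effects = default_thickness_effects(),
                          thickness_marginals = default_thickness_marginals(),
                          thickness_age_mediated = FALSE,
                          age_mean = 11.55, age_sd = 0.81,
                          seed = 1L) {
  factor_scheme <- match.arg(factor_scheme)

  loadings <- default_true_loadings()
  if (!is.null(true_loadings)) {
    bad <- setdiff(names(true_loadings), names(loadings))
    if (length(bad))
      stop("unknown indicator(s) in true_loadings: ", paste(bad, collapse = ", "))
    loadings[names(true_loadings)] <- true_loadings
  }

  so <- default_second_order_loadings(factor_scheme)
  if (!is.null(second_order_loadings)) {
    bad <- setdiff(names(second_order_loadings), names(so))
    if (length(bad))
      stop("unknown factor(s) in second_order_loadings: ",
           paste(bad, collapse = ", "))
    so[names(second_order_loadings)] <- second_order_loadings
  }

  if (is.null(age_correlations)) {
    age_correlations <- if (factor_scheme == "two_factor")
      c(ADR = 0.58, GON = 0.70) else c(PUB = 0.73)
  }

  te <- default_thickness_effects()
  if (!identical(thickness_effects, te)) {
    if (is.null(names(thickness_effects)) &&
        length(thickness_effects) == length(te)) {
      names(thickness_effects) <- names(te)
    } else {
      bad <- setdiff(names(thickness_effects), names(te))
      if (length(bad))
        stop("unknown region(s) in thickness_effects: ",
             paste(head(bad, 3), collapse = ", "))
      te[names(thickness_effects)] <- thickness_effects
      thickness_effects <- te
    }
  }

  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    factor_scheme = factor_scheme,
    true_loadings = loadings,
    second_order_loadings = so,
    factor_correlation = factor_correlation,
    age_correlations = age_correlations,
    sameday_residual_corr = sameday_residual_corr,
    hormone_marginals = hormone_marginals,
    item_thresholds = item_thresholds,
    missing_rates = missing_rates,
    outlier_rate = outlier_rate,
    outlier_magnitude = outlier_magnitude,
    thickness_effects = thickness_effects,
    thickness_marginals = thickness_marginals,
    thickness_age_mediated = isTRUE(thickness_age_mediated),
    age_mean = age_mean, age_sd = age_sd,
    seed = as.integer(seed)), class = "pubsem_config")
  validate_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @export
default_true_loadings <- function() {
  c(pds1 = 0.50, pds2 = 0.80, pds3 = 0.75, pds4 = 0.85, pds6 = 0.80,
    ld1 = 0.85, ld2 = 0.80,
    saliva_dhea_1 = 0.90, saliva_dhea_2 = 0.93,
    saliva_dhea_3 = 0.91, saliva_dhea_4 = 0.92,
    saliva_t_1 = 0.72, saliva_t_2 = 0.87,
    saliva_t_3 = 0.80, saliva_t_4 = 0.76,
    saliva_e2_1 = 0.72, saliva_e2_2 = 0.90,
    saliva_e2_3 = 0.80, saliva_e2_4 = 0.85,
    hair_dhea = 0.20, hair_t = 0.30, hair_e2 = 0.30)
}

#' @rdname cohort_config
#' @param factor_scheme see above.
#' @export
default_second_order_loadings <- function(factor_scheme = "two_factor") {
  if (factor_scheme == "two_factor")
    c(sal_dhea = 0.80, sal_t = 0.70, sr_adr = 0.80,
      sal_e2 = 0.60, sr_gon = 0.85)
  else
    c(sal_dhea = 0.85, sal_t = 0.75, sal_e2 = 0.65, sr_pub = 0.60)
}

#' @rdname cohort_config
#' @export
default_hormone_marginals <- function() {
  data.frame(
    hormone = c("saliva_dhea", "saliva_t", "saliva_e2",
                "hair_dhea", "hair_t", "hair_e2"),
    mean = c(104, 40.4, 0.91, 15.24, 1.81, 37.80),
    sd   = c(127, 24.1, 0.55, 14.84, 2.88, 15.82))
}

#' @rdname cohort_config
#' @export
default_item_thresholds <- function() {
  list(pds1 = c(-1, 0, 1), pds2 = c(-1, 0, 1), pds3 = c(-1, 0, 1),
       pds4 = c(-1, 0, 1), pds6 = 0.25,
       ld1 = c(-1.5, -0.5, 0.5, 1.5), ld2 = c(-1.5, -0.5, 0.5, 1.5))
}

#' @rdname cohort_config
#' @export
default_thickness_effects <- function() {
  eff <- setNames(rep(0, 68), dk_regions())
  eff[dk_posterior_regions()] <- -0.30
  eff
}

#' @rdname cohort_config
#' @export
default_thickness_marginals <- function() {
  data.frame(region = dk_regions(), mean = 2.55, sd = 0.12)
}

validate_config <- function(cfg) {
  if (cfg$n_participants < 1L) stop("n_participants must be >= 1")
  if (abs(cfg$factor_correlation) > 1) stop("factor_correlation outside [-1, 1]")
  if (abs(cfg$sameday_residual_corr) > 1)
    stop("sameday_residual_corr outside [-1, 1]")
  if (any(abs(cfg$age_correlations) > 1)) stop("age correlation outside [-1, 1]")
  if (any(abs(cfg$thickness_effects) > 1)) stop("thickness effect outside [-1, 1]")
  for (item in names(cfg$item_thresholds)) {
    tau <- cfg$item_thresholds[[item]]
    if (length(tau) >= 2 && any(diff(tau) <= 0))
      stop("item_thresholds for ", item, " must be strictly increasing")
  }
  rates <- unlist(cfg$missing_rates)
  if (any(rates < 0 | rates > 1)) stop("missing rates must lie in [0, 1]")
  if (any(cfg$hormone_marginals$mean <= 0) || any(cfg$hormone_marginals$sd <= 0))
    stop("hormone marginal means and SDs must be positive")
  invisible(cfg)
}

#' @export
print.pubsem_config <- function(x, ...) {
  cat("Synthetic pubertal cohort configuration\n")
  cat("  scheme:      ", x$factor_scheme, "\n")
  cat("  participants:", x$n_participants, "\n")
  cat("  factor corr: ", x$factor_correlation, "  same-day resid corr:",
      x$sameday_residual_corr, "\n")
  cat("  age corr:    ",
      paste(names(x$age_correlations), round(x$age_correlations, 2),
            sep = "=", collapse = ", "), "\n")
  cat("  planted thickness effects:",
      sum(x$thickness_effects != 0), "non-zero regions\n")
  invisible(x)
}

# log-normal parameters (mu, sigma on log scale) matching a raw-scale
# mean/SD pair
lognormal_params <- function(mean, sd) {
  sigma2 <- log(1 + sd^2 / mean^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}
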