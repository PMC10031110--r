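# Shared fixtures: configurations without the missingness/outlier layers, so
# structural checks are not confounded with the injection machinery.

clean_config <- function(n, ...) {
  cohort_config(n_participants = n,
                missing_rates = list(selfreport = 0, saliva = 0,
                                     hair = 0, thickness = 0),
                outlier_rate = 0, ...)
}

# a configuration with every structural path switched off
null_config <- function(n = 10) {
  ld <- default_true_loadings() * 0
  so <- default_second_order_loadings() * 0
  clean_config(n, true_loadings = ld, second_order_loadings = so,
               factor_correlation = 0, age_correlations = c(ADR = 0, GON = 0),
               sameday_residual_corr = 0,
               thickness_effects = setNames(rep(0, 68), dk_regions()))
}

quiet_ml_fit <- function(...) suppressWarnings(ml_fit(...))
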