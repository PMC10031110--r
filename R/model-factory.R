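# Construction of the analysed model variants: one- vs two-factor schemes,
# self-report / hormone / multi-method indicator sets, residual-covariance
# options, the hair-DHEA zero constraint, age handling, and Tanner-stage
# stratified refits.

sameday_covariance_lines <- function() {
  unlist(lapply(1:4, function(k) {
    trio <- paste0(c("saliva_dhea_", "saliva_t_", "saliva_e2_"), k)
    c(paste(trio[1], "~~", trio[2]),
      paste(trio[1], "~~", trio[3]),
      paste(trio[2], "~~", trio[3]))
  }))
}

selfreport_lines <- function(scheme) {
  if (scheme == "two_factor")
    c("sr_adr =~ pds2 + pds3 + ld2",
      "sr_gon =~ pds1 + pds4 + pds6 + ld1")
  else
    "sr_pub =~ pds1 + pds2 + pds3 + pds4 + pds6 + ld1 + ld2"
}

saliva_factor_lines <- function() {
  c("sal_dhea =~ saliva_dhea_1 + saliva_dhea_2 + saliva_dhea_3 + saliva_dhea_4",
    "sal_t =~ saliva_t_1 + saliva_t_2 + saliva_t_3 + saliva_t_4",
    "sal_e2 =~ saliva_e2_1 + saliva_e2_2 + saliva_e2_3 + saliva_e2_4")
}

#' Describe a model variant
#'
#' Bundles the analysis choices that distinguish the fitted models: the
#' factor scheme (separate adrenarche/gonadarche factors or one overall
#' puberty factor), the indicator set, residual-covariance options, the
#' hair-DHEA zero constraint, how age enters, and an optional
#' Tanner-stage stratum.
#'
#' @param factor_scheme `"two_factor"` or `"one_factor"`.
#' @param indicator_set one of `"selfreport_only"`, `"hormones_saliva_hair"`,
#'   `"hormones_saliva_only"`, `"full_multimethod"` (self-report plus saliva;
#'   hair is excluded from the full models).
#' @param sameday_saliva add residual covariances among the three hormones'
#'   same-day saliva samples (12 covariances). Defaults to `TRUE` whenever
#'   saliva indicators are present.
#' @param correlated_uniqueness_questionnaire add residual covariances among
#'   items of the same questionnaire (PDS pairs and the LD pair).
#' @param hair_dhea_constrained_zero fix the hair-DHEA loading to 0
#'   (hair indicator sets only).
#' @param age_mode `"none"`, `"correlate"` (age covaries with the top-level
#'   factors) or `"regress"` (top-level factors regressed on age, so factor
#'   covariances are age-partialled).
#' @param stratum `"all"`, `"pds_stage_ge3"` or `"pds_stage_lt3"`.
#' @return a list of class `pubsem_variant`.
#' @export
model_variant <- function(factor_scheme = c("two_factor", "one_factor"),
                          indicator_set = c("full_multimethod",
                                            "selfreport_only",
                                            "hormones_saliva_hair",
                                            "hormones_saliva_only"),
                          sameday_saliva = NULL,
                          correlated_uniqueness_questionnaire = FALSE,
                          hair_dhea_constrained_zero = FALSE,
                          age_mode = c("none", "correlate", "regress"),
                          stratum = c("all", "pds_stage_ge3", "pds_stage_lt3")) {
  factor_scheme <- match.arg(factor_scheme)
  indicator_set <- match.arg(indicator_set)
  age_mode <- match.arg(age_mode)
  stratum <- match.arg(stratum)
  has_saliva <- indicator_set != "selfreport_only"
  if (is.null(sameday_saliva)) sameday_saliva <- has_saliva
  if (sameday_saliva && !has_saliva)
    stop("same-day saliva covariances require saliva indicators")
  if (hair_dhea_constrained_zero && indicator_set != "hormones_saliva_hair")
    stop("the hair-DHEA constraint applies to the saliva+hair indicator set")
  structure(list(factor_scheme = factor_scheme, indicator_set = indicator_set,
                 sameday_saliva = sameday_saliva,
                 correlated_uniqueness_questionnaire =
                   correlated_uniqueness_questionnaire,
                 hair_dhea_constrained_zero = hair_dhea_constrained_zero,
                 age_mode = age_mode, stratum = stratum),
            class = "pubsem_variant")
}

#' Build the model specification for a variant
#'
#' Topology: one first-order factor per saliva hormone (four sample
#' indicators each) and self-report factor(s) over the ordinal items; in the
#' two-factor scheme the second-order adrenarche factor collects the saliva
#' DHEA and T factors and the self-report ADR factor, and the gonadarche
#' factor collects the saliva E2 factor and the self-report GON factor; the
#' one-factor scheme collapses the second order to a single puberty factor.
#' Hair concentrations (hormone-only sets) load directly on the top-level
#' factor(s). Identification is checked at the start values; an unidentified
#' variant (e.g. a two-factor saliva-only model, whose gonadal factor has a
#' single first-order indicator) raises a diagnostic.
#'
#' @param variant a [model_variant()] (or arguments forwarded to it).
#' @param check_id verify local identification (default `TRUE`).
#' @return a `pubsem_model` with attribute `"variant"`.
#' @export
#' @examples
#' m <- build_model(model_variant("two_factor", "full_multimethod"))
#' length(m$obs)      # 19 observed indicators
#' length(m$latents)  # 7 latent variables
build_model <- function(variant = model_variant(), check_id = TRUE) {
  v <- variant
  scheme <- v$factor_scheme
  lines <- character(0)
  top <- if (scheme == "two_factor") c("ADR", "GON") else "PUB"

  sr_first <- if (scheme == "two_factor") c("sr_adr", "sr_gon") else "sr_pub"
  if (v$indicator_set %in% c("selfreport_only", "full_multimethod"))
    lines <- c(lines, selfreport_lines(scheme))
  if (v$indicator_set != "selfreport_only")
    lines <- c(lines, saliva_factor_lines())

  if (v$indicator_set == "selfreport_only") {
    if (scheme == "two_factor") lines <- c(lines, "sr_adr ~~ sr_gon")
    top <- sr_first   # the self-report factors are the top level here
  } else if (v$indicator_set == "full_multimethod") {
    if (scheme == "two_factor") {
      lines <- c(lines, "ADR =~ sal_dhea + sal_t + sr_adr",
                 "GON =~ sal_e2 + sr_gon", "ADR ~~ GON")
    } else {
      lines <- c(lines, "PUB =~ sal_dhea + sal_t + sal_e2 + sr_pub")
    }
  } else {  # hormone-only sets
    hair <- v$indicator_set == "hormones_saliva_hair"
    dhea_term <- if (hair && v$hair_dhea_constrained_zero) " + 0*hair_dhea"
    else if (hair) " + hair_dhea" else ""
    if (scheme == "two_factor") {
      lines <- c(lines,
                 paste0("ADR =~ sal_dhea + sal_t", dhea_term,
                        if (hair) " + hair_t" else ""),
                 paste0("GON =~ sal_e2", if (hair) " + hair_e2" else ""),
                 "ADR ~~ GON")
    } else {
      lines <- c(lines,
                 paste0("PUB =~ sal_dhea + sal_t + sal_e2", dhea_term,
                        if (hair) " + hair_t + hair_e2" else ""))
    }
  }

  if (v$sameday_saliva) lines <- c(lines, sameday_covariance_lines())
  if (v$correlated_uniqueness_questionnaire &&
      v$indicator_set %in% c("selfreport_only", "full_multimethod")) {
    # questionnaire (method) covariances among items of different pubertal
    # processes; within-process pairs are confounded with the trait factor
    # and would destroy identification
    adr_items <- c("pds2", "pds3"); gon_items <- c("pds1", "pds4", "pds6")
    cu <- as.vector(outer(adr_items, gon_items, paste, sep = " ~~ "))
    lines <- c(lines, cu, "ld2 ~~ ld1")
  }

  if (v$age_mode == "correlate") {
    lines <- c(lines, "age ~~ age", paste("age ~~", top))
  } else if (v$age_mode == "regress") {
    lines <- c(lines, "age ~~ age", paste(top, "~ age"))
  }

  model <- parse_model(lines)
  if (check_id) {
    id <- check_identification(model)
    if (!isTRUE(id))
      stop("variant is not identified (Jacobian rank ", attr(id, "rank"),
           " < ", model$nfree, " free parameters); a factor with a single ",
           "indicator and free loading-plus-covariance is the usual cause ",
           "(the saliva-only gonadal factor makes the one- and two-factor ",
           "schemes equivalent)")
  }
  attr(model, "variant") <- v
  model
}

#' Shared variance between two constructs
#'
#' The percentage of variance two constructs share given their correlation,
#' or the correlation implied by a standardized path chain (the product of
#' its coefficients): `100 * r^2`, rounded to the nearest integer percent.
#'
#' @param r correlation in `[-1, 1]`, or a vector of standardized path
#'   coefficients whose product is the implied correlation.
#' @return integer percent.
#' @export
#' @examples
#' shared_variance(0.695)  # 48
#' shared_variance(0.977)  # 95
shared_variance <- function(r) {
  r <- prod(r)
  if (abs(r) > 1) stop("|correlation| > 1")
  round(100 * r^2)
}

# estimator ladder: PML for ordinal-only, ML for continuous-only, FIML for
# the combined models
default_estimator <- function(variant) {
  switch(variant$indicator_set,
         selfreport_only = "pml",
         hormones_saliva_hair = "ml",
         hormones_saliva_only = "ml",
         full_multimethod = "fiml")
}

fit_with <- function(model, data, estimator, ...) {
  switch(estimator,
         ml = ml_fit(model, data = data, ...),
         mlr = ml_fit(model, data = data, ...),
         fiml = fiml_fit(model, data = data, ...),
         pml = pml_fit_ordinal(model, data, ...),
         stop("unknown estimator: ", estimator))
}

#' Fit a series of model variants
#'
#' Builds and fits each requested variant on a preprocessed cohort, using
#' the estimator ladder the analysis prescribes (pairwise likelihood for
#' ordinal-only self-report models, maximum likelihood for continuous-only
#' hormone models, full-information maximum likelihood for the combined
#' models) unless overridden, and tabulates the comparison.
#'
#' @param cohort preprocessed cohort data frame (log-scale hormones).
#' @param variants named list of [model_variant()] objects.
#' @param estimator optional single estimator name applied to all variants
#'   (`"ml"`, `"fiml"`, `"pml"`).
#' @return list with `fits` (named `pubsem_fit` list; failed fits carry the
#'   condition message), `comparison` (over the fits with a defined
#'   chi-square and common n), and `loadings` (standardized loading tables).
#' @export
run_model_series <- function(cohort, variants, estimator = NULL) {
  if (inherits(variants, "pubsem_variant")) variants <- list(variants)
  if (is.null(names(variants)))
    names(variants) <- paste0("variant", seq_along(variants))
  fits <- list()
  for (nm in names(variants)) {
    v <- variants[[nm]]
    est <- if (is.null(estimator)) default_estimator(v) else estimator
    dat <- cohort
    if (v$stratum != "all") {
      if (!"pds_stage" %in% names(dat))
        stop("stratified variant needs a pds_stage column (run score_composites)")
      keep <- if (v$stratum == "pds_stage_ge3") dat$pds_stage >= 3
      else dat$pds_stage < 3
      dat <- dat[keep %in% TRUE, , drop = FALSE]
    }
    fits[[nm]] <- tryCatch({
      model <- build_model(v)
      fit_with(model, dat, est)
    }, error = function(e) structure(list(error = conditionMessage(e)),
                                     class = "pubsem_fit_error"))
  }
  ok <- !vapply(fits, inherits, logical(1), "pubsem_fit_error")
  with_chisq <- ok & vapply(fits, function(f)
    isTRUE(is.finite(f$chisq)), logical(1))
  comparison <- NULL
  if (sum(with_chisq) >= 2) {
    sub <- fits[with_chisq]
    ns <- vapply(sub, `[[`, numeric(1), "n")
    sub <- sub[ns == ns[1]]
    if (length(sub) >= 2)
      comparison <- compare_models(sub, names = names(sub))
  }
  loadings <- lapply(fits[ok], function(f) {
    s <- standardize(f)
    s[s$mat == "A", c("lhs", "rhs", "est", "std")]
  })
  list(fits = fits, comparison = comparison, loadings = loadings)
}

#' Fit one model separately within strata
#'
#' @param cohort preprocessed cohort.
#' @param model a `pubsem_model`.
#' @param stratifier factor/vector aligned with the cohort rows, or the name
#'   of a cohort column.
#' @param estimator `"ml"`, `"fiml"` or `"pml"`.
#' @return list with per-stratum fits and a side-by-side standardized
#'   loading table.
#' @export
stratified_fit <- function(cohort, model, stratifier, estimator = "ml") {
  s <- if (is.character(stratifier) && length(stratifier) == 1)
    cohort[[stratifier]] else stratifier
  s <- factor(s)
  if (any(is.na(s))) {
    cohort <- cohort[!is.na(s), , drop = FALSE]
    s <- s[!is.na(s)]
  }
  counts <- table(s)
  if (any(counts == 0) || length(counts) < 1) stop("empty stratum")
  fits <- lapply(levels(s), function(lv) {
    dat <- cohort[s == lv, , drop = FALSE]
    if (nrow(dat) <= model$nfree)
      stop("stratum '", lv, "' has fewer cases (", nrow(dat),
           ") than free parameters (", model$nfree, ")")
    fit_with(model, dat, estimator)
  })
  names(fits) <- levels(s)
  tabs <- lapply(names(fits), function(nm) {
    st <- standardize(fits[[nm]])
    st <- st[st$mat == "A", c("lhs", "rhs", "std")]
    names(st)[3] <- paste0("std_", nm)
    st
  })
  side <- Reduce(function(a, b) merge(a, b, by = c("lhs", "rhs"), sort = FALSE),
                 tabs)
  list(fits = fits, loadings = side)
}
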