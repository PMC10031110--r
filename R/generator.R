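# Latent structure assembly and cohort simulation.
#
# All variables are assembled on a standardized latent scale first (unit
# variances), as a correlation matrix R = Lambda Psi Lambda' + Theta, and
# only then rescaled to the declared marginals: hormones get log-normal
# marginals (the latent column is the log concentration), ordinal items are
# cut at their thresholds, age and thickness are shifted/scaled normals.

cohort_indicator_names <- function() {
  c("pds1", "pds2", "pds3", "pds4", "pds6", "ld1", "ld2",
    paste0("saliva_dhea_", 1:4), paste0("saliva_t_", 1:4),
    paste0("saliva_e2_", 1:4), "hair_dhea", "hair_t", "hair_e2")
}

item_names <- function() c("pds1", "pds2", "pds3", "pds4", "pds6", "ld1", "ld2")

# map indicator -> factor it loads on, per scheme
indicator_factor_map <- function(scheme) {
  m <- c(saliva_dhea_1 = "sal_dhea", saliva_dhea_2 = "sal_dhea",
         saliva_dhea_3 = "sal_dhea", saliva_dhea_4 = "sal_dhea",
         saliva_t_1 = "sal_t", saliva_t_2 = "sal_t",
         saliva_t_3 = "sal_t", saliva_t_4 = "sal_t",
         saliva_e2_1 = "sal_e2", saliva_e2_2 = "sal_e2",
         saliva_e2_3 = "sal_e2", saliva_e2_4 = "sal_e2")
  if (scheme == "two_factor") {
    c(m, pds2 = "sr_adr", pds3 = "sr_adr", ld2 = "sr_adr",
      pds1 = "sr_gon", pds4 = "sr_gon", pds6 = "sr_gon", ld1 = "sr_gon",
      hair_dhea = "ADR", hair_t = "ADR", hair_e2 = "GON")
  } else {
    c(m, pds1 = "sr_pub", pds2 = "sr_pub", pds3 = "sr_pub",
      pds4 = "sr_pub", pds6 = "sr_pub", ld1 = "sr_pub", ld2 = "sr_pub",
      hair_dhea = "PUB", hair_t = "PUB", hair_e2 = "PUB")
  }
}

# factor-frame covariance (second-order factors + age + first-order factors),
# loading matrix over all observed variables, and residual structure
implied_structure <- function(cfg) {
  scheme <- cfg$factor_scheme
  top <- if (scheme == "two_factor") c("ADR", "GON", "age_f") else c("PUB", "age_f")
  first <- names(cfg$second_order_loadings)

  psi_top <- diag(length(top))
  dimnames(psi_top) <- list(top, top)
  if (scheme == "two_factor") {
    psi_top["ADR", "GON"] <- psi_top["GON", "ADR"] <- cfg$factor_correlation
    psi_top["ADR", "age_f"] <- psi_top["age_f", "ADR"] <- cfg$age_correlations[["ADR"]]
    psi_top["GON", "age_f"] <- psi_top["age_f", "GON"] <- cfg$age_correlations[["GON"]]
  } else {
    psi_top["PUB", "age_f"] <- psi_top["age_f", "PUB"] <- cfg$age_correlations[["PUB"]]
  }

  # first-order factors: f = L2 %*% top + disturbance, unit total variance
  target_of <- if (scheme == "two_factor")
    c(sal_dhea = "ADR", sal_t = "ADR", sr_adr = "ADR",
      sal_e2 = "GON", sr_gon = "GON")
  else
    c(sal_dhea = "PUB", sal_t = "PUB", sal_e2 = "PUB", sr_pub = "PUB")
  L2 <- matrix(0, length(first), length(top), dimnames = list(first, top))
  for (f in first) L2[f, target_of[[f]]] <- cfg$second_order_loadings[[f]]

  frame <- c(top, first)
  psi <- matrix(0, length(frame), length(frame), dimnames = list(frame, frame))
  psi[top, top] <- psi_top
  psi[first, top] <- L2 %*% psi_top
  psi[top, first] <- t(psi[first, top])
  ff <- L2 %*% psi_top %*% t(L2)
  dist_var <- 1 - diag(ff)
  if (any(dist_var < -1e-10))
    stop("second-order loadings imply first-order factor variance > 1")
  psi[first, first] <- ff + diag(pmax(dist_var, 0), length(first))

  obs <- c("age", cohort_indicator_names(), names(cfg$thickness_effects))
  lambda <- matrix(0, length(obs), length(frame), dimnames = list(obs, frame))
  lambda["age", "age_f"] <- 1
  fmap <- indicator_factor_map(scheme)
  for (v in cohort_indicator_names())
    lambda[v, fmap[[v]]] <- cfg$true_loadings[[v]]
  regions <- names(cfg$thickness_effects)
  if (cfg$thickness_age_mediated) {
    lambda[regions, "age_f"] <- cfg$thickness_effects
  } else if (scheme == "two_factor") {
    w <- 1 / sqrt(2 + 2 * cfg$factor_correlation)
    lambda[regions, "ADR"] <- cfg$thickness_effects * w
    lambda[regions, "GON"] <- cfg$thickness_effects * w
  } else {
    lambda[regions, "PUB"] <- cfg$thickness_effects
  }

  common <- lambda %*% psi %*% t(lambda)
  theta_diag <- 1 - diag(common)
  theta_diag["age"] <- 0
  if (any(theta_diag < -1e-10)) {
    bad <- names(which.min(theta_diag))
    stop("configuration implies communality > 1 for ", bad)
  }
  theta <- diag(pmax(theta_diag, 0), length(obs))
  dimnames(theta) <- list(obs, obs)
  rho_d <- cfg$sameday_residual_corr
  if (rho_d != 0) {
    for (k in 1:4) {
      trio <- paste0(c("saliva_dhea_", "saliva_t_", "saliva_e2_"), k)
      for (i in 1:2) for (j in (i + 1):3) {
        a <- trio[i]; b <- trio[j]
        theta[a, b] <- theta[b, a] <-
          rho_d * sqrt(theta_diag[a] * theta_diag[b])
      }
    }
  }

  R <- common + theta
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf(
      "configuration implies a non-positive-semi-definite covariance (eigenvalue %.3g)",
      min(ev)))

  # marginal scale and location per observed variable (latent/log scale)
  scale <- setNames(rep(1, length(obs)), obs)
  loc <- setNames(rep(0, length(obs)), obs)
  scale["age"] <- cfg$age_sd; loc["age"] <- cfg$age_mean
  hm <- cfg$hormone_marginals
  for (i in seq_len(nrow(hm))) {
    lp <- lognormal_params(hm$mean[i], hm$sd[i])
    cols <- if (grepl("^saliva_", hm$hormone[i]))
      paste0(hm$hormone[i], "_", 1:4) else hm$hormone[i]
    scale[cols] <- lp$sigma; loc[cols] <- lp$mu
  }
  tm <- cfg$thickness_marginals
  scale[tm$region] <- tm$sd; loc[tm$region] <- tm$mean

  list(obs = obs, R = R, scale = scale, loc = loc, regions = regions)
}

#' Population covariance implied by a generator configuration
#'
#' Assembles, by covariance (path-tracing) algebra, the population covariance
#' matrix over every observed continuous or latent-response variable: age,
#' the seven ordinal items' standard-normal latent responses, the twelve
#' saliva and three hair log-concentrations, and the 68 regional thickness
#' values. The diagonal equals the declared marginal variances (1 for latent
#' item responses, the log-scale variance for hormones, the configured
#' variances for age and thickness).
#'
#' @param config a [cohort_config()] object.
#' @return symmetric positive semi-definite covariance matrix with one
#'   row/column per observed variable.
#' @export
#' @examples
#' cfg <- cohort_config()
#' S <- implied_population_covariance(cfg)
#' S["saliva_dhea_1", "saliva_dhea_2"] # within-hormone covariance, log scale
implied_population_covariance <- function(config) {
  validate_config(config)
  str <- implied_structure(config)
  D <- diag(str$scale, length(str$obs))
  S <- D %*% str$R %*% D
  dimnames(S) <- list(str$obs, str$obs)
  S
}

# named substream seeds derived once from the master seed; adding names at
# the END of this vector leaves earlier streams unchanged
substream_seeds <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("latent", "outlier", "missing", "reserved")
  s
}

#' Generate a synthetic multi-method pubertal cohort
#'
#' Draws participants from the population defined by a [cohort_config()]:
#' a multivariate-normal draw from the implied correlation structure,
#' hormone columns exponentiated so raw concentrations are log-normal
#' (positively skewed, as observed assay data are), ordinal items produced
#' by thresholding their latent responses, heavy upper-tail outliers and
#' missing-completely-at-random cells injected per configuration. The draw
#' is deterministic given `seed`, with independent substreams for the latent
#' draw, outlier injection and missingness, so switching one block on or off
#' does not perturb the others.
#'
#' @param config a [cohort_config()].
#' @param seed integer; defaults to `config$seed`.
#' @param raw_scale if `FALSE`, return the untransformed continuous draw
#'   (log-scale hormones, latent item responses; no outliers, no
#'   missingness) for distributional diagnostics.
#' @return list with elements `cohort` (participant-level indicators) and
#'   `thickness` (participant x 68-region table, mm).
#' @export
#' @examples
#' dat <- generate_cohort(cohort_config(n_participants = 50), seed = 7)
#' dim(dat$cohort); dim(dat$thickness)
generate_cohort <- function(config, seed = config$seed, raw_scale = TRUE) {
  validate_config(config)
  str <- implied_structure(config)
  n <- config$n_participants
  V <- length(str$obs)
  streams <- substream_seeds(seed)

  ee <- eigen(str$R, symmetric = TRUE)
  A <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), V)
  set.seed(streams[["latent"]])
  Z <- matrix(rnorm(n * V), n, V) %*% t(A)
  colnames(Z) <- str$obs

  id <- sprintf("sub%05d", seq_len(n))
  if (!raw_scale) {
    X <- sweep(sweep(Z, 2, str$scale, "*"), 2, str$loc, "+")
    return(list(cohort = data.frame(participant_id = id,
                                    X[, c("age", cohort_indicator_names()),
                                      drop = FALSE], check.names = FALSE),
                thickness = data.frame(participant_id = id,
                                       X[, str$regions, drop = FALSE],
                                       check.names = FALSE)))
  }

  # outliers on the standardized log scale, upper tail only (hormone assays)
  hcols <- grep("^(saliva_(dhea|t|e2)_\\d|hair_)", str$obs, value = TRUE)
  set.seed(streams[["outlier"]])
  if (config$outlier_rate > 0) {
    mask <- matrix(runif(n * length(hcols)) < config$outlier_rate,
                   n, length(hcols))
    bump <- matrix(abs(rnorm(n * length(hcols))) * 0.5, n, length(hcols))
    Zh <- Z[, hcols, drop = FALSE]
    Zh[mask] <- config$outlier_magnitude + bump[mask]
    Z[, hcols] <- Zh
  }

  cohort <- data.frame(participant_id = id,
                       age = config$age_mean + config$age_sd * Z[, "age"])
  for (it in item_names()) {
    tau <- config$item_thresholds[[it]]
    val <- findInterval(Z[, it], tau) + 1L
    if (it == "pds6") val <- val - 1L   # binary menarche coded 0/1
    cohort[[it]] <- val
  }
  for (h in hcols)
    cohort[[h]] <- exp(str$loc[[h]] + str$scale[[h]] * Z[, h])
  for (k in 1:4) cohort[[paste0("saliva_day_", k)]] <- k

  thick <- data.frame(participant_id = id, check.names = FALSE)
  for (r in str$regions)
    thick[[r]] <- str$loc[[r]] + str$scale[[r]] * Z[, r]

  rates <- config$missing_rates
  cohort <- inject_missingness(cohort,
                               rates[setdiff(names(rates), "thickness")],
                               seed = streams[["missing"]])
  if (!is.null(rates$thickness) && rates$thickness > 0)
    thick <- inject_missingness(thick, list(thickness = rates$thickness),
                                seed = streams[["missing"]] + 1L)
  list(cohort = cohort, thickness = thick)
}

column_block <- function(col) {
  if (grepl("^(pds|ld)\\d$", col)) return("selfreport")
  if (grepl("^saliva_(dhea|t|e2)_\\d$", col)) return("saliva")
  if (grepl("^hair_", col)) return("hair")
  if (col %in% dk_regions()) return("thickness")
  NA_character_
}

#' Inject missing-completely-at-random cells
#'
#' Sets cells to `NA` independently with the block-specific rate. Blocks are
#' `selfreport` (PDS and line-drawing items), `saliva`, `hair` and
#' `thickness`; identifier, age and collection-day columns are never
#' blanked. Deterministic given `seed`.
#'
#' @param table data frame (cohort or thickness table).
#' @param rates named list/vector of rates in \[0, 1\] per block.
#' @param seed integer seed.
#' @return the table with `NA`s injected.
#' @export
inject_missingness <- function(table, rates, seed = 1L) {
  rates <- rates[vapply(rates, function(r) !is.null(r) && r > 0, logical(1))]
  if (any(unlist(rates) < 0 | unlist(rates) > 1))
    stop("missing rates must lie in [0, 1]")
  if (!length(rates)) return(table)
  set.seed(as.integer(seed))
  n <- nrow(table)
  blocks <- vapply(names(table), column_block, character(1))
  for (b in c("selfreport", "saliva", "hair", "thickness")) { # fixed order
    if (is.null(rates[[b]])) next
    for (col in names(table)[!is.na(blocks) & blocks == b])
      table[[col]][runif(n) < rates[[b]]] <- NA
  }
  table
}

#' Simulate a cohort and write it to disk
#'
#' Convenience wrapper: generates the cohort and thickness tables and writes
#' them as comma-separated text (missing values as empty fields), plus the
#' thickness table in the FreeSurfer aparc-stats-like dialect.
#'
#' @param config a [cohort_config()], or a path to a YAML file accepted by
#'   [read_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, the list returned by [generate_cohort()].
#' @export
simulate_cohort <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(seed)) seed <- config$seed
  dat <- generate_cohort(config, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(dat$cohort, file.path(out_dir, "cohort.csv"))
  write_thickness(dat$thickness, file.path(out_dir, "thickness.csv"))
  write_thickness(dat$thickness, file.path(out_dir, "thickness_aparc.tsv"),
                  dialect = "aparc")
  invisible(dat)
}
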