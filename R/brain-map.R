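# Region-wise SEM associations between latent pubertal factors and cortical
# thickness across the 68 Desikan-Killiany regions.

top_factors <- function(variant) {
  if (variant$indicator_set == "selfreport_only") {
    if (variant$factor_scheme == "two_factor") c("sr_adr", "sr_gon") else "sr_pub"
  } else if (variant$factor_scheme == "two_factor") c("ADR", "GON") else "PUB"
}

factor_display <- c(ADR = "ADR", GON = "GON", PUB = "PUB",
                    sr_adr = "ADR", sr_gon = "GON", sr_pub = "PUB")

#' Fit one region's thickness-factor model
#'
#' Adds a region's cortical thickness to a measurement-model variant as an
#' observed variable covarying with the top-level latent factor(s) (and with
#' age, when age is in the model) and extracts the standardized latent
#' factor-thickness correlation(s). Under `age_mode = "regress"` both the
#' factors and thickness are regressed on age, so the reported association
#' is the age-partialled (pubertal-timing) correlation; under
#' `"correlate"` age is a correlate and the association keeps its marginal
#' (pubertal-stage) interpretation.
#'
#' @param cohort preprocessed cohort (log-scale hormones), one row per
#'   participant.
#' @param thickness thickness table with a `participant_id` column.
#' @param region region column name (one of [dk_regions()]).
#' @param variant a [model_variant()]; its `age_mode` controls the age
#'   adjustment.
#' @param estimator `"ml"` (default) or `"fiml"`.
#' @return data frame with one row per top-level factor: `region`, `hemi`,
#'   `factor`, `method_set`, `age_mode`, `r`, `se`, `converged`.
#' @export
fit_region <- function(cohort, thickness, region, variant = model_variant(),
                       estimator = "ml") {
  if (!region %in% names(thickness))
    stop("region column not found: ", region)
  dat <- merge(cohort, thickness[, c("participant_id", region)],
               by = "participant_id")
  dat$cth <- dat[[region]]
  facs <- top_factors(variant)

  base <- build_model(variant, check_id = FALSE)
  lines <- c(base$syntax, "cth ~~ cth")
  if (variant$age_mode == "regress") {
    lines <- c(lines, "cth ~ age",
               paste0(facs, " ~~ cth"))
  } else {
    lines <- c(lines, paste0(facs, " ~~ cth"))
    if (variant$age_mode == "correlate") lines <- c(lines, "age ~~ cth")
  }
  model <- parse_model(lines)

  hemi <- sub("_.*$", "", region)
  out <- data.frame(region = region, hemi = hemi,
                    factor = unname(factor_display[facs]),
                    method_set = variant$indicator_set,
                    age_mode = variant$age_mode,
                    r = NA_real_, se = NA_real_, converged = FALSE,
                    stringsAsFactors = FALSE)
  fit <- tryCatch(
    suppressWarnings(fit_with(model, dat, estimator, check_id = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  V <- implied_cov_all(model, fit$theta)$V
  if (variant$age_mode == "regress") {
    # age-partialled (timing) association: condition the implied covariance
    # of thickness and the factors on age
    keep <- c("cth", facs)
    V[keep, keep] <- V[keep, keep] -
      V[keep, "age"] %*% t(V[keep, "age"]) / V["age", "age"]
  }
  for (i in seq_along(facs)) {
    f <- facs[i]
    out$r[i] <- V["cth", f] / sqrt(V["cth", "cth"] * V[f, f])
    lab <- paste0(f, "~~cth")
    k <- match(lab, model$labels)
    if (!is.na(k) && !is.null(fit$se))
      out$se[i] <- fit$se[k] / sqrt(V["cth", "cth"] * V[f, f])
  }
  out$converged <- fit$converged
  out
}

#' Sweep thickness-factor associations across the cortex
#'
#' Fits the region model of [fit_region()] for every requested region and
#' every combination of variant and age option, producing the long-format
#' brain map table with effect-size bands attached.
#'
#' @param cohort,thickness as in [fit_region()].
#' @param variants named list of [model_variant()]s (one map per variant per
#'   age option).
#' @param age_modes character vector among `"none"`, `"correlate"`,
#'   `"regress"`.
#' @param regions region columns to sweep (defaults to all 68).
#' @param estimator `"ml"` or `"fiml"`.
#' @return data frame of class `pubsem_brainmap`; missing requested region
#'   columns raise an error naming them.
#' @export
brain_sweep <- function(cohort, thickness, variants = list(
  multimethod = model_variant("one_factor", "full_multimethod")),
  age_modes = "none", regions = NULL, estimator = "ml") {
  if (is.null(regions)) regions <- intersect(dk_regions(), names(thickness))
  missing_regions <- setdiff(regions, names(thickness))
  if (length(missing_regions))
    stop("missing region columns: ", paste(missing_regions, collapse = ", "))
  if (inherits(variants, "pubsem_variant")) variants <- list(variants)
  if (is.null(names(variants)))
    names(variants) <- paste0("variant", seq_along(variants))
  rows <- list()
  for (nm in names(variants)) for (am in age_modes) {
    v <- variants[[nm]]
    v$age_mode <- am
    for (rg in regions)
      rows[[length(rows) + 1L]] <- fit_region(cohort, thickness, rg, v,
                                              estimator = estimator)
  }
  map <- do.call(rbind, rows)
  map <- classify_effects(map)
  class(map) <- c("pubsem_brainmap", "data.frame")
  map
}

#' Label effect-size bands
#'
#' Classifies each association by its magnitude into documented bands; a
#' value exactly at a boundary is assigned to the upper band.
#'
#' @param map a brain-map data frame with an `r` column.
#' @param bands named increasing vector of band upper bounds; the defaults
#'   label `|r| < 0.1` weak, `0.1 <= |r| < 0.3` small, `0.3 <= |r| < 0.5`
#'   medium, and anything larger `large`.
#' @return the map with a `band` column.
#' @export
#' @examples
#' classify_effects(data.frame(r = c(0, 0.15, 0.43)))$band
classify_effects <- function(map, bands = c(weak = 0.1, small = 0.3,
                                            medium = 0.5)) {
  if (any(diff(bands) <= 0)) stop("bands must be strictly increasing")
  cuts <- c(0, unname(bands), Inf)
  labels <- c(names(bands), "large")
  idx <- findInterval(abs(map$r), cuts, left.open = FALSE,
                      rightmost.closed = FALSE)
  map$band <- ifelse(is.na(map$r), NA_character_, labels[pmin(idx, length(labels))])
  map
}

#' @export
print.pubsem_brainmap <- function(x, ...) {
  needed <- c("region", "factor", "method_set", "age_mode", "r")
  if (!all(needed %in% names(x))) {
    print.data.frame(x, ...)
    return(invisible(x))
  }
  cat(sprintf("Brain map: %d associations over %d regions\n",
              nrow(x), length(unique(x$region))))
  print(summary_brainmap(x), row.names = FALSE)
  invisible(x)
}

#' Summarize a brain map
#'
#' Strongest positive and negative association per (factor, method set,
#' age option) map.
#'
#' @param map a `pubsem_brainmap`.
#' @return data frame, one row per map.
#' @export
summary_brainmap <- function(map) {
  key <- interaction(map$factor, map$method_set, map$age_mode, drop = TRUE)
  do.call(rbind, lapply(split(seq_len(nrow(map)), key), function(ix) {
    m <- map[ix, ]
    m <- m[!is.na(m$r), , drop = FALSE]
    if (!nrow(m)) return(NULL)
    data.frame(factor = m$factor[1], method_set = m$method_set[1],
               age_mode = m$age_mode[1],
               strongest_neg_region = m$region[which.min(m$r)],
               strongest_neg_r = min(m$r),
               strongest_pos_region = m$region[which.max(m$r)],
               strongest_pos_r = max(m$r), stringsAsFactors = FALSE)
  }))
}

#' Write a brain map as long-format TSV
#'
#' @param map a `pubsem_brainmap`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_brainmap <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
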