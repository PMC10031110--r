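# Reading/writing cohort and thickness tables, run configuration, and the
# end-to-end pipeline.

cohort_mandatory_columns <- function()
  c("participant_id", "age", item_names(),
    paste0("saliva_dhea_", 1:4), paste0("saliva_t_", 1:4),
    paste0("saliva_e2_", 1:4), "hair_dhea", "hair_t", "hair_e2")

#' Read a cohort table
#'
#' Comma-separated with a header row; empty fields are missing values.
#' Mandatory columns are validated by name, hormone columns must be numeric
#' and strictly positive where present; unknown columns are preserved.
#'
#' @param path CSV file path.
#' @return cohort data frame.
#' @export
read_cohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_mandatory_columns(), names(tab))
  if (length(missing))
    stop("cohort file lacks mandatory columns: ",
         paste(missing, collapse = ", "))
  for (col in hormone_columns(tab)) {
    if (!is.numeric(tab[[col]]))
      stop("non-numeric value in hormone column '", col, "'")
    bad <- which(!is.na(tab[[col]]) & tab[[col]] <= 0)
    if (length(bad))
      stop("non-positive concentration in column '", col, "', row ", bad[1])
  }
  tab$participant_id <- as.character(tab$participant_id)
  tab
}

#' @rdname read_cohort
#' @param cohort cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

canonical_region_name <- function(x) sub("_thickness$", "", x)

#' Read a cortical thickness table
#'
#' Accepts either a single merged CSV (participant id plus the 68
#' `lh_`/`rh_`-prefixed region columns, with or without a `_thickness`
#' suffix) or one or two FreeSurfer aparc-stats-like tab-separated files
#' (first column the participant id, then `<hemi>_<region>_thickness`
#' headers), merged on participant id. Column names are canonicalized to
#' `lh_<region>` / `rh_<region>`.
#'
#' @param path one file path, or two (one per hemisphere).
#' @return thickness data frame with `participant_id` plus 68 region
#'   columns.
#' @export
read_thickness <- function(path) {
  read_one <- function(p) {
    first <- readLines(p, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
    tab <- read.csv(p, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
    names(tab)[1] <- "participant_id"
    names(tab)[-1] <- canonical_region_name(names(tab)[-1])
    if (anyDuplicated(tab$participant_id))
      stop("duplicate participant ids in ", p)
    tab$participant_id <- as.character(tab$participant_id)
    tab
  }
  tabs <- lapply(path, read_one)
  tab <- Reduce(function(a, b) merge(a, b, by = "participant_id"), tabs)
  regions <- setdiff(names(tab), "participant_id")
  for (h in c("lh", "rh")) {
    got <- grep(paste0("^", h, "_"), regions, value = TRUE)
    if (length(got) != 34) {
      expected <- paste0(h, "_", dk_regions(prefixed = FALSE))
      absent <- setdiff(expected, got)
      stop(length(got), " ", h, " region columns found (expected 34)",
           if (length(absent)) paste0("; missing: ",
                                      paste(head(absent, 5), collapse = ", ")))
    }
  }
  unknown <- setdiff(regions, dk_regions())
  if (length(unknown))
    stop("unknown region columns: ", paste(head(unknown, 5), collapse = ", "))
  bad <- vapply(dk_regions(), function(r)
    any(!is.na(tab[[r]]) & (tab[[r]] <= 0 | !is.finite(tab[[r]]))), logical(1))
  if (any(bad))
    stop("non-positive or non-finite thickness in ",
         names(bad)[bad][1])
  tab[, c("participant_id", dk_regions())]
}

#' @rdname read_thickness
#' @param thickness thickness data frame.
#' @param dialect `"csv"` (merged, canonical names) or `"aparc"`
#'   (tab-separated, `<hemi>_<region>_thickness` headers).
#' @export
write_thickness <- function(thickness, path, dialect = c("csv", "aparc")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    write.csv(thickness, path, row.names = FALSE, na = "")
  } else {
    out <- thickness
    names(out)[-1] <- paste0(names(out)[-1], "_thickness")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML file with an optional `generator` section (arguments to
#' [cohort_config()]), `preprocess` options, a `variants` list and `brain`
#' sweep options, plus a top-level `seed`.
#'
#' @param path YAML file.
#' @return list of class `pubsem_runconfig`; its `generator` element is a
#'   realized [cohort_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- raw
  gen_args <- raw$generator
  if (!is.null(gen_args)) {
    if (!is.null(raw$seed) && is.null(gen_args$seed))
      gen_args$seed <- raw$seed
    if (!is.null(gen_args$thickness_effects))
      gen_args$thickness_effects <- unlist(gen_args$thickness_effects)
    cfg$generator <- do.call(cohort_config, gen_args)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  class(cfg) <- "pubsem_runconfig"
  cfg
}

variant_from_name <- function(nm) {
  parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
  scheme <- parts[1]
  set <- if (length(parts) >= 2) parts[2] else "full_multimethod"
  age <- if (length(parts) >= 3) parts[3] else "none"
  model_variant(scheme, set, age_mode = age)
}

#' Run the full analysis pipeline
#'
#' Simulate (when the configuration has a `generator` section) or read the
#' cohort, preprocess (log transform, winsorization, composites), apply MRI
#' QC when a ledger is given, fit the requested model variants, compare
#' them, sweep the thickness associations, and write every table plus a run
#' manifest (seed, configuration digest, package version, stage counts)
#' into `out_dir`.
#'
#' @param config a `pubsem_runconfig` from [read_config()], or a path to a
#'   YAML file.
#' @param out_dir output directory.
#' @return invisibly, a list with the pipeline objects (`cohort`,
#'   `processed`, `series`, `map`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[pubsem] ", sprintf(...))
  counts <- list()

  if (!is.null(config$generator)) {
    log_stage("simulate: n=%d, seed=%d", config$generator$n_participants,
              config$seed)
    dat <- generate_cohort(config$generator, seed = config$seed)
    cohort <- dat$cohort
    thickness <- dat$thickness
  } else {
    cohort <- read_cohort(config$paths$cohort)
    thickness <- read_thickness(unlist(config$paths$thickness))
  }
  counts$participants <- nrow(cohort)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  write_thickness(thickness, file.path(out_dir, "thickness.csv"))

  pp <- config$preprocess
  processed <- preprocess_cohort(cohort,
                                 k_sd = pp$winsorize_sd %||% 3,
                                 increment = pp$winsorize_increment %||% 0.01)
  write_cohort(processed, file.path(out_dir, "cohort_processed.csv"))
  log_stage("preprocess: %d records cleaned", nrow(processed))

  if (!is.null(config$paths$qc)) {
    ledger <- read.csv(config$paths$qc, stringsAsFactors = FALSE)
    qc <- apply_mri_qc(ledger)
    counts$mri_analyzed <- unname(qc$tally[["retained"]])
    counts$mri_exclusions <- as.list(qc$tally)
    thickness <- thickness[thickness$participant_id %in% qc$retained, ,
                           drop = FALSE]
    log_stage("qc: %d retained of %d", counts$mri_analyzed,
              qc$tally[["enrolled"]])
  }

  series <- NULL
  if (!is.null(config$variants)) {
    vs <- lapply(config$variants, variant_from_name)
    names(vs) <- unlist(config$variants)
    series <- run_model_series(processed, vs)
    if (!is.null(series$comparison))
      write.csv(as.data.frame(series$comparison),
                file.path(out_dir, "model_comparison.csv"), row.names = FALSE)
    for (nm in names(series$loadings))
      write.csv(series$loadings[[nm]],
                file.path(out_dir, paste0("loadings_",
                                          gsub("[^a-z0-9_]+", "_", nm),
                                          ".csv")), row.names = FALSE)
    ok <- sum(!vapply(series$fits, inherits, logical(1), "pubsem_fit_error"))
    counts$models_fitted <- ok
    counts$models_failed <- length(series$fits) - ok
    log_stage("fit series: %d fitted, %d failed", ok,
              counts$models_failed)
  }

  map <- NULL
  if (!is.null(config$brain)) {
    b <- config$brain
    vs <- lapply(b$variants %||% list("one_factor:full_multimethod"),
                 variant_from_name)
    map <- brain_sweep(processed, thickness, variants = vs,
                       age_modes = b$age %||% "none",
                       regions = unlist(b$regions),
                       estimator = b$estimator %||% "ml")
    write_brainmap(map, file.path(out_dir, "brainmap.tsv"))
    counts$brain_rows <- nrow(map)
    counts$brain_nonconverged <- sum(!map$converged)
    log_stage("brain sweep: %d associations (%d non-converged)",
              nrow(map), counts$brain_nonconverged)
  }

  cfg_file <- file.path(out_dir, "config_used.yaml")
  dump <- config
  dump$generator <- if (!is.null(config$generator))
    unclass(config$generator[c("n_participants", "factor_scheme", "seed")])
  yaml::write_yaml(lapply(unclass(dump), function(x)
    if (is.function(x)) NULL else x), cfg_file)
  manifest <- list(seed = config$seed,
                   config_digest = unname(tools::md5sum(cfg_file)),
                   package_version = as.character(utils::packageVersion("pubsem")),
                   counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, processed = processed, series = series,
                 map = map, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
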