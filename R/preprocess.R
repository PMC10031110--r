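# Hormone cleaning, saliva-window selection, composite scoring, MRI QC.

hormone_columns <- function(table)
  grep("^(saliva_(dhea|t|e2)_\\d|hair_(dhea|t|e2))$", names(table), value = TRUE)

#' Natural-log transform of hormone concentrations
#'
#' Applies `log()` to every saliva and hair hormone column, preserving
#' missing values. Assay concentrations must be strictly positive; a
#' non-positive cell is an upstream data error and is reported by row and
#' column rather than silently producing `-Inf`/`NaN`.
#'
#' @param table cohort data frame.
#' @return the table with hormone columns on the natural-log scale.
#' @export
log_transform_hormones <- function(table) {
  for (col in hormone_columns(table)) {
    x <- table[[col]]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad))
      stop(sprintf("non-positive concentration in column '%s', row %d (value %g)",
                   col, bad[1], x[bad[1]]))
    table[[col]] <- log(x)
  }
  table
}

#' Rank-preserving winsorization
#'
#' Replaces values more than `k_sd` sample standard deviations from the mean
#' by the value at the cut plus (above) or minus (below) small increments
#' that preserve the original ordering of the outliers: the j-th smallest
#' upper outlier becomes `mean + k_sd*sd + j*increment`, and symmetrically
#' below. Non-outliers and missing values are untouched, and the rank vector
#' of the data is unchanged.
#'
#' The mean and SD default to the sample moments of the non-missing input;
#' they can be supplied (`center`, `scale`) to winsorize against fixed cut
#' statistics, under which the operation is exactly idempotent.
#'
#' @param values numeric vector (>= 2 non-missing values).
#' @param k_sd cut in SD units (default 3).
#' @param increment rank-preserving step beyond the cut (default 0.01,
#'   i.e. 0.01 concentration units on whatever scale `values` is on).
#' @param center,scale optional fixed mean and SD for the cut.
#' @return the winsorized vector.
#' @export
#' @examples
#' winsorize_rank_preserving(c(rep(0, 19), 10))  # 10 -> 7.218...
winsorize_rank_preserving <- function(values, k_sd = 3, increment = 0.01,
                                      center = NULL, scale = NULL) {
  if (increment <= 0) stop("increment must be positive")
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values")
  m <- if (is.null(center)) mean(values[ok]) else center
  s <- if (is.null(scale)) sd(values[ok]) else scale
  hi <- m + k_sd * s
  lo <- m - k_sd * s
  up <- which(ok & values > hi)
  if (length(up)) {
    j <- rank(values[up], ties.method = "first")  # ascending, stable in input order
    values[up] <- hi + j * increment
  }
  dn <- which(ok & values < lo)
  if (length(dn)) {
    j <- rank(-values[dn], ties.method = "first") # most extreme gets largest step
    values[dn] <- lo - j * increment
  }
  values
}

#' Select the saliva sampling window
#'
#' Of a participant's dated saliva samples, retains the (up to) four with the
#' latest collection dates not after the second lab session, in
#' chronological order.
#'
#' @param dates vector of collection dates (`Date` or numeric day index);
#'   undated samples are an error.
#' @param session2_date date of the second session (same type as `dates`).
#' @return integer indices into `dates` of the retained samples (length <= 4,
#'   chronological).
#' @export
#' @examples
#' select_saliva_window(1:7, 10)  # -> 4 5 6 7
select_saliva_window <- function(dates, session2_date) {
  if (any(is.na(dates))) stop("undated saliva sample at position ",
                              which(is.na(dates))[1])
  eligible <- which(dates <= session2_date)
  if (!length(eligible)) return(integer(0))
  ord <- eligible[order(dates[eligible])]
  tail(ord, 4)
}

#' Default composite item mapping
#'
#' Theory-driven assignment of self-report items to pubertal processes:
#' body hair (PDS2), skin changes (PDS3) and the pubic-hair line drawing
#' (LD2) to adrenarche; height growth (PDS1), breast development (PDS4),
#' menarche (PDS6) and the breast line drawing (LD1) to gonadarche. The
#' assignment of PDS1 is conventional rather than settled (height growth may
#' track a separate growth-axis process) and can be overridden.
#'
#' @return named list with components `adrenarche` and `gonadarche`.
#' @export
default_composite_map <- function() {
  list(adrenarche = c("pds2", "pds3", "ld2"),
       gonadarche = c("pds1", "pds4", "pds6", "ld1"))
}

rescale_item_1to5 <- function(x, item) {
  if (item == "pds6") return(ifelse(x > 0, 5, 1))     # menarche no/yes
  if (grepl("^pds", item)) return(1 + (x - 1) * 4 / 3) # 4-point -> 1..5
  x                                                    # LD already 1..5
}

#' Composite pubertal scores and approximate Tanner stage
#'
#' Computes the adrenarche and gonadarche composites (means of the mapped
#' items, each linearly rescaled to the 1-5 range), the overall puberty
#' composite (mean of the two), and a PDS-only stage score approximating
#' Tanner stages. The stage mapping is a documented reconstruction of the
#' conventional scheme from body hair (PDS2), breast development (PDS4) and
#' menarche (PDS6): without menarche, stages 1-3 as the hair+breast sum is
#' 2, 3-5, or 6+; with menarche, stage 5 when both items are complete and
#' stage 4 otherwise.
#'
#' @param items data frame with columns `pds1`-`pds4` (1-4), `pds6` (0/1),
#'   `ld1`, `ld2` (1-5); missing values allowed.
#' @param map composite item mapping, see [default_composite_map()].
#' @param on_empty `"error"` (default) to fail when a participant has every
#'   item of a composite missing, or `"na"` to score it `NA`.
#' @return data frame with `adrenarche_composite`, `gonadarche_composite`,
#'   `puberty_composite`, `pds_stage`, all in \[1, 5\].
#' @export
score_composites <- function(items, map = default_composite_map(),
                             on_empty = c("error", "na")) {
  on_empty <- match.arg(on_empty)
  comp <- function(cols) {
    m <- sapply(cols, function(cl) rescale_item_1to5(items[[cl]], cl))
    m <- matrix(m, nrow = nrow(items))
    n_ok <- rowSums(!is.na(m))
    if (any(n_ok == 0) && on_empty == "error")
      stop("participant row ", which(n_ok == 0)[1],
           " has all items of a composite missing")
    rowMeans(m, na.rm = TRUE)
  }
  adr <- comp(map$adrenarche)
  gon <- comp(map$gonadarche)
  data.frame(adrenarche_composite = adr,
             gonadarche_composite = gon,
             puberty_composite = (adr + gon) / 2,
             pds_stage = pds_stage(items))
}

#' @rdname score_composites
#' @export
pds_stage <- function(items) {
  hb <- items$pds2 + items$pds4                # each 1-4, sum 2-8
  men <- items$pds6 > 0
  stage <- ifelse(men,
                  ifelse(hb == 8, 5, 4),
                  ifelse(hb <= 2, 1, ifelse(hb <= 5, 2, 3)))
  stage[is.na(hb) | is.na(men)] <- NA
  stage
}

#' MRI quality-control filter
#'
#' Applies the image-quality exclusion cascade: participants who opted out
#' of the MRI, whose raw T1 was rated 3 (worst) on the three-point quality
#' scale, or whose rating-2 image was excluded on re-examination for major
#' motion, are dropped. Returns the retained ids with an exclusion tally by
#' reason.
#'
#' @param ledger data frame with columns `participant_id`, `opted_out`
#'   (logical), `raw_rating` (1/2/3, `NA` when no MRI), and
#'   `rating2_motion_excluded` (logical; meaningful only for rating 2).
#' @return object of class `pubsem_qc`: list with `retained` (character ids)
#'   and `tally` (named counts).
#' @export
apply_mri_qc <- function(ledger) {
  if (anyDuplicated(ledger$participant_id))
    stop("duplicate participant ids in QC ledger")
  if (!nrow(ledger))
    return(structure(list(retained = character(0),
                          tally = c(enrolled = 0L, opted_out = 0L, rating3 = 0L,
                                    motion_excluded = 0L, retained = 0L)),
                     class = "pubsem_qc"))
  rating <- ledger$raw_rating
  if (any(!is.na(rating) & !rating %in% 1:3))
    stop("raw_rating must be 1, 2 or 3 when present")
  opted <- ledger$opted_out %in% TRUE
  r3 <- !opted & !is.na(rating) & rating == 3
  motion <- !opted & !is.na(rating) & rating == 2 &
    ledger$rating2_motion_excluded %in% TRUE
  keep <- !opted & !r3 & !motion & !is.na(rating)
  structure(list(
    retained = as.character(ledger$participant_id[keep]),
    tally = c(enrolled = nrow(ledger), opted_out = sum(opted),
              rating3 = sum(r3), motion_excluded = sum(motion),
              retained = sum(keep))), class = "pubsem_qc")
}

#' @export
print.pubsem_qc <- function(x, ...) {
  cat("MRI QC cascade:\n")
  t <- x$tally
  cat(sprintf("  enrolled %d | opted out %d | rating-3 excluded %d | motion excluded %d -> retained %d\n",
              t[["enrolled"]], t[["opted_out"]], t[["rating3"]],
              t[["motion_excluded"]], t[["retained"]]))
  invisible(x)
}

#' Synthetic QC ledger mirroring the published exclusion cascade
#'
#' Builds a ledger with the enrolment arithmetic of the study cascade:
#' of `n_total` enrolled, `n_opt_out` skip the MRI; the remainder are rated
#' 1-3 with `n_rating3` at the worst grade and `n_rating2` at grade 2, of
#' whom `n_motion` are excluded for major motion. Ids are synthetic.
#'
#' @param n_total,n_opt_out,n_rating3,n_rating2,n_motion cascade counts;
#'   defaults encode 174 enrolled, 10 opt-outs, 25 rating-3, 112 rating-2
#'   with 27 motion exclusions (the remaining 27 scans are rating 1).
#' @return a QC ledger data frame for [apply_mri_qc()].
#' @export
qc_cascade_ledger <- function(n_total = 174, n_opt_out = 10, n_rating3 = 25,
                              n_rating2 = 112, n_motion = 27) {
  n_scanned <- n_total - n_opt_out
  n_rating1 <- n_scanned - n_rating3 - n_rating2
  if (n_rating1 < 0) stop("rating counts exceed scanned participants")
  if (n_motion > n_rating2) stop("motion exclusions exceed rating-2 scans")
  rating <- c(rep(NA_integer_, n_opt_out), rep(1L, n_rating1),
              rep(2L, n_rating2), rep(3L, n_rating3))
  motion <- c(rep(FALSE, n_opt_out + n_rating1),
              rep(c(TRUE, FALSE), c(n_motion, n_rating2 - n_motion)),
              rep(FALSE, n_rating3))
  data.frame(participant_id = sprintf("sub%05d", seq_len(n_total)),
             opted_out = rating %in% NA,
             raw_rating = rating,
             rating2_motion_excluded = motion)
}

#' End-to-end hormone cleaning and scoring
#'
#' Runs the cleaning pipeline on a cohort table: log-transform hormone
#' concentrations, winsorize each hormone column beyond `k_sd` SDs on the
#' log scale with rank-preserving increments, and append the composite
#' scores of [score_composites()].
#'
#' @param cohort cohort data frame (see [generate_cohort()]).
#' @param k_sd,increment winsorization settings, applied on the log scale.
#' @param composite_map see [default_composite_map()].
#' @return the cleaned cohort with composite columns appended.
#' @export
preprocess_cohort <- function(cohort, k_sd = 3, increment = 0.01,
                              composite_map = default_composite_map()) {
  out <- log_transform_hormones(cohort)
  for (col in hormone_columns(out))
    out[[col]] <- winsorize_rank_preserving(out[[col]], k_sd = k_sd,
                                            increment = increment)
  cbind(out, score_composites(out, map = composite_map, on_empty = "na"))
}
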