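# Hormone cleaning, saliva window, composites, MRI QC.

test_that("log transform hits known values and flags bad cells", {
  tab <- data.frame(saliva_dhea_1 = c(1, exp(1), 104, NA))
  out <- log_transform_hormones(tab)
  expect_equal(out$saliva_dhea_1[1:3], c(0, 1, log(104)))
  expect_equal(out$saliva_dhea_1[3], 4.644, tolerance = 1e-3)
  expect_true(is.na(out$saliva_dhea_1[4]))
  expect_error(log_transform_hormones(data.frame(hair_t = c(2, -1))),
               "hair_t.*row 2")
})

test_that("winsorization replaces the known outlier at cut plus one increment", {
  x <- c(rep(0, 19), 10)
  out <- winsorize_rank_preserving(x)
  cut <- 0.5 + 3 * sqrt(5)    # mean 0.5, sample SD sqrt(5)
  expect_equal(out[20], cut + 0.01)
  expect_equal(out[20], 7.218, tolerance = 1e-3)
  expect_equal(out[1:19], rep(0, 19))
})

test_that("winsorization leaves outlier-free data untouched and preserves ranks", {
  set.seed(4)
  x <- rnorm(50)
  expect_identical(winsorize_rank_preserving(x), x)
  y <- c(rnorm(500), 8, 9, 12, -7)
  out <- winsorize_rank_preserving(y)
  expect_identical(rank(out), rank(y))
  expect_identical(out[1:500], y[1:500])
})

test_that("tied upper outliers get consecutive increments in input order", {
  x <- c(rep(0, 40), 50, 50)
  out <- winsorize_rank_preserving(x)
  m <- mean(x); s <- sd(x)
  expect_equal(out[41:42], m + 3 * s + c(0.01, 0.02))
  # symmetric treatment below the mean
  z <- c(rep(0, 40), -50)
  lo <- mean(z) - 3 * sd(z)
  expect_equal(winsorize_rank_preserving(z)[41], lo - 0.01)
})

test_that("winsorization with fixed cut statistics is idempotent", {
  x <- c(rnorm(100), 15, 20)
  once <- winsorize_rank_preserving(x, center = 0, scale = 1)
  twice <- winsorize_rank_preserving(once, center = 0, scale = 1)
  expect_identical(once, twice)
})

test_that("winsorization rejects degenerate input", {
  expect_error(winsorize_rank_preserving(c(1, NA)), "2 non-missing")
  expect_error(winsorize_rank_preserving(1:10, increment = 0), "increment")
})

test_that("saliva window keeps the last four samples before session 2", {
  expect_equal(select_saliva_window(1:7, 100), 4:7)
  expect_equal(select_saliva_window(1:4, 100), 1:4)
  expect_equal(select_saliva_window(c(1, 2, 3, 4, 50), 10), 1:4)
  expect_equal(select_saliva_window(c(30, 10, 20), 25), c(2, 3))
  expect_error(select_saliva_window(c(1, NA, 3), 5), "undated")
})

test_that("composites hit the scale boundaries and stay in range", {
  lo <- data.frame(pds1 = 1, pds2 = 1, pds3 = 1, pds4 = 1, pds6 = 0,
                   ld1 = 1, ld2 = 1)
  hi <- data.frame(pds1 = 4, pds2 = 4, pds3 = 4, pds4 = 4, pds6 = 1,
                   ld1 = 5, ld2 = 5)
  expect_equal(unlist(score_composites(lo)[1, 1:3]),
               c(adrenarche_composite = 1, gonadarche_composite = 1,
                 puberty_composite = 1))
  expect_equal(unname(unlist(score_composites(hi)[1, ])), c(5, 5, 5, 5))
})

test_that("composites are monotone in every constituent item", {
  base <- data.frame(pds1 = 2, pds2 = 2, pds3 = 2, pds4 = 2, pds6 = 0,
                     ld1 = 3, ld2 = 3)
  s0 <- score_composites(base)
  for (col in names(base)) {
    up <- base
    up[[col]] <- up[[col]] + 1
    s1 <- score_composites(up)
    expect_true(all(unlist(s1[1, 1:3]) >= unlist(s0[1, 1:3]) - 1e-12),
                info = col)
  }
})

test_that("synthetic cohort composite means sit in the descriptive band", {
  dat <- generate_cohort(clean_config(2000), seed = 8)
  sc <- score_composites(dat$cohort, on_empty = "na")
  expect_gt(mean(sc$puberty_composite, na.rm = TRUE), 2.91 - 0.5)
  expect_lt(mean(sc$puberty_composite, na.rm = TRUE), 2.91 + 0.5)
  expect_gt(sd(sc$puberty_composite, na.rm = TRUE), 0.4)
  expect_lt(sd(sc$puberty_composite, na.rm = TRUE), 1.4)
  expect_true(all(sc$pds_stage %in% 1:5 | is.na(sc$pds_stage)))
})

test_that("composite scoring errors when a composite has no items", {
  empty <- data.frame(pds1 = 1, pds2 = NA, pds3 = NA, pds4 = 1, pds6 = 0,
                      ld1 = 2, ld2 = NA)
  expect_error(score_composites(empty), "all items")
  expect_true(is.na(score_composites(empty, on_empty = "na")$adrenarche_composite))
})

test_that("MRI QC cascade reproduces the enrolment arithmetic", {
  qc <- apply_mri_qc(qc_cascade_ledger())
  expect_equal(unname(qc$tally[["retained"]]), 112)
  expect_equal(unname(qc$tally[["enrolled"]]), 174)
  expect_equal(unname(qc$tally[["opted_out"]]), 10)
  expect_equal(unname(qc$tally[["rating3"]]), 25)
  expect_equal(unname(qc$tally[["motion_excluded"]]), 27)
  expect_length(qc$retained, 112)
})

test_that("MRI QC handles edge ledgers", {
  empty <- qc_cascade_ledger(0, 0, 0, 0, 0)
  expect_length(apply_mri_qc(empty)$retained, 0)
  allgood <- qc_cascade_ledger(50, 5, 0, 0, 0)   # 45 scans, all rating 1
  expect_length(apply_mri_qc(allgood)$retained, 45)
  dup <- qc_cascade_ledger(10, 0, 0, 0, 0)
  dup$participant_id[2] <- dup$participant_id[1]
  expect_error(apply_mri_qc(dup), "duplicate")
})

test_that("preprocessing pipeline winsorizes on the log scale", {
  dat <- generate_cohort(cohort_config(n_participants = 1000,
                                       outlier_rate = 0.02), seed = 13)
  proc <- preprocess_cohort(dat$cohort)
  z <- scale(proc$saliva_dhea_2[!is.na(proc$saliva_dhea_2)])
  # after winsorization nothing sits far beyond the 3 SD cut
  expect_lt(max(z), 3.5)
  expect_true(all(c("adrenarche_composite", "pds_stage") %in% names(proc)))
})
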