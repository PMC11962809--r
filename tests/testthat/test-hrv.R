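make_annotations <- function(r_samples_list, quality = NULL, fs = 500) {
  if (is.null(quality)) {
    quality <- stats::setNames(rep("ok", length(r_samples_list)),
                               names(r_samples_list))
  }
  structure(list(per_lead_r_samples = r_samples_list,
                 per_lead_quality = quality, fs = fs),
            class = "beat_annotations")
}

test_that("per-lead heart rate is 60000 / mean RR", {
  # RR all 800 ms = 400 samples at 500 Hz
  ann <- make_annotations(list(II = as.integer(seq(1, by = 400, length.out = 10))))
  hr <- per_lead_heart_rate(ann)
  expect_equal(unname(hr["II"]), 75.0)
  # two leads with RR means 1000 ms and 600 ms
  ann2 <- make_annotations(list(I = as.integer(seq(1, by = 500, length.out = 8)),
                                II = as.integer(seq(1, by = 300, length.out = 8))))
  hr2 <- per_lead_heart_rate(ann2)
  expect_equal(unname(hr2["I"]), 60.0)
  expect_equal(unname(hr2["II"]), 100.0)
})

test_that("a record with no reliable lead is flagged HR-undeterminable", {
  ann <- make_annotations(list(I = integer(0), II = integer(0)),
                          quality = c(I = "unreliable", II = "unreliable"))
  hr <- per_lead_heart_rate(ann)
  expect_identical(length(hr), 0L)
  expect_true(attr(hr, "hr_undeterminable"))
})

test_that("median-lead selection follows the odd, even and tie rules", {
  expect_identical(select_median_lead(c(I = 70, II = 72, V1 = 75)), "II")
  # even count: lead holding the lower of the two middle values
  expect_identical(select_median_lead(c(I = 70, II = 72, V1 = 74, V2 = 76)),
                   "II")
  # exact tie broken by canonical lead order
  expect_identical(select_median_lead(c(V1 = 72, II = 72, I = 72)), "I")
  expect_error(select_median_lead(numeric(0)), "empty")
})

test_that("NN filtering applies the bounds and running-median rules", {
  f1 <- filter_nn_intervals(c(800, 810, 790, 805))
  expect_identical(f1$intervals, c(800, 810, 790, 805))
  expect_identical(f1$n_rejected, 0L)
  f2 <- filter_nn_intervals(c(800, 810, 2500, 805))
  expect_identical(f2$intervals, c(800, 810, 805))
  expect_identical(f2$n_rejected, 1L)
  f3 <- filter_nn_intervals(c(800, 790, 810, 795, 805, 1200))
  expect_identical(f3$intervals, c(800, 790, 810, 795, 805))
  expect_identical(f3$n_rejected, 1L)
  expect_true(f3$valid)
  # fewer than 3 survivors makes the series invalid
  f4 <- filter_nn_intervals(c(100, 100, 800, 810))
  expect_false(f4$valid)
  expect_error(filter_nn_intervals(800), "at least 2")
})

test_that("hand-evaluable HRV feature cases match their closed forms", {
  constant <- compute_hrv_features(as_nn_series(c(800, 800, 800, 800)))
  expect_equal(constant$sdnn, 0)
  expect_equal(constant$rmssd, 0)
  expect_equal(constant$pnn20, 0)
  expect_equal(constant$pnn50, 0)
  expect_equal(constant$hr_mad, 0)
  expect_equal(constant$heart_rate, 75)

  jittered <- compute_hrv_features(as_nn_series(c(800, 860, 805, 900)))
  expect_equal(jittered$rmssd, sqrt((60^2 + 55^2 + 95^2) / 3))
  expect_equal(jittered$pnn20, 100)
  expect_equal(jittered$pnn50, 100)

  ramp <- compute_hrv_features(as_nn_series(c(700, 800, 900)))
  expect_equal(ramp$ibi, 800)
  expect_equal(ramp$heart_rate, 75)
  expect_equal(ramp$sdnn, sqrt(20000 / 3))
})

test_that("all 8 features match the naive-loop oracle on 100 random series", {
  set.seed(99)
  for (i in 1:100) {
    x <- round(runif(sample(5:50, 1), 350, 1900), 3)
    got <- compute_hrv_features(as_nn_series(x))
    want <- naive_hrv(x)
    for (nm in names(want)) {
      denom <- max(abs(want[[nm]]), 1e-12)
      expect_lt(abs(got[[nm]] - want[[nm]]) / denom, 1e-9)
    }
  }
})

test_that("HRV features are scale-equivariant and satisfy the rmssd identity", {
  set.seed(4)
  x <- runif(30, 500, 1200)
  f1 <- compute_hrv_features(as_nn_series(x))
  f2 <- compute_hrv_features(as_nn_series(3 * x))
  for (nm in c("ibi", "sdnn", "sdsd", "rmssd", "hr_mad")) {
    expect_equal(f2[[nm]], 3 * f1[[nm]], tolerance = 1e-12)
  }
  expect_equal(f2$heart_rate, f1$heart_rate / 3, tolerance = 1e-12)
  d <- diff(x)
  expect_equal(f1$rmssd^2, f1$sdsd^2 + mean(d)^2, tolerance = 1e-9)
  # invariant bundle: non-negativity, pnn ordering, HR identity
  expect_true(all(c(f1$sdnn, f1$sdsd, f1$rmssd, f1$hr_mad) >= 0))
  expect_gte(f1$pnn20, f1$pnn50)
  expect_equal(f1$heart_rate, 60000 / f1$ibi, tolerance = 1e-6)
})

test_that("sample-SD mode matches R's sd and population is the default", {
  x <- c(700, 820, 760, 900, 650)
  pop <- compute_hrv_features(as_nn_series(x))
  smp <- compute_hrv_features(as_nn_series(x), sd_mode = "sample")
  expect_equal(smp$sdnn, sd(x))
  expect_equal(pop$sdnn, sqrt(mean((x - mean(x))^2)))
  alt <- compute_hrv_features(as_nn_series(x), hr_mad_mode = "mean_nn")
  expect_equal(alt$hr_mad, mean(abs(x - mean(x))))
})

test_that("an invalid NN series yields valid = FALSE with features absent", {
  f <- compute_hrv_features(as_nn_series(c(800, 810)))
  expect_false(f$valid)
  expect_null(f$sdnn)
})

test_that("end-to-end extraction recovers the configured heart rate", {
  cfg <- clean_config(n_records = 2, prevalence = 0.5,
                      sinus_hr_range = c(72, 72), sinus_rr_sd = 0, seed = 21)
  cohort <- generate_cohort(cfg)
  r <- cohort$records[[which(vapply(cohort$records, `[[`, "", "label") ==
                               "negative")[1]]]
  f <- extract_hrv(r)
  expect_true(f$valid)
  expect_lt(abs(f$heart_rate - 72), 1)
  expect_lt(f$sdnn, 5)
})

test_that("the batch feature table has the documented columns and flags invalids", {
  cfg <- synth_config(n_records = 4, prevalence = 0.5, seed = 22)
  cohort <- generate_cohort(cfg)
  # one record the detector cannot use: flat signal
  flat <- ecg_record(matrix(0, 8, 5000),
                     c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6"), 500,
                     label = "negative", id = "flat01")
  tab <- hrv_feature_table(c(cohort$records, list(flat)))
  expect_identical(names(tab),
                   c("record_id", "lead", "heart_rate", "ibi", "sdnn",
                     "sdsd", "rmssd", "pnn20", "pnn50", "hr_mad", "valid"))
  expect_identical(nrow(tab), 5L)
  expect_false(tab$valid[tab$record_id == "flat01"])
  expect_true(is.na(tab$sdnn[tab$record_id == "flat01"]))
  expect_true(all(tab$valid[tab$record_id != "flat01"]))
})
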