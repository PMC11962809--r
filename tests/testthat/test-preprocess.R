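canonical <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

test_that("standardise_record reduces shuffled 12-lead input to canonical 8 x 5000", {
  set.seed(1)
  leads12 <- c("V4", "III", "I", "aVR", "V1", "II", "aVL", "V6", "V2",
               "aVF", "V3", "V5")
  raw <- matrix(rnorm(12 * 6000), 12, 6000)
  out <- standardise_record(raw, leads12, 500)
  expect_identical(dim(out), c(8L, 5000L))
  expect_identical(rownames(out), canonical)
  # values come from the right rows, truncated from the end
  expect_identical(out["V4", ], raw[1, 1:5000])
  expect_identical(out["I", ], raw[3, 1:5000])
})

test_that("standardise_record is the identity on canonical input and idempotent", {
  set.seed(2)
  raw <- matrix(rnorm(8 * 5000), 8, 5000)
  out <- standardise_record(raw, canonical, 500)
  expect_identical(unname(out), unname(raw))
  expect_identical(standardise_record(out, rownames(out), 500), out)
})

test_that("standardise_record rejects bad rates, missing leads and short records", {
  raw <- matrix(0, 8, 5000)
  expect_error(standardise_record(raw, canonical, 250), "sampling rate")
  expect_error(standardise_record(raw[1:7, ], canonical[1:7], 500),
               "missing retained lead")
  expect_error(standardise_record(matrix(0, 8, 4000), canonical, 500),
               "shorter than 5000")
})

test_that("wavelet denoising maps zero to zero and never adds energy", {
  expect_identical(wavelet_denoise(rep(0, 5000)), rep(0, 5000))
  set.seed(3)
  x <- sin((1:5000) / 40) + rnorm(5000, 0, 0.1)
  d <- wavelet_denoise(x)
  expect_identical(length(d), length(x))
  expect_lte(sum(d^2), sum(x^2) * (1 + 1e-6))
})

test_that("wavelet denoising reduces RMSE against the clean reference at SNR 10 dB", {
  cfg <- clean_config(n_records = 1, seed = 2)
  set.seed(2)
  rr <- generate_rr_sequence("negative", cfg)
  clean <- render_beat_train(rr, "negative", cfg)$signal["II", ]
  noise_sd <- sqrt(mean(clean^2) / 10) # SNR 10 dB
  set.seed(10)
  rmse <- replicate(20, {
    x <- clean + rnorm(length(clean), 0, noise_sd)
    d <- wavelet_denoise(x)
    c(before = sqrt(mean((x - clean)^2)), after = sqrt(mean((d - clean)^2)))
  })
  expect_lt(mean(rmse["after", ]), mean(rmse["before", ]))
})

test_that("a second denoising pass changes the RMS far less than the first", {
  cfg <- clean_config(n_records = 1, seed = 2)
  set.seed(2)
  rr <- generate_rr_sequence("negative", cfg)
  clean <- render_beat_train(rr, "negative", cfg)$signal["II", ]
  set.seed(11)
  x <- clean + rnorm(length(clean), 0, sqrt(mean(clean^2) / 10))
  rms <- function(v) sqrt(mean(v^2))
  d1 <- wavelet_denoise(x)
  d2 <- wavelet_denoise(d1)
  change1 <- abs(rms(d1) - rms(x))
  change2 <- abs(rms(d2) - rms(d1))
  expect_lt(change2, 0.1 * change1)
})

test_that("the detector finds every truth peak on clean sinus leads with no extras", {
  cfg <- clean_config(n_records = 6, prevalence = 0.5, seed = 7)
  cohort <- generate_cohort(cfg)
  for (r in cohort$records) {
    if (r$label != "negative") next
    det <- detect_r_peaks(wavelet_denoise(r$signal["II", ]), r$fs)
    expect_identical(det$quality, "ok")
    sc <- peak_scores(det$r_samples, r$truth)
    expect_identical(unname(sc["recall"]), 1)
    expect_identical(unname(sc["precision"]), 1)
    expect_identical(length(det$r_samples), length(r$truth))
  }
})

test_that("a flat lead yields no peaks and an unreliable flag", {
  det <- detect_r_peaks(rep(0, 5000), 500)
  expect_identical(det$r_samples, integer(0))
  expect_identical(det$quality, "unreliable")
})

test_that("detection stays above 0.95 recall and precision at SNR 10 dB", {
  cfg <- clean_config(n_records = 20, prevalence = 0.3, seed = 8)
  cohort <- generate_cohort(cfg)
  set.seed(9)
  sc <- vapply(cohort$records, function(r) {
    x <- r$signal["II", ]
    x <- x + rnorm(length(x), 0, sqrt(mean(x^2) / 10))
    det <- detect_r_peaks(wavelet_denoise(x), r$fs)
    peak_scores(det$r_samples, r$truth)
  }, numeric(2))
  expect_gte(mean(sc["recall", ]), 0.95)
  expect_gte(mean(sc["precision", ]), 0.95)
})

test_that("detected peaks are strictly increasing with the 200 ms refractory enforced", {
  # AF records with noise and wander on: the stress case for spacing
  cfg <- synth_config(n_records = 4, prevalence = 0.75, seed = 10)
  cohort <- generate_cohort(cfg)
  for (r in cohort$records) {
    det <- detect_r_peaks(wavelet_denoise(r$signal["II", ]), r$fs)
    if (length(det$r_samples) > 1) {
      expect_true(all(diff(det$r_samples) >= 0.2 * r$fs))
    }
  }
})

test_that("detector heart rate matches a zero-variance sinus record within 1 bpm", {
  cfg <- clean_config(n_records = 2, prevalence = 0.5,
                      sinus_hr_range = c(80, 80), sinus_rr_sd = 0, seed = 3)
  cohort <- generate_cohort(cfg)
  r <- cohort$records[[which(vapply(cohort$records, `[[`, "", "label") ==
                               "negative")[1]]]
  det <- detect_r_peaks(wavelet_denoise(r$signal["II", ]), r$fs)
  hr <- 60000 / mean(diff(det$r_samples) / r$fs * 1000)
  expect_lt(abs(hr - 80), 1)
})

test_that("annotate_beats returns per-lead annotations for all 8 leads", {
  cfg <- clean_config(n_records = 1, prevalence = 0.5, seed = 14)
  expect_warning(cohort <- generate_cohort(cfg), "forcing one positive")
  r <- cohort$records[[1]]
  ann <- annotate_beats(r)
  expect_s3_class(ann, "beat_annotations")
  expect_identical(names(ann$per_lead_r_samples), canonical)
  expect_identical(names(ann$per_lead_quality), canonical)
  expect_true(all(ann$per_lead_quality == "ok"))
  for (l in canonical) {
    expect_true(all(ann$per_lead_r_samples[[l]] <= ncol(r$signal)))
  }
})
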