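#' @useDynLib afdetect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom median sd quantile predict filter fft
#' @importFrom utils write.csv read.csv
NULL

CANONICAL_LEADS <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

# Relative amplitude of the beat template in each retained lead.
LEAD_SCALES <- c(I = 0.6, II = 1.0, V1 = 0.5, V2 = 0.8,
                 V3 = 0.9, V4 = 1.0, V5 = 0.9, V6 = 0.8)

# P, Q, R, S, T gaussian bump parameters: offset from R (ms), width (ms),
# base amplitude (mV). Each bump is rendered on a +/- 3.5 sigma support so
# that neighbouring waves do not bleed into the R apex.
WAVE_MU_MS    <- c(P = -160, Q = -40, R = 0, S = 40, T = 300)
WAVE_SIGMA_MS <- c(P = 25, Q = 10, R = 12, S = 10, T = 60)
WAVE_AMP_MV   <- c(P = 0.15, Q = -0.10, R = 1.0, S = -0.20, T = 0.30)

#' Configuration for the synthetic ECG cohort generator
#'
#' Builds a validated configuration object describing one synthetic cohort.
#' The generator emulates 8-lead, 10 s, 500 Hz recordings in which the
#' positive (AF/AFL) class has irregular RR intervals, no P-wave and a
#' low-amplitude fibrillatory baseline oscillation, while the negative
#' (sinus) class has regular RR intervals and full P-QRS-T morphology.
#' Demographics are class-correlated: AF cases are older on average and
#' slightly more often male.
#'
#' @param n_records number of records in the cohort.
#' @param prevalence positive-class fraction in (0,1); default 0.044.
#' @param fs sampling rate in Hz.
#' @param duration record length in seconds.
#' @param sinus_hr_range per-record sinus heart-rate range (bpm).
#' @param sinus_rr_sd within-record RR standard deviation for sinus (ms).
#' @param af_rr_sd_range range of per-record RR standard deviation for AF (ms).
#' @param af_rr_mean_range range of per-record mean RR for AF (ms).
#' @param fib_wave_amp fibrillatory wave amplitude (mV).
#' @param fib_wave_freq_range fibrillatory wave frequency range (Hz).
#' @param noise_sd additive white noise standard deviation (mV).
#' @param baseline_wander_amp baseline wander amplitude (mV).
#' @param corrupt_lead_prob per-lead probability of a 10x noise corruption.
#' @param age_pos,age_neg (mean, sd) of age in years per class.
#' @param seed integer seed; the cohort is a pure function of the config.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_records = 1000,
                         prevalence = 0.044,
                         fs = 500,
                         duration = 10,
                         sinus_hr_range = c(55, 95),
                         sinus_rr_sd = 25,
                         af_rr_sd_range = c(90, 180),
                         af_rr_mean_range = c(550, 900),
                         fib_wave_amp = 0.05,
                         fib_wave_freq_range = c(4, 9),
                         noise_sd = 0.02,
                         baseline_wander_amp = 0.1,
                         corrupt_lead_prob = 0,
                         age_pos = c(74, 9),
                         age_neg = c(60, 14),
                         seed = 1L) {
  cfg <- list(n_records = as.integer(n_records), prevalence = prevalence,
              fs = fs, duration = duration,
              sinus_hr_range = sinus_hr_range, sinus_rr_sd = sinus_rr_sd,
              af_rr_sd_range = af_rr_sd_range,
              af_rr_mean_range = af_rr_mean_range,
              fib_wave_amp = fib_wave_amp,
              fib_wave_freq_range = fib_wave_freq_range,
              noise_sd = noise_sd,
              baseline_wander_amp = baseline_wander_amp,
              corrupt_lead_prob = corrupt_lead_prob,
              age_pos = age_pos, age_neg = age_neg,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!(cfg$prevalence > 0 && cfg$prevalence < 1))
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  n_samples <- cfg$fs * cfg$duration
  if (abs(n_samples - round(n_samples)) > 1e-9)
    stop("fs * duration must be an integer sample count", call. = FALSE)
  for (nm in c("sinus_hr_range", "af_rr_sd_range", "af_rr_mean_range",
               "fib_wave_freq_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || r[1] > r[2])
      stop(nm, " must be an ordered (low, high) pair", call. = FALSE)
  }
  if (cfg$sinus_rr_sd < 0 || cfg$noise_sd < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  if (cfg$af_rr_sd_range[1] <= 0)
    stop("af_rr_sd_range must be positive", call. = FALSE)
  if (cfg$corrupt_lead_prob < 0 || cfg$corrupt_lead_prob > 1)
    stop("corrupt_lead_prob must be a fraction", call. = FALSE)
  invisible(cfg)
}

#' Construct an ECG record object
#'
#' @param signal numeric matrix `[n_leads x n_samples]` in mV.
#' @param lead_names ordered lead labels.
#' @param fs sampling rate (Hz).
#' @param age age in years (or `NA`).
#' @param sex `"male"` or `"female"` (or `NA`).
#' @param label `"AF_positive"` or `"negative"`.
#' @param source free-text provenance tag.
#' @param truth optional ground-truth R-peak sample indices (synthetic only).
#' @param id record identifier.
#' @return object of class `ecg_record`.
#' @export
ecg_record <- function(signal, lead_names, fs, age = NA_real_,
                       sex = NA_character_, label = "negative",
                       source = "unknown", truth = NULL, id = NA_character_) {
  stopifnot(is.matrix(signal), nrow(signal) == length(lead_names),
            !anyDuplicated(lead_names), all(is.finite(signal)))
  rownames(signal) <- lead_names
  structure(list(signal = signal, lead_names = lead_names, fs = fs,
                 age = age, sex = sex, label = label, source = source,
                 truth = truth, id = id),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d leads x %d samples @ %g Hz, label=%s, age=%s, sex=%s>\n",
              x$id, nrow(x$signal), ncol(x$signal), x$fs, x$label,
              format(x$age), x$sex))
  invisible(x)
}

# Draw from N(mean, sd) truncated to [lo, hi] by rejection; sd = 0 collapses
# to the mean.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate one record's RR interval sequence
#'
#' Sinus records draw RR around a fixed per-record mean (60000/HR with HR
#' uniform over `sinus_hr_range`) with standard deviation `sinus_rr_sd`.
#' AF records draw RR independently from a truncated normal on
#' \[300, 1800\] ms with per-record mean and standard deviation drawn from
#' `af_rr_mean_range` / `af_rr_sd_range`. The sequence always covers at
#' least the configured record duration. Randomness comes from the current
#' R RNG state; seed upstream for reproducibility.
#'
#' @param class_label `"AF_positive"` or `"negative"`.
#' @param config a [synth_config()].
#' @return numeric vector of RR intervals (ms) whose cumulative sum exceeds
#'   `duration * 1000`.
#' @export
generate_rr_sequence <- function(class_label, config) {
  validate_synth_config(config)
  total_ms <- config$duration * 1000
  if (class_label == "AF_positive") {
    mu <- runif(1, config$af_rr_mean_range[1], config$af_rr_mean_range[2])
    sdv <- runif(1, config$af_rr_sd_range[1], config$af_rr_sd_range[2])
    draw <- function(n) rtruncnorm(n, mu, sdv, 300, 1800)
  } else {
    hr <- runif(1, config$sinus_hr_range[1], config$sinus_hr_range[2])
    mu <- 60000 / hr
    sdv <- config$sinus_rr_sd
    draw <- function(n) rtruncnorm(n, mu, sdv, 300, 1800)
  }
  rr <- draw(ceiling(total_ms / max(mu - 3 * sdv, 300)) + 4L)
  while (sum(rr) <= total_ms) rr <- c(rr, draw(8L))
  idx <- which(cumsum(rr) > total_ms)[1]
  rr[seq_len(idx)]
}

# Add one gaussian bump (trimmed at +/- 3.5 sigma) to a single-lead trace.
add_bump <- function(trace, centre_s, sigma_s, amp, fs, n) {
  lo <- max(1L, floor((centre_s - 3.5 * sigma_s) * fs) + 1L)
  hi <- min(n, ceiling((centre_s + 3.5 * sigma_s) * fs) + 1L)
  if (lo > n || hi < 1L) return(trace)
  t <- (seq(lo, hi) - 1L) / fs
  trace[lo:hi] <- trace[lo:hi] + amp * exp(-(t - centre_s)^2 / (2 * sigma_s^2))
  trace
}

#' Render a beat train into an 8-lead signal matrix
#'
#' Each beat is a sum of gaussian bumps for the P, Q, R, S and T waves at
#' fixed offsets from the R time. AF records have the P amplitude set to
#' zero and a continuous fibrillatory sinusoid added; all records receive
#' additive white noise and low-frequency baseline wander (both switchable
#' off through the config).
#'
#' @inheritParams generate_rr_sequence
#' @param rr_sequence RR intervals in ms, as from [generate_rr_sequence()].
#' @return list with `signal` (8 x n_samples matrix, mV) and `truth`
#'   (1-based R-peak sample indices).
#' @export
render_beat_train <- function(rr_sequence, class_label, config) {
  validate_synth_config(config)
  total_ms <- config$duration * 1000
  if (sum(rr_sequence) <= total_ms)
    stop("rr_sequence does not cover the record duration", call. = FALSE)
  n <- as.integer(round(config$fs * config$duration))
  fs <- config$fs
  r_times_ms <- cumsum(rr_sequence)
  r_times_ms <- r_times_ms[r_times_ms < total_ms - 40] # keep QRS inside
  # snap R apexes to the sample grid so truth indices are exact
  r_idx <- as.integer(round(r_times_ms / 1000 * fs))
  r_times_s <- r_idx / fs
  amps <- WAVE_AMP_MV
  if (class_label == "AF_positive") amps["P"] <- 0

  template <- numeric(n)
  for (rt in r_times_s) {
    for (w in names(WAVE_MU_MS)) {
      if (amps[[w]] == 0) next
      template <- add_bump(template, rt + WAVE_MU_MS[[w]] / 1000,
                           WAVE_SIGMA_MS[[w]] / 1000, amps[[w]], fs, n)
    }
  }
  if (class_label == "AF_positive" && config$fib_wave_amp > 0) {
    f <- runif(1, config$fib_wave_freq_range[1], config$fib_wave_freq_range[2])
    phase <- runif(1, 0, 2 * pi)
    tt <- (seq_len(n) - 1L) / fs
    template <- template + config$fib_wave_amp * sin(2 * pi * f * tt + phase)
  }
  signal <- outer(unname(LEAD_SCALES), template)
  rownames(signal) <- CANONICAL_LEADS

  if (config$baseline_wander_amp > 0) {
    tt <- (seq_len(n) - 1L) / fs
    for (l in seq_len(8)) {
      fbw <- runif(1, 0.15, 0.4)
      ph <- runif(1, 0, 2 * pi)
      a <- runif(1, 0.5, 1) * config$baseline_wander_amp
      signal[l, ] <- signal[l, ] + a * sin(2 * pi * fbw * tt + ph)
    }
  }
  if (config$noise_sd > 0 || config$corrupt_lead_prob > 0) {
    corrupt <- runif(8) < config$corrupt_lead_prob
    sds <- config$noise_sd * ifelse(corrupt, 10, 1)
    # a corrupted lead gets at least some noise to corrupt
    sds[corrupt & sds == 0] <- 0.1
    for (l in seq_len(8)) {
      if (sds[l] > 0) signal[l, ] <- signal[l, ] + rnorm(n, 0, sds[l])
    }
  }
  truth <- as.integer(round(r_times_ms / 1000 * fs)) + 1L
  list(signal = signal, truth = truth)
}

#' Generate a labelled synthetic cohort
#'
#' Produces exactly `round(n_records * prevalence)` positive records (at
#' least one, with a warning if rounding would give zero). Ages are drawn
#' from class-specific normals clipped to \[18, 95\] years; sex is Bernoulli
#' with male probability 0.55 for positives and 0.50 for negatives. The
#' whole cohort, including signals, is a deterministic function of the
#' config (seed included).
#'
#' @param config a [synth_config()].
#' @return list with `records` (list of [ecg_record()]) and `manifest`
#'   (data.frame: id, label, age, sex, source, seed).
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  n <- config$n_records
  n_pos <- round(n * config$prevalence)
  if (n_pos < 1) {
    warning("n_records * prevalence < 1; forcing one positive record")
    n_pos <- 1L
  }
  labels <- sample(c(rep("AF_positive", n_pos), rep("negative", n - n_pos)))
  records <- vector("list", n)
  ages <- numeric(n); sexes <- character(n)
  for (i in seq_len(n)) {
    pos <- labels[i] == "AF_positive"
    ap <- if (pos) config$age_pos else config$age_neg
    ages[i] <- min(95, max(18, rnorm(1, ap[1], ap[2])))
    sexes[i] <- if (runif(1) < (if (pos) 0.55 else 0.50)) "male" else "female"
    rr <- generate_rr_sequence(labels[i], config)
    bt <- render_beat_train(rr, labels[i], config)
    records[[i]] <- ecg_record(bt$signal, CANONICAL_LEADS, config$fs,
                               age = ages[i], sex = sexes[i],
                               label = labels[i], source = "synthetic",
                               truth = bt$truth,
                               id = sprintf("syn%05d", i))
  }
  manifest <- data.frame(id = vapply(records, `[[`, "", "id"),
                         label = labels, age = ages, sex = sexes,
                         source = "synthetic", seed = config$seed,
                         stringsAsFactors = FALSE)
  list(records = records, manifest = manifest)
}
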