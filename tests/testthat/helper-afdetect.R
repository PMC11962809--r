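# Shared fixtures and independent oracles for the afdetect test suite.
# Oracles are deliberately written as naive loops so they share no code
# path with the package implementations they check.

# Noise-free generator settings.
clean_config <- function(...) {
  synth_config(noise_sd = 0, baseline_wander_amp = 0, ...)
}

# Independent naive-loop HRV oracle over an NN interval vector (ms),
# population-SD convention, strict pNN inequalities, median-NN HR MAD.
naive_hrv <- function(x) {
  n <- length(x)
  s <- 0
  for (v in x) s <- s + v
  ibi <- s / n
  ss <- 0
  for (v in x) ss <- ss + (v - ibi)^2
  sdnn <- sqrt(ss / n)
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) d[i] <- x[i + 1] - x[i]
  dm <- 0
  for (v in d) dm <- dm + v
  dm <- dm / length(d)
  sv <- 0
  for (v in d) sv <- sv + (v - dm)^2
  sdsd <- sqrt(sv / length(d))
  r2 <- 0
  for (v in d) r2 <- r2 + v^2
  rmssd <- sqrt(r2 / length(d))
  c20 <- 0
  c50 <- 0
  for (v in d) {
    if (abs(v) > 20) c20 <- c20 + 1
    if (abs(v) > 50) c50 <- c50 + 1
  }
  med <- function(v) {
    v <- sort(v)
    m <- length(v)
    if (m %% 2 == 1) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
  }
  mnn <- med(x)
  ad <- numeric(n)
  for (i in seq_len(n)) ad[i] <- abs(x[i] - mnn)
  list(heart_rate = 60000 / ibi, ibi = ibi, sdnn = sdnn, sdsd = sdsd,
       rmssd = rmssd, pnn20 = 100 * c20 / length(d),
       pnn50 = 100 * c50 / length(d), hr_mad = med(ad))
}

# Wrap an arbitrary NN vector as an nn_series without passing the filter
# (the oracle tests feature computation, not filtering).
as_nn_series <- function(x, lead = "II") {
  structure(list(intervals = x, lead = lead, n_rejected = 0L,
                 valid = length(x) >= 3),
            class = "nn_series")
}

# Brute-force all-pairs concordance AUROC (ties count one half).
brute_auroc <- function(y, p) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# R-peak recall/precision against generator truth at +/- tol_samples.
peak_scores <- function(detected, truth, tol_samples = 25L) {
  hit <- if (length(detected)) {
    vapply(detected, function(p) any(abs(truth - p) <= tol_samples),
           logical(1))
  } else logical(0)
  matched <- vapply(truth, function(t) {
    length(detected) > 0 && any(abs(detected - t) <= tol_samples)
  }, logical(1))
  c(recall = mean(matched),
    precision = if (length(hit)) mean(hit) else 0)
}

# A linearly separable toy cohort: the positive class is an
# amplitude-scaled sinusoid, the negative class a faint one.
make_toy_records <- function(n = 60, seed = 5) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pos <- i %% 2 == 0
    tt <- (0:4999) / 500
    sig <- matrix(rep((if (pos) 1 else 0.1) * sin(2 * pi * 1.3 * tt), 8),
                  8, byrow = TRUE) +
      matrix(rnorm(8 * 5000, 0, 0.05), 8)
    ecg_record(sig, c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6"), 500,
               age = 50 + i, sex = if (i %% 3 == 0) "female" else "male",
               label = if (pos) "AF_positive" else "negative",
               id = sprintf("toy%03d", i))
  })
}

# One small trained multimodal bundle shared by the stack/interpret tests;
# built once per test run.
.fixture_env <- new.env(parent = emptyenv())

tiny_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    cfg <- synth_config(n_records = 120, prevalence = 0.3, seed = 4242)
    cohort <- generate_cohort(cfg)
    hrv <- hrv_feature_table(cohort$records)
    data <- assemble_modality_data(cohort$records, "ecg_demo_hrv", hrv)
    split <- split_dataset(data$y, 7L, 5L)
    tc <- train_config("ecg_demo_hrv", use_class_weights = TRUE,
                       epochs = 3, batch_size = 16, split_seed = 7L)
    set.seed(8L)
    net <- build_multimodal(backbone_spec("lenet1d"), ncol(data$tab))
    set.seed(9L)
    bundle <- train_network(net, data,
                            setdiff(split$train_idx, split$folds[[1]]),
                            split$folds[[1]], tc)
    .fixture_env$fx <- list(cohort = cohort, hrv = hrv, data = data,
                            split = split, bundle = bundle)
  }
  .fixture_env$fx
}
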