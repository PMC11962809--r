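#' Per-lead heart rate from beat annotations
#'
#' Heart rate for each reliable lead is `60000 / mean(RR)` with RR in ms.
#' Leads flagged unreliable by the detector are omitted. When no lead is
#' reliable the record's heart rate is undeterminable and an empty map is
#' returned with attribute `hr_undeterminable = TRUE`.
#'
#' @param annotations a `beat_annotations` object from [annotate_beats()].
#' @return named numeric vector of per-lead heart rates (bpm).
#' @export
per_lead_heart_rate <- function(annotations) {
  stopifnot(inherits(annotations, "beat_annotations"))
  fs <- annotations$fs
  ok <- names(which(annotations$per_lead_quality == "ok"))
  hr <- numeric(0)
  for (l in ok) {
    r <- annotations$per_lead_r_samples[[l]]
    if (length(r) < 2) next
    rr_ms <- diff(r) / fs * 1000
    hr[l] <- 60000 / mean(rr_ms)
  }
  if (!length(hr)) attr(hr, "hr_undeterminable") <- TRUE
  hr
}

#' Select the lead with the median heart rate
#'
#' For an odd number of leads this is the lead holding the sample median;
#' for an even number, the lead holding the lower of the two middle values.
#' Exact ties are broken by canonical lead order (I, II, V1-V6).
#'
#' @param hr_map named numeric vector of per-lead heart rates (bpm).
#' @return the selected lead label.
#' @export
select_median_lead <- function(hr_map) {
  if (!length(hr_map)) stop("empty heart-rate map", call. = FALSE)
  ord <- order(match(names(hr_map), CANONICAL_LEADS))
  hr <- hr_map[ord] # canonical order so equal-value ties resolve to I first
  k <- (length(hr) + 1L) %/% 2L # lower middle for even counts
  med <- sort(hr)[k]
  names(hr)[which(hr == med)[1L]]
}

#' Clean a raw RR series into NN intervals
#'
#' Removes intervals outside \[300, 2000\] ms and intervals deviating more
#' than `max_rel_dev` (default 30%) from the running median of the previous
#' 5 accepted intervals (applied once at least 5 intervals have been
#' accepted).
#'
#' @param raw_rr numeric vector of RR intervals (ms).
#' @param lead lead label recorded for provenance.
#' @param bounds absolute acceptance bounds in ms.
#' @param max_rel_dev maximal relative deviation from the running median.
#' @return object of class `nn_series`: `intervals`, `lead`, `n_rejected`,
#'   `valid` (FALSE when fewer than 3 intervals survive).
#' @export
filter_nn_intervals <- function(raw_rr, lead = NA_character_,
                                bounds = c(300, 2000), max_rel_dev = 0.3) {
  if (length(raw_rr) < 2)
    stop("need at least 2 raw intervals", call. = FALSE)
  accepted <- numeric(0)
  n_rejected <- 0L
  for (x in raw_rr) {
    drop <- x < bounds[1] || x > bounds[2]
    if (!drop && length(accepted) >= 5) {
      m <- median(utils::tail(accepted, 5))
      drop <- abs(x - m) / m > max_rel_dev
    }
    if (drop) n_rejected <- n_rejected + 1L else accepted <- c(accepted, x)
  }
  structure(list(intervals = accepted, lead = lead, n_rejected = n_rejected,
                 valid = length(accepted) >= 3),
            class = "nn_series")
}

#' Time-domain HRV features from an NN series
#'
#' Computes the 8-feature vector: heart rate (bpm), mean inter-beat
#' interval (ms), SDNN, SDSD, RMSSD (ms), pNN20 and pNN50 (%, strict
#' inequalities), and HR MAD. Standard deviations use the population
#' (1/N) convention by default (`sd_mode = "population"`), under which
#' `rmssd^2 = sdsd^2 + mean(d)^2` holds exactly. HR MAD is by default the
#' median absolute deviation of the NN intervals around their median
#' (`hr_mad_mode = "median_nn"`); `"mean_nn"` gives the mean absolute
#' deviation of NN around the mean, and `"mean_hr"` the mean absolute
#' deviation of the per-beat heart rates (bpm).
#'
#' @param nn an `nn_series` from [filter_nn_intervals()].
#' @param sd_mode `"population"` or `"sample"`.
#' @param hr_mad_mode `"median_nn"`, `"mean_nn"` or `"mean_hr"`.
#' @return object of class `hrv_features` (a named list; `valid = FALSE`
#'   with absent features when the series is invalid).
#' @export
compute_hrv_features <- function(nn, sd_mode = c("population", "sample"),
                                 hr_mad_mode = c("median_nn", "mean_nn",
                                                 "mean_hr")) {
  stopifnot(inherits(nn, "nn_series"))
  sd_mode <- match.arg(sd_mode)
  hr_mad_mode <- match.arg(hr_mad_mode)
  if (!nn$valid) {
    return(structure(list(valid = FALSE, lead = nn$lead,
                          n_beats = length(nn$intervals)),
                     class = "hrv_features"))
  }
  x <- nn$intervals
  n <- length(x)
  sdfun <- if (sd_mode == "population") {
    function(v) sqrt(mean((v - mean(v))^2))
  } else {
    function(v) sd(v)
  }
  d <- diff(x)
  ibi <- mean(x)
  hr_mad <- switch(hr_mad_mode,
                   median_nn = median(abs(x - median(x))),
                   mean_nn = mean(abs(x - mean(x))),
                   mean_hr = { h <- 60000 / x; mean(abs(h - mean(h))) })
  structure(list(heart_rate = 60000 / ibi,
                 ibi = ibi,
                 sdnn = sdfun(x),
                 sdsd = sdfun(d),
                 rmssd = sqrt(mean(d^2)),
                 pnn20 = 100 * sum(abs(d) > 20) / length(d),
                 pnn50 = 100 * sum(abs(d) > 50) / length(d),
                 hr_mad = hr_mad,
                 lead = nn$lead,
                 n_beats = n + 1L,
                 valid = TRUE),
            class = "hrv_features")
}

#' @export
print.hrv_features <- function(x, ...) {
  if (!isTRUE(x$valid)) {
    cat(sprintf("<hrv_features: invalid (lead=%s, %d beats)>\n",
                x$lead, x$n_beats))
    return(invisible(x))
  }
  cat(sprintf("<hrv_features: lead %s, %d beats>\n", x$lead, x$n_beats))
  units <- c(heart_rate = "bpm", ibi = "ms", sdnn = "ms", sdsd = "ms",
             rmssd = "ms", pnn20 = "%", pnn50 = "%", hr_mad = "ms")
  for (nm in names(units)) {
    cat(sprintf("  %-10s %8.3f %s\n", nm, x[[nm]], units[[nm]]))
  }
  invisible(x)
}

HRV_FEATURE_NAMES <- c("heart_rate", "ibi", "sdnn", "sdsd", "rmssd",
                       "pnn20", "pnn50", "hr_mad")

#' Full HRV extraction for one record
#'
#' Runs per-lead beat detection, selects the median-heart-rate lead,
#' filters its RR series to NN intervals and computes the feature vector.
#'
#' @param record an [ecg_record()].
#' @param denoise apply wavelet denoising before detection.
#' @param ... passed to [compute_hrv_features()].
#' @return `hrv_features` object (invalid when no lead yields a reliable
#'   heart rate).
#' @export
extract_hrv <- function(record, denoise = TRUE, ...) {
  ann <- annotate_beats(record, denoise = denoise)
  hr <- per_lead_heart_rate(ann)
  if (!length(hr)) {
    return(structure(list(valid = FALSE, lead = NA_character_, n_beats = 0L),
                     class = "hrv_features"))
  }
  lead <- select_median_lead(hr)
  r <- ann$per_lead_r_samples[[lead]]
  rr_ms <- diff(r) / ann$fs * 1000
  nn <- filter_nn_intervals(rr_ms, lead = lead)
  compute_hrv_features(nn, ...)
}

#' Batch HRV feature table
#'
#' @param records list of [ecg_record()].
#' @param ... passed to [extract_hrv()].
#' @return data.frame: record_id, lead, the 8 features, valid. Invalid
#'   records carry `NA` features.
#' @export
hrv_feature_table <- function(records, ...) {
  rows <- lapply(records, function(rec) {
    f <- extract_hrv(rec, ...)
    vals <- if (isTRUE(f$valid)) {
      vapply(HRV_FEATURE_NAMES, function(nm) f[[nm]], numeric(1))
    } else {
      stats::setNames(rep(NA_real_, length(HRV_FEATURE_NAMES)),
                      HRV_FEATURE_NAMES)
    }
    c(list(record_id = rec$id, lead = if (is.null(f$lead)) NA_character_ else f$lead),
      as.list(vals), list(valid = isTRUE(f$valid)))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
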