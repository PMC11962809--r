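# db4 (8-tap Daubechies) scaling filter, orthonormal (sum of squares = 1).
DB4_H <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
           -0.027983769416984, -0.187034811718881, 0.030841381835987,
           0.032883011666983, -0.010597401784997)
DB4_G <- rev(DB4_H) * c(1, -1, 1, -1, 1, -1, 1, -1) # QMF highpass

#' Standardise a raw multi-lead ECG to the canonical 8 x 5000 form
#'
#' Retains leads I, II and V1-V6 in canonical order (the augmented and
#' derived limb leads III, aVR, aVL, aVF carry no independent information),
#' truncates signals longer than 5000 samples from the end, and rejects
#' records shorter than 10 s or sampled at anything other than 500 Hz.
#'
#' @param raw_signal numeric matrix `[n_leads x n_samples]`.
#' @param raw_lead_names lead labels matching the rows of `raw_signal`.
#' @param fs sampling rate in Hz; must be 500.
#' @return numeric matrix `[8 x 5000]` with canonical lead rownames.
#' @export
standardise_record <- function(raw_signal, raw_lead_names, fs) {
  stopifnot(is.matrix(raw_signal))
  if (fs != 500)
    stop("unsupported sampling rate: ", fs, " Hz (only 500 Hz handled)",
         call. = FALSE)
  nm <- toupper(trimws(raw_lead_names))
  missing <- setdiff(CANONICAL_LEADS, nm)
  if (length(missing))
    stop("missing retained lead(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  n_target <- 5000L
  if (ncol(raw_signal) < n_target)
    stop("record shorter than 5000 samples; excluded", call. = FALSE)
  out <- raw_signal[match(CANONICAL_LEADS, nm), seq_len(n_target), drop = FALSE]
  rownames(out) <- CANONICAL_LEADS
  out
}

# One periodised DWT analysis level (x must have even length) and its
# inverse (the transpose of the orthogonal analysis operator).
dwt_level <- function(x) .dwt_level_cpp(x, DB4_H, DB4_G)
idwt_level <- function(a, d) .idwt_level_cpp(a, d, DB4_H, DB4_G)

#' Wavelet denoising of one ECG lead
#'
#' Periodised db4 discrete wavelet decomposition (default 4 levels) with
#' soft thresholding of all detail coefficients at the universal threshold
#' `sigma * sqrt(2 log N)`, where `sigma` is estimated from the finest
#' detail level as `median(|d1|) / 0.6745`. The signal is symmetrically
#' padded to a multiple of `2^levels` and the pad removed after
#' reconstruction. Because the transform is orthonormal and thresholding
#' only shrinks coefficients, output energy never exceeds input energy
#' (up to the padding edges).
#'
#' @param lead_signal numeric vector, one lead in mV.
#' @param fs sampling rate (Hz); unused by the transform, kept for the
#'   module interface.
#' @param levels decomposition depth.
#' @return denoised signal, same length as the input.
#' @export
wavelet_denoise <- function(lead_signal, fs = 500, levels = 4L) {
  stopifnot(all(is.finite(lead_signal)))
  n <- length(lead_signal)
  block <- 2L^levels
  pad <- (block - n %% block) %% block
  x <- if (pad > 0) c(lead_signal, rev(lead_signal)[seq_len(pad)]) else lead_signal
  approx_x <- x
  details <- vector("list", levels)
  for (lv in seq_len(levels)) {
    dec <- dwt_level(approx_x)
    approx_x <- dec$a
    details[[lv]] <- dec$d
  }
  sigma <- median(abs(details[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  if (thr > 0) {
    details <- lapply(details, function(d) sign(d) * pmax(abs(d) - thr, 0))
  }
  for (lv in rev(seq_len(levels))) {
    approx_x <- idwt_level(approx_x, details[[lv]])
  }
  approx_x[seq_len(n)]
}

# Zero-phase band-pass via FFT with raised-cosine band edges.
fft_bandpass <- function(x, fs, f_lo = 5, f_hi = 15, roll = 2) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs) # two-sided
  mask <- rep(0, n)
  up <- freqs >= f_lo & freqs <= f_hi
  mask[up] <- 1
  lo_edge <- freqs >= f_lo - roll & freqs < f_lo
  mask[lo_edge] <- 0.5 * (1 + cos(pi * (f_lo - freqs[lo_edge]) / roll))
  hi_edge <- freqs > f_hi & freqs <= f_hi + roll
  mask[hi_edge] <- 0.5 * (1 + cos(pi * (freqs[hi_edge] - f_hi) / roll))
  Re(fft(fft(x) * mask, inverse = TRUE)) / n
}

# Centered moving average by cumulative sums (O(n)).
moving_average <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect R peaks in one lead (derivative-energy detector)
#'
#' Pan-Tompkins-style pipeline: zero-phase band-pass (5-15 Hz),
#' differentiation, squaring, 150 ms moving-window integration, adaptive
#' signal/noise threshold tracking over local maxima with a 200 ms
#' refractory period, then refinement of each detection to the local
#' extremum of the band-passed signal. A lead is flagged `unreliable` when
#' fewer than 4 peaks are found or the implied heart rate falls outside
#' 20-300 bpm.
#'
#' @param lead_signal numeric vector (one denoised lead, mV).
#' @param fs sampling rate (Hz).
#' @return list with `r_samples` (1-based sample indices, strictly
#'   increasing, >= 200 ms apart) and `quality` (`"ok"` or `"unreliable"`).
#' @export
detect_r_peaks <- function(lead_signal, fs = 500) {
  n <- length(lead_signal)
  unreliable <- list(r_samples = integer(0), quality = "unreliable")
  if (n < fs || sd(lead_signal) < 1e-12) return(unreliable)

  bp <- fft_bandpass(lead_signal, fs)
  if (!all(is.finite(bp))) return(unreliable)

  der <- c(0, diff(bp))
  sq <- der^2
  w <- max(3L, as.integer(round(0.15 * fs)))
  integ <- moving_average(sq, w)

  # local maxima of the integrated energy
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  cand <- cand[integ[cand] > 0]
  if (length(cand) < 1) return(unreliable)

  refractory <- as.integer(round(0.2 * fs))
  init <- integ[seq_len(min(n, 2L * fs))]
  spki <- 0.6 * max(init)
  npki <- mean(init) * 0.5
  accepted <- integer(0)
  for (c0 in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[c0] > thr) {
      if (length(accepted) && c0 - accepted[length(accepted)] < refractory) {
        if (integ[c0] > integ[accepted[length(accepted)]]) {
          accepted[length(accepted)] <- c0
        }
      } else {
        accepted <- c(accepted, c0)
      }
      spki <- 0.125 * integ[c0] + 0.875 * spki
    } else {
      npki <- 0.125 * integ[c0] + 0.875 * npki
    }
  }
  if (length(accepted) < 2) return(unreliable)

  # refine to the band-passed extremum near each energy peak
  hw <- as.integer(round(0.1 * fs))
  refined <- vapply(accepted, function(c0) {
    lo <- max(1L, c0 - hw); hi <- min(n, c0 + hw)
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory after refinement, keeping the stronger peak
  r <- integer(0)
  for (p in refined) {
    if (!length(r) || p - r[length(r)] >= refractory) {
      r <- c(r, p)
    } else if (abs(bp[p]) > abs(bp[r[length(r)]])) {
      r[length(r)] <- p
    }
  }

  quality <- "ok"
  if (length(r) < 4) quality <- "unreliable"
  else {
    hr <- 60000 / mean(diff(r) / fs * 1000)
    if (hr < 20 || hr > 300) quality <- "unreliable"
  }
  list(r_samples = as.integer(r), quality = quality)
}

#' Per-lead beat annotation for a record
#'
#' Applies [wavelet_denoise()] then [detect_r_peaks()] to every lead.
#'
#' @param record an [ecg_record()].
#' @param denoise logical; apply wavelet denoising before detection.
#' @return object of class `beat_annotations`: per-lead R-sample lists,
#'   per-lead quality flags, and `fs`.
#' @export
annotate_beats <- function(record, denoise = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  leads <- record$lead_names
  r <- vector("list", length(leads)); names(r) <- leads
  q <- character(length(leads)); names(q) <- leads
  for (l in leads) {
    x <- record$signal[l, ]
    if (denoise) x <- wavelet_denoise(x, record$fs)
    det <- detect_r_peaks(x, record$fs)
    r[[l]] <- det$r_samples
    q[[l]] <- det$quality
  }
  structure(list(per_lead_r_samples = r, per_lead_quality = q,
                 fs = record$fs),
            class = "beat_annotations")
}
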