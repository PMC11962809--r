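#' Gradient saliency map for one record
#'
#' Absolute gradient of the positive-class pre-sigmoid output (the logit)
#' with respect to every input sample, optionally smoothed along time with
#' a moving average (default 20 ms window), then normalised by the map
#' maximum. Deterministic in inference mode. A dead model (all-zero
#' gradient) yields a map of zeros with a warning.
#'
#' @param bundle trained `model_bundle`.
#' @param record an [ecg_record()] (already standardised).
#' @param tab_row optional 1-row tabular matrix for multimodal bundles
#'   (raw scale; the bundle's scaler is applied).
#' @param smooth_ms moving-average window in ms (0 disables smoothing).
#' @return object of class `saliency_map`: `values` (matrix `[8 x 5000]`
#'   in `[0, 1]`), `record_id`, `model_tag`, `target_class`.
#' @export
saliency <- function(bundle, record, tab_row = NULL, smooth_ms = 20) {
  stopifnot(inherits(bundle, "model_bundle"), inherits(record, "ecg_record"))
  x <- array(record$signal, dim = c(dim(record$signal), 1L))
  tab_t <- NULL
  if (!is.null(bundle$net$tab_layers)) {
    if (is.null(tab_row))
      stop("multimodal bundle needs the record's tabular inputs", call. = FALSE)
    tab_t <- t(apply_scaler(tab_row, bundle$tabular_scaler))
  }
  fw <- net_forward(bundle$net, x, tab_t, keep_cache = TRUE)
  grads <- new.env(parent = emptyenv())
  dx <- net_backward(bundle$net, fw$cache, matrix(1, 1L, 1L), grads,
                     need_dx = TRUE)
  g <- abs(matrix(dx, nrow(record$signal), ncol(record$signal)))
  if (smooth_ms > 0) {
    w <- max(1L, as.integer(round(smooth_ms / 1000 * record$fs)))
    if (w > 1L) {
      for (l in seq_len(nrow(g))) g[l, ] <- moving_average(g[l, ], w)
    }
  }
  mx <- max(g)
  if (mx <= 0) {
    warning("all-zero gradient: dead model, returning a zero map")
  } else {
    g <- g / mx
  }
  rownames(g) <- record$lead_names
  structure(list(values = g, record_id = record$id,
                 model_tag = bundle$spec$name,
                 target_class = "AF_positive"),
            class = "saliency_map")
}

#' Export a per-lead saliency overlay
#'
#' Writes a CSV of `(sample, signal, saliency)` for the chosen lead
#' (default V6, the left-lateral precordial lead with the clearest view of
#' left-atrial activity) and, optionally, a PNG of the signal trace with a
#' saliency heat underlay.
#'
#' @param map a `saliency_map` from [saliency()].
#' @param record the matching [ecg_record()].
#' @param lead lead label.
#' @param csv_path output CSV path (`NULL` skips).
#' @param png_path output PNG path (`NULL` skips).
#' @return the overlay data.frame, invisibly.
#' @export
export_saliency_plot <- function(map, record, lead = "V6",
                                 csv_path = NULL, png_path = NULL) {
  stopifnot(inherits(map, "saliency_map"))
  if (!lead %in% record$lead_names)
    stop("unknown lead: ", lead, call. = FALSE)
  sig <- record$signal[lead, ]
  sal <- map$values[lead, ]
  df <- data.frame(sample = seq_along(sig), signal = sig, saliency = sal)
  if (!is.null(csv_path)) write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 1400, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    cols <- grDevices::hcl.colors(100, "YlOrRd", rev = TRUE)
    idx <- pmin(100L, pmax(1L, as.integer(sal * 99) + 1L))
    plot(df$sample, df$signal, type = "n",
         xlab = "sample", ylab = paste0(lead, " (mV)"),
         main = sprintf("%s saliency, record %s", map$model_tag,
                        map$record_id))
    graphics::segments(df$sample[-1], min(sig), df$sample[-1], max(sig),
                       col = grDevices::adjustcolor(cols[idx[-1]], 0.25))
    graphics::lines(df$sample, df$signal, col = "black")
  }
  invisible(df)
}
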