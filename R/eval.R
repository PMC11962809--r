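#' Confusion-matrix point metrics at a threshold
#'
#' Sensitivity, specificity, PPV, NPV and F1 from hard calls at
#' `threshold`. Metrics with a zero denominator are reported as `NA`
#' (absent), never as zero.
#'
#' @param labels 0/1 or `"AF_positive"`/`"negative"` vector.
#' @param probabilities predicted positive-class probabilities.
#' @param threshold decision cut-off.
#' @return named list: tp, fn, tn, fp, sensitivity, specificity, ppv, npv,
#'   f_score.
#' @export
confusion_metrics <- function(labels, probabilities, threshold = 0.5) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  stopifnot(length(y) == length(probabilities))
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  f <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_
       else 2 * ppv * sens / (ppv + sens)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
       f_score = f)
}

#' Rank-based AUROC (Mann-Whitney statistic)
#'
#' Area under the ROC curve computed from midranks; tied
#' positive/negative score pairs count one half. Equals the probability
#' that a random positive outscores a random negative.
#'
#' @inheritParams confusion_metrics
#' @return area in `[0, 1]`.
#' @export
auroc <- function(labels, probabilities) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  r <- rank(probabilities) # midranks handle ties as 1/2
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples positives and negatives separately (preserving class counts),
#' recomputes `metric_fn(labels, probabilities)` on each resample, and
#' returns the 2.5/97.5 percentile interval. When the metric is undefined
#' (`NA`) on more than half of the resamples the interval is absent, with
#' a warning.
#'
#' @inheritParams confusion_metrics
#' @param metric_fn function `(labels, probabilities) -> scalar`.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @param level confidence level.
#' @return numeric `c(ci_low, ci_high)` (possibly `NA`).
#' @export
bootstrap_ci <- function(labels, probabilities, metric_fn, n_boot = 2000L,
                         seed = 1L, level = 0.95) {
  stopifnot(n_boot >= 100)
  y <- as_binary_labels(labels)
  pos <- which(y == 1); neg <- which(y == 0)
  set.seed(seed)
  vals <- vapply(seq_len(n_boot), function(i) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    tryCatch(metric_fn(y[idx], probabilities[idx]),
             error = function(e) NA_real_)
  }, numeric(1))
  if (mean(is.na(vals)) > 0.5) {
    warning("metric undefined on more than half of the resamples; CI absent")
    return(c(NA_real_, NA_real_))
  }
  alpha <- (1 - level) / 2
  unname(quantile(vals, c(alpha, 1 - alpha), na.rm = TRUE, type = 7))
}

#' Full metrics report for one model/modality/source cell
#'
#' Point metrics plus AUROC, each with a stratified bootstrap 95% CI.
#'
#' @inheritParams confusion_metrics
#' @param n_boot,ci_seed bootstrap settings (see [bootstrap_ci()]).
#' @param model_tag,modality_tag,source_tag report labels.
#' @return object of class `metrics_report` (named list; each metric a
#'   `(point, ci_low, ci_high)` triple).
#' @export
metrics_report <- function(labels, probabilities, threshold = 0.5,
                           n_boot = 500L, ci_seed = 1L,
                           model_tag = "model", modality_tag = "ecg",
                           source_tag = "synthetic") {
  y <- as_binary_labels(labels)
  cm <- confusion_metrics(y, probabilities, threshold)
  out <- list()
  mk <- function(point, fn) {
    ci <- if (is.na(point)) c(NA_real_, NA_real_)
          else bootstrap_ci(y, probabilities, fn, n_boot = n_boot,
                            seed = ci_seed)
    c(point = point, ci_low = ci[1], ci_high = ci[2])
  }
  for (m in c("sensitivity", "specificity", "ppv", "npv", "f_score")) {
    fn <- local({
      mm <- m
      function(l, p) confusion_metrics(l, p, threshold)[[mm]]
    })
    out[[m]] <- mk(cm[[m]], fn)
  }
  out$auroc <- mk(auroc(y, probabilities), auroc)
  structure(c(out, list(n_pos = sum(y == 1), n_neg = sum(y == 0),
                        threshold = threshold, model_tag = model_tag,
                        modality_tag = modality_tag,
                        source_tag = source_tag)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: %s / %s / %s>\n",
              x$model_tag, x$modality_tag, x$source_tag))
  cat(sprintf("  test set: %d positive, %d negative (threshold %.2f)\n",
              x$n_pos, x$n_neg, x$threshold))
  for (nm in c("sensitivity", "specificity", "ppv", "npv", "f_score",
               "auroc")) {
    v <- x[[nm]]
    cat(sprintf("  %-12s %6.4f  [%.4f, %.4f]\n",
                nm, v["point"], v["ci_low"], v["ci_high"]))
  }
  invisible(x)
}

#' ROC curve coordinates
#'
#' Stepwise ROC points from the sorted unique score thresholds, beginning
#' at (0, 0) and ending at (1, 1).
#'
#' @inheritParams confusion_metrics
#' @return data.frame with `fpr` and `tpr`.
#' @export
roc_coordinates <- function(labels, probabilities) {
  y <- as_binary_labels(labels)
  ord <- order(probabilities, decreasing = TRUE)
  y <- y[ord]; p <- probabilities[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- c(diff(p) != 0, TRUE) # one point per distinct threshold
  data.frame(fpr = c(0, fp[last] / sum(y == 0)),
             tpr = c(0, tp[last] / sum(y == 1)))
}

report_row <- function(rep) {
  stopifnot(inherits(rep, "metrics_report"))
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "f_score", "auroc")
  do.call(rbind, lapply(metrics, function(m) {
    data.frame(model = rep$model_tag, modality = rep$modality_tag,
               source = rep$source_tag, metric = m,
               point = unname(rep[[m]]["point"]),
               ci_low = unname(rep[[m]]["ci_low"]),
               ci_high = unname(rep[[m]]["ci_high"]),
               n_pos = rep$n_pos, n_neg = rep$n_neg,
               stringsAsFactors = FALSE)
  }))
}

#' Tabulate and export a grid of metrics reports
#'
#' Flattens a list of `metrics_report` objects into a long data.frame (one
#' row per model/modality/source/metric) and optionally writes CSV and
#' JSON versions plus per-report ROC coordinates.
#'
#' @param reports list of `metrics_report` objects.
#' @param roc_data optional named list of [roc_coordinates()] frames.
#' @param output_dir directory to write `report.csv`, `report.json` and
#'   `roc_<name>.csv`; `NULL` skips writing.
#' @return the long data.frame, invisibly when writing.
#' @export
export_report <- function(reports, roc_data = NULL, output_dir = NULL) {
  tab <- do.call(rbind, lapply(reports, report_row))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(output_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(list(schema = "afdetect-report-v1", rows = tab),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    for (nm in names(roc_data)) {
      write.csv(roc_data[[nm]],
                file.path(output_dir, paste0("roc_", nm, ".csv")),
                row.names = FALSE)
    }
    return(invisible(tab))
  }
  tab
}
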