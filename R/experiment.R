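#' Experiment configuration for the full analysis grid
#'
#' Describes one reproducible experiment: a cohort source (a
#' [synth_config()] or a WFDB directory), the backbones, the modality and
#' class-weighting grid, and the shared training settings. All randomness
#' in the run flows from `seed`.
#'
#' @param cohort a [synth_config()] or a path to a WFDB directory.
#' @param backbones list of [backbone_spec()].
#' @param modalities character vector of modalities (see [train_config()]).
#' @param use_class_weights logical vector (grid axis).
#' @param epochs,batch_size,lr_init,lr_factor,lr_patience,early_stop_patience,n_folds
#'   shared training settings (see [train_config()]).
#' @param seed master seed (splits, init, shuffling, bootstrap).
#' @param output_dir where results are written.
#' @param n_boot bootstrap resamples per metric CI.
#' @param label_table optional diagnostic-code table for WFDB input.
#' @param stack run the boosted-tree stacking stage on the first backbone.
#' @param verbose log progress lines.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(cohort,
                              backbones = list(backbone_spec("alexnet1d")),
                              modalities = c("ecg", "ecg_demo_hrv"),
                              use_class_weights = TRUE,
                              epochs = 6L, batch_size = 64L, lr_init = 1e-3,
                              lr_factor = 0.5, lr_patience = 2L,
                              early_stop_patience = 5L, n_folds = 5L,
                              seed = 1L, output_dir = tempfile("afexp"),
                              n_boot = 200L, label_table = NULL,
                              stack = FALSE, verbose = TRUE) {
  stopifnot(length(backbones) >= 1, length(modalities) >= 1)
  structure(list(cohort = cohort, backbones = backbones,
                 modalities = modalities,
                 use_class_weights = use_class_weights,
                 epochs = epochs, batch_size = batch_size, lr_init = lr_init,
                 lr_factor = lr_factor, lr_patience = lr_patience,
                 early_stop_patience = early_stop_patience, n_folds = n_folds,
                 seed = as.integer(seed), output_dir = output_dir,
                 n_boot = n_boot, label_table = label_table, stack = stack,
                 verbose = verbose),
            class = "experiment_config")
}

#' Save / load a trained model bundle
#'
#' The weights go to an RDS file; a JSON sidecar records the backbone spec,
#' modality, scaler, threshold and training log for inspection without
#' deserialising the weights.
#'
#' @param bundle a `model_bundle`.
#' @param dir target directory (created).
#' @return `save_bundle`: the directory, invisibly. `load_bundle`: the
#'   bundle.
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(bundle, file.path(dir, "bundle.rds"))
  sidecar <- list(schema = "afdetect-bundle-v1",
                  spec = unclass(bundle$spec), modality = bundle$modality,
                  threshold = bundle$threshold,
                  tabular_scaler = bundle$tabular_scaler,
                  training_log = bundle$training_log)
  jsonlite::write_json(sidecar, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_bundle
#' @param dir directory written by `save_bundle`.
#' @export
load_bundle <- function(dir) readRDS(file.path(dir, "bundle.rds"))

exp_log <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf("[afdetect] %s", sprintf(...)))
}

cell_tag <- function(bk, mod, wt) {
  sprintf("%s__%s__%s", bk, mod, if (wt) "weighted" else "unweighted")
}

#' Run the full experiment grid
#'
#' For every backbone x modality x class-weighting cell: trains a model,
#' evaluates it on the shared held-out test set (metrics + bootstrap CIs),
#' and exports a saliency overlay for one positive and one negative test
#' record. Completed cells (their `report.json` already present in
#' `output_dir`) are skipped on re-runs, so an interrupted grid can be
#' resumed. Writes a top-level `summary.json`; re-running the identical
#' configuration into a fresh directory reproduces it bit-for-bit.
#'
#' @param cfg an [experiment_config()].
#' @return the summary list, invisibly; side effects under
#'   `cfg$output_dir`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  exp_log(cfg, "loading cohort (seed %d)", cfg$seed)
  if (inherits(cfg$cohort, "synth_config")) {
    cohort <- generate_cohort(cfg$cohort)
    records <- cohort$records
  } else {
    records <- read_wfdb_cohort(cfg$cohort, cfg$label_table)
    records <- lapply(records, function(r) {
      sig <- standardise_record(r$signal, r$lead_names, r$fs)
      ecg_record(sig, rownames(sig), r$fs, age = r$age, sex = r$sex,
                 label = r$label, source = r$source, id = r$id)
    })
  }
  labels <- vapply(records, `[[`, "", "label")
  exp_log(cfg, "%d records (%d positive)", length(records),
          sum(labels == "AF_positive"))

  needs_hrv <- any(grepl("hrv", cfg$modalities)) || isTRUE(cfg$stack)
  hrv_tab <- NULL
  if (needs_hrv) {
    exp_log(cfg, "extracting HRV features")
    hrv_tab <- hrv_feature_table(records)
    write.csv(hrv_tab, file.path(cfg$output_dir, "hrv_features.csv"),
              row.names = FALSE)
  }

  grid <- expand.grid(backbone = seq_along(cfg$backbones),
                      modality = cfg$modalities,
                      weighted = cfg$use_class_weights,
                      stringsAsFactors = FALSE)
  summary <- list(schema = "afdetect-summary-v1", seed = cfg$seed,
                  n_records = length(records),
                  n_positive = sum(labels == "AF_positive"),
                  cells = list())
  reports <- list()
  for (i in seq_len(nrow(grid))) {
    spec <- cfg$backbones[[grid$backbone[i]]]
    mod <- grid$modality[i]
    wt <- grid$weighted[i]
    tag <- cell_tag(spec$name, mod, wt)
    cell_dir <- file.path(cfg$output_dir, tag)
    done_file <- file.path(cell_dir, "report.json")
    if (file.exists(done_file)) {
      exp_log(cfg, "cell %s already complete; skipping", tag)
      summary$cells[[tag]] <- jsonlite::read_json(done_file,
                                                  simplifyVector = TRUE)
      next
    }
    exp_log(cfg, "training cell %s", tag)
    cell <- tryCatch({
      tc <- train_config(modality = mod, use_class_weights = wt,
                         epochs = cfg$epochs, batch_size = cfg$batch_size,
                         lr_init = cfg$lr_init, lr_factor = cfg$lr_factor,
                         lr_patience = cfg$lr_patience,
                         early_stop_patience = cfg$early_stop_patience,
                         split_seed = cfg$seed, n_folds = cfg$n_folds)
      tm <- train_model(records, spec, tc, hrv_table = hrv_tab)
      test_idx <- tm$split$test_idx
      p <- predict_bundle(tm$bundle, tm$data, test_idx)
      rep <- metrics_report(tm$data$y[test_idx], p,
                            threshold = tm$bundle$threshold,
                            n_boot = cfg$n_boot, ci_seed = cfg$seed,
                            model_tag = spec$name, modality_tag = mod,
                            source_tag = if (wt) "weighted" else "unweighted")
      dir.create(cell_dir, recursive = TRUE, showWarnings = FALSE)
      save_bundle(tm$bundle, file.path(cell_dir, "bundle"))
      roc <- roc_coordinates(tm$data$y[test_idx], p)
      write.csv(roc, file.path(cell_dir, "roc.csv"), row.names = FALSE)
      # saliency samples: first positive and first negative test record
      for (cls in c(1, 0)) {
        j <- test_idx[which(tm$data$y[test_idx] == cls)][1]
        if (is.na(j)) next
        rec <- records[[tm$data$kept[j]]]
        tab_row <- if (!is.null(tm$data$tab))
          tm$data$tab[j, , drop = FALSE] else NULL
        sm <- saliency(tm$bundle, rec, tab_row)
        export_saliency_plot(sm, rec,
                             csv_path = file.path(cell_dir,
                                                  sprintf("saliency_%s.csv",
                                                          rec$label)))
      }
      cell_summary <- list(
        tag = tag, backbone = spec$name, modality = mod, weighted = wt,
        n_test = length(test_idx),
        n_test_pos = sum(tm$data$y[test_idx] == 1),
        epochs_run = nrow(tm$bundle$training_log),
        metrics = lapply(rep[c("sensitivity", "specificity", "ppv", "npv",
                               "f_score", "auroc")], as.list))
      jsonlite::write_json(cell_summary, done_file, auto_unbox = TRUE,
                           digits = NA)
      reports[[tag]] <- rep
      cell_summary
    }, error = function(e) {
      exp_log(cfg, "cell %s FAILED: %s", tag, conditionMessage(e))
      list(tag = tag, error = conditionMessage(e))
    })
    summary$cells[[tag]] <- cell
  }

  if (isTRUE(cfg$stack)) {
    exp_log(cfg, "stacking: boosted trees on CNN embeddings")
    summary$stack <- tryCatch({
      spec <- cfg$backbones[[1]]
      tc <- train_config(modality = "ecg_demo_hrv",
                         use_class_weights = TRUE, epochs = cfg$epochs,
                         batch_size = cfg$batch_size, lr_init = cfg$lr_init,
                         split_seed = cfg$seed, n_folds = cfg$n_folds)
      # reuse the trained weighted multimodal cell when available
      tag <- cell_tag(spec$name, "ecg_demo_hrv", TRUE)
      data <- assemble_modality_data(records, "ecg_demo_hrv", hrv_tab)
      split <- split_dataset(data$y, cfg$seed, cfg$n_folds)
      bdir <- file.path(cfg$output_dir, tag, "bundle")
      bundle <- if (file.exists(file.path(bdir, "bundle.rds"))) {
        load_bundle(bdir)
      } else {
        set.seed(cfg$seed + 1L)
        net <- build_multimodal(spec, ncol(data$tab))
        set.seed(cfg$seed + 2L)
        train_network(net, data, setdiff(split$train_idx, split$folds[[1]]),
                      split$folds[[1]],
                      train_config(modality = "ecg_demo_hrv",
                                   epochs = cfg$epochs,
                                   split_seed = cfg$seed))
      }
      ev <- evaluate_modalities(bundle, data, split, seed = cfg$seed,
                                n_boot = cfg$n_boot)
      lapply(ev$reports, function(r) {
        lapply(r[c("sensitivity", "specificity", "f_score", "auroc")],
               as.list)
      })
    }, error = function(e) {
      exp_log(cfg, "stacking FAILED: %s", conditionMessage(e))
      list(error = conditionMessage(e))
    })
  }

  if (length(reports)) {
    export_report(reports, output_dir = cfg$output_dir)
  }
  jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  exp_log(cfg, "done: %s", file.path(cfg$output_dir, "summary.json"))
  invisible(summary)
}
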