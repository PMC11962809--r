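#' Extract CNN embeddings for a set of records
#'
#' Deterministic inference-mode pass through a trained bundle's signal
#' stream; the embedding is the output of the final (penultimate-to-head)
#' dense layer.
#'
#' @param bundle a trained `model_bundle`.
#' @param data modality data from [assemble_modality_data()] (the signal
#'   list is used; tabular inputs are not needed for the embedding).
#' @param idx optional row subset.
#' @return numeric matrix `[n x embedding_dim]`.
#' @export
extract_embeddings <- function(bundle, data, idx = NULL) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (is.null(idx)) idx <- seq_along(data$signals)
  emb <- matrix(0, length(idx), bundle$spec$embedding_dim)
  pos <- 1L
  for (b in split(idx, ceiling(seq_along(idx) / 64L))) {
    x <- batch_cube(data$signals, b)
    fw <- chain_forward(bundle$net$trunk, bundle$net$params, x,
                        keep_cache = FALSE)
    emb[pos:(pos + length(b) - 1L), ] <- t(fw$out)
    pos <- pos + length(b)
  }
  colnames(emb) <- sprintf("emb%03d", seq_len(ncol(emb)))
  emb
}

default_xgb_params <- function() {
  # xgboost-native sampling defaults: on very low-dimensional tables,
  # column subsampling below 1 can hide a feature from entire trees and
  # make interaction-only signals (e.g. XOR) unlearnable.
  list(max_depth = 4, eta = 0.1, subsample = 1, colsample_bytree = 1,
       min_child_weight = 1, nrounds = 200)
}

sample_xgb_params <- function() {
  list(max_depth = sample(2:8, 1),
       eta = exp(runif(1, log(0.02), log(0.3))),
       subsample = runif(1, 0.6, 1),
       colsample_bytree = runif(1, 0.5, 1),
       min_child_weight = sample(1:8, 1),
       nrounds = 400)
}

fit_xgb_once <- function(x_tr, y_tr, x_val, y_val, pars, spw, nthread = 1L) {
  dtr <- xgboost::xgb.DMatrix(x_tr, label = y_tr, nthread = nthread)
  dval <- xgboost::xgb.DMatrix(x_val, label = y_val, nthread = nthread)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", eval_metric = "logloss",
                  max_depth = pars$max_depth, eta = pars$eta,
                  subsample = pars$subsample,
                  colsample_bytree = pars$colsample_bytree,
                  min_child_weight = pars$min_child_weight,
                  scale_pos_weight = spw, nthread = nthread,
                  seed = 0),
    data = dtr, nrounds = pars$nrounds,
    evals = list(val = dval),
    early_stopping_rounds = 20, verbose = 0)
}

#' Fit a gradient-boosted tree classifier on stacked features
#'
#' Trains an XGBoost binary classifier with early stopping on a validation
#' split; hyperparameters (tree depth, learning rate, row/column
#' subsampling, minimum child weight) are chosen by seeded random search
#' over `search_budget` trials scored by validation log-loss. The
#' positive-class weight is set from the class ratio. A budget of 0 fits
#' documented defaults directly.
#'
#' @param features numeric matrix `[n x p]`.
#' @param labels 0/1 or label strings, length n.
#' @param train_idx,val_idx row splits (validation drives early stopping
#'   and the search).
#' @param search_budget number of random-search trials.
#' @param seed integer seed for the search.
#' @return object of class `stacked_model`: the xgboost booster, chosen
#'   hyperparameters, and the validation log-loss per trial.
#' @export
fit_boosted_classifier <- function(features, labels, train_idx, val_idx,
                                   search_budget = 25L, seed = 1L) {
  y <- as_binary_labels(labels)
  if (length(unique(y[train_idx])) < 2)
    stop("both classes must be present in the training rows", call. = FALSE)
  x_tr <- features[train_idx, , drop = FALSE]
  x_val <- features[val_idx, , drop = FALSE]
  y_tr <- y[train_idx]; y_val <- y[val_idx]
  spw <- sum(y_tr == 0) / sum(y_tr == 1)
  set.seed(seed)
  trials <- if (search_budget >= 1) {
    replicate(search_budget, sample_xgb_params(), simplify = FALSE)
  } else {
    list(default_xgb_params())
  }
  best <- NULL; best_loss <- Inf; losses <- numeric(length(trials))
  for (i in seq_along(trials)) {
    fit <- fit_xgb_once(x_tr, y_tr, x_val, y_val, trials[[i]], spw)
    vl <- as.numeric(xgboost::xgb.attributes(fit)$best_score)
    losses[i] <- vl
    if (vl < best_loss) {
      best_loss <- vl
      best <- list(model = fit, params = trials[[i]])
    }
  }
  structure(list(model = best$model, params = best$params,
                 val_logloss = best_loss, trial_losses = losses,
                 scale_pos_weight = spw),
            class = "stacked_model")
}

#' @export
predict.stacked_model <- function(object, newdata, ...) {
  predict(object$model, xgboost::xgb.DMatrix(newdata, nthread = 1L))
}

stack_feature_sets <- function() {
  list(embedding = character(0),
       embedding_demo = "demo",
       embedding_hrv = "hrv",
       embedding_demo_hrv = c("demo", "hrv"))
}

#' Evaluate stacked classifiers over a modality grid
#'
#' For each feature set (CNN embedding alone, +demographics, +HRV, +both)
#' fits a boosted classifier on the training rows (validation rows drive
#' early stopping / search) and evaluates it on the identical held-out test
#' rows. Test rows must be disjoint from training/validation rows; overlap
#' raises an error (leakage guard).
#'
#' @param bundle trained `model_bundle` supplying embeddings.
#' @param data modality data (must carry demo and/or HRV columns for the
#'   feature sets requested).
#' @param split list with `test_idx` and `folds`/`train_idx` as from
#'   [split_dataset()].
#' @param feature_sets character vector naming subsets of
#'   `c("embedding", "embedding_demo", "embedding_hrv",
#'   "embedding_demo_hrv")`.
#' @param search_budget,seed passed to [fit_boosted_classifier()].
#' @param n_boot bootstrap resamples per metric CI.
#' @return list: `reports` (one `metrics_report` per feature set),
#'   `models`, `probs` (per-set test probabilities).
#' @export
evaluate_modalities <- function(bundle, data, split,
                                feature_sets = names(stack_feature_sets()),
                                search_budget = 10L, seed = 1L,
                                n_boot = 200L) {
  sets <- stack_feature_sets()
  stopifnot(all(feature_sets %in% names(sets)))
  val_idx <- split$folds[[1]]
  train_idx <- setdiff(split$train_idx, val_idx)
  test_idx <- split$test_idx
  if (length(intersect(test_idx, c(train_idx, val_idx))))
    stop("leakage: test records appear in the training partition",
         call. = FALSE)
  emb <- extract_embeddings(bundle, data)
  blocks <- list()
  if (any(vapply(sets[feature_sets], function(s) "demo" %in% s, logical(1)))) {
    stopifnot(!is.null(data$tab), all(c("age", "sex") %in% colnames(data$tab)))
    blocks$demo <- data$tab[, c("age", "sex"), drop = FALSE]
  }
  if (any(vapply(sets[feature_sets], function(s) "hrv" %in% s, logical(1)))) {
    stopifnot(!is.null(data$tab),
              all(HRV_FEATURE_NAMES %in% colnames(data$tab)))
    blocks$hrv <- data$tab[, HRV_FEATURE_NAMES, drop = FALSE]
  }
  reports <- list(); models <- list(); probs <- list()
  for (fs in feature_sets) {
    x <- emb
    for (bk in sets[[fs]]) x <- cbind(x, blocks[[bk]])
    fit <- fit_boosted_classifier(x, data$y, train_idx, val_idx,
                                  search_budget = search_budget, seed = seed)
    p <- predict(fit, x[test_idx, , drop = FALSE])
    reports[[fs]] <- metrics_report(data$y[test_idx], p,
                                    threshold = bundle$threshold,
                                    n_boot = n_boot, ci_seed = seed,
                                    model_tag = paste0(bundle$spec$name,
                                                       "+xgb"),
                                    modality_tag = fs)
    models[[fs]] <- fit
    probs[[fs]] <- p
  }
  list(reports = reports, models = models, probs = probs)
}
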