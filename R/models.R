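#' Backbone specification
#'
#' Names a 1-D CNN backbone from the registry and its scaling knobs.
#' `width_multiplier` scales every convolutional channel count (floored at
#' 4 channels); the default 0.25 targets single-CPU training on cohorts of
#' a few thousand 10 s records.
#'
#' @param name one of `"lenet1d"`, `"alexnet1d"`, `"vgg1d"`.
#' @param width_multiplier positive channel-width factor.
#' @param embedding_dim size of the penultimate dense (embedding) layer.
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = c("lenet1d", "alexnet1d", "vgg1d"),
                          width_multiplier = 0.25, embedding_dim = 64L) {
  name <- match.arg(name)
  stopifnot(width_multiplier > 0, embedding_dim >= 8)
  structure(list(name = name, width_multiplier = width_multiplier,
                 embedding_dim = as.integer(embedding_dim)),
            class = "backbone_spec")
}

scale_ch <- function(base, w) pmax(4L, as.integer(round(base * w)))

# Registry of trunk topologies. Each entry returns list(layers, out_dim)
# for an 8-channel, 5000-sample input, ending at the flattened feature
# vector (before the embedding dense layer).
backbone_registry <- function() {
  list(
    # 2 conv-pool blocks + dense
    lenet1d = function(w, L = 5000L, ic = 8L) {
      c1 <- scale_ch(24, w); c2 <- scale_ch(48, w)
      layers <- list(conv_layer("c1", ic, c1, 25L, 5L), relu_layer(),
                     maxpool_layer(4L),
                     conv_layer("c2", c1, c2, 9L, 1L), relu_layer(),
                     maxpool_layer(4L))
      t1 <- conv_out_len(L, 25L, 5L) %/% 4L
      t2 <- conv_out_len(t1, 9L, 1L) %/% 4L
      list(layers = layers, out_dim = c2 * t2)
    },
    # 5 conv layers (3 pooled) + 2 dense (embedding dense + head)
    alexnet1d = function(w, L = 5000L, ic = 8L) {
      ch <- scale_ch(c(32, 64, 96, 64, 64), w)
      layers <- list(conv_layer("c1", ic, ch[1], 16L, 8L), relu_layer(),
                     maxpool_layer(2L),
                     conv_layer("c2", ch[1], ch[2], 9L, 1L), relu_layer(),
                     maxpool_layer(2L),
                     conv_layer("c3", ch[2], ch[3], 5L, 1L), relu_layer(),
                     conv_layer("c4", ch[3], ch[4], 5L, 1L), relu_layer(),
                     conv_layer("c5", ch[4], ch[5], 5L, 1L), relu_layer(),
                     maxpool_layer(2L))
      t <- conv_out_len(L, 16L, 8L) %/% 2L
      t <- conv_out_len(t, 9L, 1L) %/% 2L
      t <- conv_out_len(t, 5L, 1L)
      t <- conv_out_len(t, 5L, 1L)
      t <- conv_out_len(t, 5L, 1L) %/% 2L
      list(layers = layers, out_dim = ch[5] * t)
    },
    # 4 double-conv pooled blocks + 2 dense
    vgg1d = function(w, L = 5000L, ic = 8L) {
      ch <- scale_ch(c(16, 32, 48, 64), w)
      layers <- list()
      t <- L
      prev <- ic
      for (b in seq_len(4)) {
        stride1 <- if (b == 1L) 4L else 1L # early stride keeps compute sane
        layers <- c(layers,
                    list(conv_layer(sprintf("b%dc1", b), prev, ch[b], 9L, stride1),
                         relu_layer(),
                         conv_layer(sprintf("b%dc2", b), ch[b], ch[b], 9L, 1L),
                         relu_layer(), maxpool_layer(3L)))
        t <- conv_out_len(t, 9L, stride1)
        t <- conv_out_len(t, 9L, 1L) %/% 3L
        prev <- ch[b]
      }
      list(layers = layers, out_dim = prev * t)
    }
  )
}

init_chain_params <- function(params, layers) {
  for (ly in layers) {
    if (ly$type == "conv") {
      params <- new_param(params, ly$name, c(ly$oc, ly$ic * ly$k), ly$ic * ly$k)
    } else if (ly$type == "dense") {
      params <- new_param(params, ly$name, c(ly$n_out, ly$n_in), ly$n_in)
    }
  }
  params
}

#' Build an untrained ECG-only backbone network
#'
#' Maps an `[8 x 5000]` signal to an `embedding_dim` vector through the
#' convolutional trunk and a dense embedding layer (ReLU), followed by a
#' single dense sigmoid head producing the AF probability. Weight
#' initialisation draws from the current R RNG state; seed upstream for
#' reproducibility.
#'
#' @param spec a [backbone_spec()].
#' @param input_len signal length in samples.
#' @return object of class `cnn_net`.
#' @export
build_backbone <- function(spec, input_len = 5000L) {
  stopifnot(inherits(spec, "backbone_spec"))
  reg <- backbone_registry()
  topo <- reg[[spec$name]](spec$width_multiplier, input_len)
  trunk <- c(topo$layers, list(flatten_layer(),
                               dense_layer("embed", topo$out_dim,
                                           spec$embedding_dim),
                               relu_layer()))
  head <- list(dense_layer("out", spec$embedding_dim, 1L))
  params <- init_chain_params(list(), trunk)
  params <- init_chain_params(params, head)
  structure(list(spec = spec, trunk = trunk, head = head, tab_layers = NULL,
                 n_tabular = 0L, params = params, input_len = input_len),
            class = "cnn_net")
}

#' Build an untrained two-stream multimodal network
#'
#' The signal stream is the backbone up to its embedding; the tabular
#' stream (demographics and/or HRV features) passes through two small
#' dense+ReLU layers; the streams are concatenated and fused by a dense
#' layer before the sigmoid head.
#'
#' @inheritParams build_backbone
#' @param n_tabular_features number of tabular inputs (>= 1).
#' @param tab_width width of the tabular dense layers.
#' @param fuse_width width of the fusion dense layer.
#' @return object of class `cnn_net`.
#' @export
build_multimodal <- function(spec, n_tabular_features, input_len = 5000L,
                             tab_width = 16L, fuse_width = 32L) {
  if (n_tabular_features < 1)
    stop("multimodal network needs at least one tabular feature", call. = FALSE)
  net <- build_backbone(spec, input_len)
  net$tab_layers <- list(dense_layer("tab1", n_tabular_features, tab_width),
                         relu_layer(),
                         dense_layer("tab2", tab_width, tab_width),
                         relu_layer())
  net$head <- list(dense_layer("fuse", spec$embedding_dim + tab_width,
                               fuse_width),
                   relu_layer(),
                   dense_layer("out", fuse_width, 1L))
  net$n_tabular <- as.integer(n_tabular_features)
  params <- init_chain_params(list(), net$trunk)
  params <- init_chain_params(params, net$tab_layers)
  params <- init_chain_params(params, net$head)
  net$params <- params
  net
}

#' Balanced class weights
#'
#' `w_c = n_total / (2 * n_c)`, so that `w_pos * n_pos = w_neg * n_neg`.
#'
#' @param labels vector of `"AF_positive"` / `"negative"` (or 1/0).
#' @return named numeric vector `c(negative = ..., positive = ...)`.
#' @export
compute_class_weights <- function(labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute class weights", call. = FALSE)
  n <- n_pos + n_neg
  c(negative = n / (2 * n_neg), positive = n / (2 * n_pos))
}

as_binary_labels <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  as.integer(labels == "AF_positive")
}

#' Stratified train/test split plus cross-validation folds
#'
#' Holds out `test_fraction` of records (stratified by label), then
#' partitions the remainder into `n_folds` disjoint stratified folds.
#' Deterministic in `split_seed`.
#'
#' @param labels label vector for all records.
#' @param split_seed integer seed.
#' @param n_folds number of CV folds over the non-test records.
#' @param test_fraction held-out fraction.
#' @return list: `test_idx`, `train_idx` (all non-test), `folds` (list of
#'   validation index vectors partitioning `train_idx`).
#' @export
split_dataset <- function(labels, split_seed = 1L, n_folds = 5L,
                          test_fraction = 0.2) {
  y <- as_binary_labels(labels)
  if (sum(y == 1) < n_folds)
    stop("too few positive records for ", n_folds, "-fold stratification",
         call. = FALSE)
  set.seed(split_seed)
  test_idx <- integer(0)
  for (cls in c(0, 1)) {
    ids <- which(y == cls)
    n_t <- round(length(ids) * test_fraction)
    test_idx <- c(test_idx, sample(ids, n_t))
  }
  test_idx <- sort(test_idx)
  rest <- setdiff(seq_along(y), test_idx)
  folds <- vector("list", n_folds)
  for (cls in c(0, 1)) {
    ids <- sample(rest[y[rest] == cls])
    fold_of <- rep(seq_len(n_folds), length.out = length(ids))
    for (f in seq_len(n_folds)) {
      folds[[f]] <- c(folds[[f]], ids[fold_of == f])
    }
  }
  folds <- lapply(folds, sort)
  list(test_idx = test_idx, train_idx = sort(rest), folds = folds)
}

#' Training configuration
#'
#' @param modality one of `"ecg"`, `"ecg_demo"`, `"ecg_hrv"`,
#'   `"ecg_demo_hrv"`.
#' @param use_class_weights logical.
#' @param epochs maximal epochs.
#' @param batch_size minibatch size.
#' @param lr_init initial Adam learning rate.
#' @param lr_factor multiplicative learning-rate reduction on plateau.
#' @param lr_patience epochs of non-improving validation loss before the
#'   learning rate is reduced.
#' @param early_stop_patience epochs of non-improving validation loss
#'   before training halts (best weights restored).
#' @param split_seed seed for splits, weight init and batch shuffling.
#' @param n_folds number of CV folds.
#' @return object of class `train_config`.
#' @export
train_config <- function(modality = c("ecg", "ecg_demo", "ecg_hrv",
                                      "ecg_demo_hrv"),
                         use_class_weights = TRUE, epochs = 6L,
                         batch_size = 64L, lr_init = 1e-3, lr_factor = 0.5,
                         lr_patience = 2L, early_stop_patience = 5L,
                         split_seed = 1L, n_folds = 5L) {
  modality <- match.arg(modality)
  stopifnot(lr_factor > 0, lr_factor < 1, lr_patience >= 1,
            early_stop_patience >= 1, epochs >= 1, batch_size >= 1)
  structure(list(modality = modality, use_class_weights = use_class_weights,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 split_seed = as.integer(split_seed),
                 n_folds = as.integer(n_folds)),
            class = "train_config")
}

modality_uses_tabular <- function(modality) modality != "ecg"

# Pure plateau / early-stop bookkeeping shared by the training loop.
# state: list(lr, lr_wait, es_wait, stop); improved: did the validation
# loss improve this epoch. Kept free of side effects so the schedule
# contract is testable in isolation.
plateau_step <- function(state, improved, config) {
  if (improved) {
    state$lr_wait <- 0L
    state$es_wait <- 0L
  } else {
    state$lr_wait <- state$lr_wait + 1L
    state$es_wait <- state$es_wait + 1L
    if (state$lr_wait >= config$lr_patience) {
      state$lr <- state$lr * config$lr_factor
      state$lr_wait <- 0L
    }
    if (state$es_wait >= config$early_stop_patience) state$stop <- TRUE
  }
  state
}

#' Assemble modality inputs from records
#'
#' Builds the signal list, the tabular feature matrix demanded by the
#' modality (`demo` = age in years + sex coded 0/1; `hrv` = the 8-feature
#' vector from [hrv_feature_table()]), and 0/1 labels. Records missing a
#' required tabular block (no age/sex, or an invalid HRV extraction) are
#' excluded with a message.
#'
#' @param records list of [ecg_record()].
#' @param modality modality string as in [train_config()].
#' @param hrv_table optional precomputed [hrv_feature_table()] (computed on
#'   the fly when needed and absent).
#' @return list: `signals`, `tab` (matrix n x p or NULL), `y`, `ids`,
#'   `kept` (indices into `records`).
#' @export
assemble_modality_data <- function(records, modality, hrv_table = NULL) {
  n <- length(records)
  y <- vapply(records, function(r) as_binary_labels(r$label), integer(1))
  ids <- vapply(records, `[[`, "", "id")
  tab <- NULL
  kept <- seq_len(n)
  if (modality_uses_tabular(modality)) {
    blocks <- list()
    if (modality %in% c("ecg_demo", "ecg_demo_hrv")) {
      age <- vapply(records, function(r) as.numeric(r$age), numeric(1))
      sex01 <- vapply(records, function(r) {
        if (is.na(r$sex)) NA_real_ else as.numeric(r$sex == "male")
      }, numeric(1))
      blocks$demo <- cbind(age = age, sex = sex01)
    }
    if (modality %in% c("ecg_hrv", "ecg_demo_hrv")) {
      if (is.null(hrv_table)) hrv_table <- hrv_feature_table(records)
      ht <- hrv_table[match(ids, hrv_table$record_id), HRV_FEATURE_NAMES,
                      drop = FALSE]
      blocks$hrv <- as.matrix(ht)
    }
    tab <- do.call(cbind, blocks)
    ok <- rowSums(is.na(tab)) == 0
    if (any(!ok)) {
      message(sum(!ok), " record(s) excluded: missing ", modality,
              " tabular inputs")
      kept <- which(ok)
      tab <- tab[ok, , drop = FALSE]
      y <- y[ok]; ids <- ids[ok]
    }
  }
  list(signals = lapply(records[kept], `[[`, "signal"),
       tab = tab, y = y, ids = ids, kept = kept)
}

fit_scaler <- function(tab) {
  centre <- colMeans(tab)
  scale <- apply(tab, 2, sd)
  scale[scale < 1e-12] <- 1
  list(centre = centre, scale = scale)
}

apply_scaler <- function(tab, scaler) {
  t((t(tab) - scaler$centre) / scaler$scale)
}

net_forward_batched <- function(net, signals, tab_t, idx, batch_size = 64L) {
  logits <- numeric(length(idx))
  emb <- matrix(0, net$spec$embedding_dim, length(idx))
  pos <- 1L
  for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
    x <- batch_cube(signals, b)
    tb <- if (!is.null(tab_t)) tab_t[, b, drop = FALSE]
    fw <- net_forward(net, x, tb, keep_cache = FALSE)
    span <- pos:(pos + length(b) - 1L)
    logits[span] <- as.numeric(fw$logit)
    emb[, span] <- fw$embedding
    pos <- pos + length(b)
  }
  list(logit = logits, embedding = emb)
}

#' Train a network on one train/validation split
#'
#' Minibatch Adam on weighted binary cross-entropy. The validation loss is
#' monitored each epoch: the learning rate is multiplied by `lr_factor`
#' after `lr_patience` consecutive non-improving epochs, and training halts
#' after `early_stop_patience` non-improving epochs with the
#' best-validation-loss weights restored. The tabular scaler (z-score) is
#' fitted on the training partition only.
#'
#' @param net an untrained `cnn_net` (from [build_backbone()] or
#'   [build_multimodal()]).
#' @param data modality data from [assemble_modality_data()].
#' @param train_idx,val_idx index vectors into `data` rows.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return object of class `model_bundle`: trained `net`, `spec`,
#'   `modality`, `tabular_scaler`, `threshold` (0.5) and `training_log`
#'   (data.frame epoch/train_loss/val_loss/lr).
#' @export
train_network <- function(net, data, train_idx, val_idx, config,
                          verbose = FALSE) {
  stopifnot(inherits(net, "cnn_net"), inherits(config, "train_config"))
  y <- data$y
  if (length(unique(y[train_idx])) < 2)
    stop("training partition must contain both classes", call. = FALSE)
  cw <- if (config$use_class_weights) compute_class_weights(y[train_idx])
        else c(negative = 1, positive = 1)
  w_all <- ifelse(y == 1, cw["positive"], cw["negative"])

  scaler <- NULL
  tab_t <- NULL
  if (!is.null(net$tab_layers)) {
    stopifnot(!is.null(data$tab))
    scaler <- fit_scaler(data$tab[train_idx, , drop = FALSE])
    tab_t <- t(apply_scaler(data$tab, scaler)) # p x n
  }

  adam <- adam_init(net$params)
  sched <- list(lr = config$lr_init, lr_wait = 0L, es_wait = 0L,
                stop = FALSE)
  best_loss <- Inf
  best_params <- net$params
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), lr = numeric(0))

  val_loss_fn <- function() {
    fw <- net_forward_batched(net, data$signals, tab_t, val_idx)
    bce_loss(matrix(fw$logit, 1L), y[val_idx], w_all[val_idx])$loss
  }

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_loss <- 0
    for (b in batches) {
      x <- batch_cube(data$signals, b)
      tb <- if (!is.null(tab_t)) tab_t[, b, drop = FALSE]
      fw <- net_forward(net, x, tb, keep_cache = TRUE)
      ls <- bce_loss(fw$logit, y[b], w_all[b])
      if (!is.finite(ls$loss))
        stop("non-finite training loss at epoch ", epoch, call. = FALSE)
      grads <- new.env(parent = emptyenv())
      net_backward(net, fw$cache, ls$dlogit, grads)
      upd <- adam_step(net$params, as.list(grads), adam, sched$lr)
      net$params <- upd$params
      adam <- upd$state
      tr_loss <- tr_loss + ls$loss * length(b)
    }
    tr_loss <- tr_loss / length(ord)
    vl <- val_loss_fn()
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss,
                                 val_loss = vl, lr = sched$lr))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f lr %.2g",
                      epoch, tr_loss, vl, sched$lr))
    improved <- vl < best_loss - 1e-9
    if (improved) {
      best_loss <- vl
      best_params <- net$params
    }
    sched <- plateau_step(sched, improved, config)
    if (sched$stop) break
  }
  net$params <- best_params
  structure(list(net = net, spec = net$spec, modality = config$modality,
                 tabular_scaler = scaler, threshold = 0.5,
                 training_log = log, class_weights = cw,
                 config = config),
            class = "model_bundle")
}

#' Predict AF probabilities with a trained bundle
#'
#' @param bundle a `model_bundle` from [train_network()].
#' @param data modality data from [assemble_modality_data()] (same modality
#'   as the bundle).
#' @param idx optional row subset; defaults to all rows.
#' @return numeric vector of probabilities.
#' @export
predict_bundle <- function(bundle, data, idx = NULL) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (is.null(idx)) idx <- seq_along(data$y)
  tab_t <- NULL
  if (!is.null(bundle$net$tab_layers)) {
    if (is.null(data$tab)) stop("bundle expects tabular inputs", call. = FALSE)
    tab_t <- t(apply_scaler(data$tab, bundle$tabular_scaler))
  }
  fw <- net_forward_batched(bundle$net, data$signals, tab_t, idx)
  sigmoid(fw$logit)
}

#' Train one model end-to-end on a cohort
#'
#' Convenience wrapper: assembles modality data, makes a stratified
#' 80/20 test split plus CV folds, uses the first fold as the validation
#' subset, seeds weight initialisation, and trains.
#'
#' @param records list of [ecg_record()].
#' @param spec a [backbone_spec()].
#' @param config a [train_config()].
#' @param hrv_table optional precomputed HRV table.
#' @param verbose print progress.
#' @return list: `bundle`, `data`, `split` (with indices into `data` rows).
#' @export
train_model <- function(records, spec, config, hrv_table = NULL,
                        verbose = FALSE) {
  data <- assemble_modality_data(records, config$modality, hrv_table)
  split <- split_dataset(data$y, config$split_seed, config$n_folds)
  val_idx <- split$folds[[1]]
  train_idx <- setdiff(split$train_idx, val_idx)
  set.seed(config$split_seed + 1L)
  net <- if (modality_uses_tabular(config$modality)) {
    build_multimodal(spec, ncol(data$tab))
  } else {
    build_backbone(spec)
  }
  set.seed(config$split_seed + 2L)
  bundle <- train_network(net, data, train_idx, val_idx, config,
                          verbose = verbose)
  list(bundle = bundle, data = data, split = split)
}
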