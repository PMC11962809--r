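leads8 <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

test_that("every backbone maps a random batch to probabilities and 64-d embeddings", {
  set.seed(1)
  x <- array(rnorm(8 * 5000 * 2, 0, 0.3), c(8, 5000, 2))
  for (nm in c("lenet1d", "alexnet1d", "vgg1d")) {
    set.seed(2)
    net <- build_backbone(backbone_spec(nm))
    fw <- afdetect:::net_forward(net, x)
    p <- afdetect:::sigmoid(fw$logit)
    expect_identical(dim(fw$logit), c(1L, 2L))
    expect_true(all(p >= 0 & p <= 1))
    expect_identical(nrow(fw$embedding), 64L)
  }
  expect_error(backbone_spec("resnet1d"))
})

test_that("parameter count grows monotonically with the width multiplier", {
  count <- function(w) {
    set.seed(3)
    sum(vapply(build_backbone(backbone_spec("alexnet1d",
                                            width_multiplier = w))$params,
               length, numeric(1)))
  }
  expect_lt(count(0.25), count(1.0))
})

test_that("a zeroed tabular branch makes the multimodal output ignore tabular input", {
  set.seed(4)
  net <- build_multimodal(backbone_spec("lenet1d"), 4)
  for (nm in c("tab1_W", "tab1_b", "tab2_W", "tab2_b")) {
    net$params[[nm]] <- net$params[[nm]] * 0
  }
  x <- array(rnorm(8 * 5000 * 2, 0, 0.3), c(8, 5000, 2))
  out1 <- afdetect:::net_forward(net, x, matrix(rnorm(8), 4, 2))$logit
  out2 <- afdetect:::net_forward(net, x, matrix(rnorm(8), 4, 2))$logit
  expect_identical(out1, out2)
  expect_error(build_multimodal(backbone_spec("lenet1d"), 0),
               "at least one tabular")
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(5)
  net <- build_backbone(backbone_spec("lenet1d"), input_len = 400L)
  x <- array(rnorm(8 * 400 * 2, 0, 0.5), c(8, 400, 2))
  loss_at <- function(params) {
    net2 <- net
    net2$params <- params
    sum(afdetect:::net_forward(net2, x)$logit)
  }
  fw <- afdetect:::net_forward(net, x, keep_cache = TRUE)
  grads <- new.env(parent = emptyenv())
  afdetect:::net_backward(net, fw$cache, matrix(1, 1, 2), grads)
  h <- 1e-5
  set.seed(6)
  for (nm in c("c1_W", "c1_b", "c2_W", "embed_W", "out_W", "out_b")) {
    g <- grads[[nm]]
    i <- sample(length(g), 1)
    up <- net$params
    up[[nm]][i] <- up[[nm]][i] + h
    dn <- net$params
    dn[[nm]][i] <- dn[[nm]][i] - h
    fd <- (loss_at(up) - loss_at(dn)) / (2 * h)
    expect_lt(abs(fd - g[i]), 1e-6 + 1e-3 * abs(g[i]))
  }
})

test_that("class weights follow the balanced scheme with its identity", {
  w <- compute_class_weights(c(rep("AF_positive", 44), rep("negative", 956)))
  expect_equal(unname(w["positive"]), 1000 / (2 * 44))
  expect_equal(unname(w["negative"]), 1000 / (2 * 956))
  expect_equal(w["positive"] * 44, w["negative"] * 956,
               ignore_attr = TRUE)
  balanced <- compute_class_weights(c(rep(1, 500), rep(0, 500)))
  expect_equal(unname(balanced), c(1, 1))
  expect_error(compute_class_weights(rep("negative", 10)), "both classes")
})

test_that("the split is stratified, disjoint, covering and seed-deterministic", {
  y10 <- c(rep(1, 5), rep(0, 5))
  s <- split_dataset(y10, split_seed = 1, n_folds = 5)
  expect_identical(length(s$test_idx), 2L)
  expect_identical(sort(unlist(s$folds)), s$train_idx)
  expect_identical(sum(duplicated(unlist(s$folds))), 0L)
  expect_identical(sort(c(s$test_idx, s$train_idx)), 1:10)
  s2 <- split_dataset(y10, split_seed = 1, n_folds = 5)
  expect_identical(s, s2)

  set.seed(3)
  yl <- sample(c(rep(1, 44), rep(0, 956)))
  big <- split_dataset(yl, split_seed = 2)
  expect_true(sum(yl[big$test_idx]) %in% 8:10)
  expect_error(split_dataset(c(1, rep(0, 50)), n_folds = 5),
               "too few positive")
})

test_that("modality assembly produces the documented tabular widths", {
  fx <- tiny_fixture()
  records <- fx$cohort$records
  demo <- assemble_modality_data(records, "ecg_demo")
  expect_identical(colnames(demo$tab), c("age", "sex"))
  full <- assemble_modality_data(records, "ecg_demo_hrv", fx$hrv)
  expect_identical(ncol(full$tab), 10L)
  ecg <- assemble_modality_data(records, "ecg")
  expect_null(ecg$tab)
  # a record without age is excluded from demographic modalities with a message
  noage <- records
  noage[[1]]$age <- NA_real_
  expect_message(d2 <- assemble_modality_data(noage, "ecg_demo"),
                 "excluded")
  expect_identical(length(d2$kept), length(records) - 1L)
})

test_that("the tabular scaler standardises training rows only", {
  set.seed(7)
  tab <- cbind(a = rnorm(50, 10, 3), b = runif(50))
  sc <- afdetect:::fit_scaler(tab[1:30, ])
  z <- afdetect:::apply_scaler(tab, sc)
  expect_equal(unname(colMeans(z[1:30, ])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z[1:30, ], 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_false(all(abs(colMeans(z[31:50, ])) < 1e-6))
})

test_that("a separable toy cohort reaches training AUROC 1.0 within 10 epochs", {
  records <- make_toy_records(60, seed = 5)
  data <- assemble_modality_data(records, "ecg")
  tc <- train_config("ecg", use_class_weights = FALSE, epochs = 10,
                     batch_size = 8, lr_init = 5e-3, split_seed = 11)
  set.seed(12)
  net <- build_backbone(backbone_spec("lenet1d"))
  set.seed(13)
  bundle <- train_network(net, data, 1:40, 41:60, tc)
  p <- predict_bundle(bundle, data, 1:40)
  expect_identical(auroc(data$y[1:40], p), 1)
  expect_lte(nrow(bundle$training_log), 10L)
})

test_that("the plateau schedule halves the LR exactly after lr_patience stalls", {
  cfg <- train_config("ecg", lr_patience = 2, lr_factor = 0.5,
                      early_stop_patience = 5)
  st <- list(lr = 1e-3, lr_wait = 0L, es_wait = 0L, stop = FALSE)
  st <- afdetect:::plateau_step(st, improved = TRUE, cfg)
  expect_identical(st$lr, 1e-3)
  st <- afdetect:::plateau_step(st, improved = FALSE, cfg)
  expect_identical(st$lr, 1e-3) # one stall: not yet
  st <- afdetect:::plateau_step(st, improved = FALSE, cfg)
  expect_identical(st$lr, 5e-4) # second stall: halved
  expect_identical(st$lr_wait, 0L)
  expect_false(st$stop)
  # an improvement resets both waits
  st <- afdetect:::plateau_step(st, improved = TRUE, cfg)
  expect_identical(st$es_wait, 0L)
})

test_that("early stopping halts at epoch 2 when the loss never improves", {
  records <- make_toy_records(40, seed = 15)
  data <- assemble_modality_data(records, "ecg")
  # lr 0 freezes the weights, so epoch 2 cannot improve on epoch 1
  tc <- train_config("ecg", use_class_weights = FALSE, epochs = 10,
                     batch_size = 8, lr_init = 0, early_stop_patience = 1,
                     split_seed = 11)
  set.seed(12)
  net <- build_backbone(backbone_spec("lenet1d"))
  set.seed(13)
  bundle <- train_network(net, data, 1:26, 27:40, tc)
  expect_identical(nrow(bundle$training_log), 2L)
  expect_identical(bundle$training_log$val_loss[1],
                   bundle$training_log$val_loss[2])
  # frozen weights: the restored best weights equal the initial ones
  set.seed(12)
  net0 <- build_backbone(backbone_spec("lenet1d"))
  expect_equal(bundle$net$params, net0$params)
})

test_that("seeded training is reproducible run to run", {
  records <- make_toy_records(40, seed = 16)
  data <- assemble_modality_data(records, "ecg")
  tc <- train_config("ecg", use_class_weights = TRUE, epochs = 3,
                     batch_size = 8, split_seed = 21)
  run <- function() {
    set.seed(22)
    net <- build_backbone(backbone_spec("lenet1d"))
    set.seed(23)
    train_network(net, data, 1:26, 27:40, tc)$training_log
  }
  expect_identical(run(), run())
})

test_that("training refuses a single-class partition", {
  records <- make_toy_records(20, seed = 17)
  data <- assemble_modality_data(records, "ecg")
  tc <- train_config("ecg", epochs = 1, split_seed = 1)
  set.seed(1)
  net <- build_backbone(backbone_spec("lenet1d"))
  pos_rows <- which(data$y == 1)
  expect_error(train_network(net, data, pos_rows, seq_along(data$y), tc),
               "both classes")
})
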