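# Fusion classifier: build contracts, transfer modes, training behaviour.

tiny_pair <- function() {
  fusion_config(backbones = list(backbone_spec("tiny"), backbone_spec("tiny_wide")))
}

small_dataset <- function(n_per_class = 12, contrast = 80, seed = 5) {
  ds <- generate_classification_dataset(n_per_class, contrast = contrast, seed = seed)
  set.seed(seed + 1)
  idx <- sample(length(ds$labels))
  n_val <- round(0.25 * length(idx))
  list(tr_x = ds$frames[idx[-(1:n_val)]], tr_y = ds$labels[idx[-(1:n_val)]],
       va_x = ds$frames[idx[1:n_val]], va_y = ds$labels[idx[1:n_val]])
}

test_that("frozen mode has zero trainable backbone parameters", {
  model <- build_fusion_model(fusion_config(mode = "frozen"), seed = 1)
  expect_equal(n_trainable_params(model, "backbones"), 0L)
  expect_gt(n_trainable_params(model, "head"), 0L)
  walk <- layer_trainability(model, 1)
  expect_false(any(walk$trainable))
})

test_that("fine_tune_last_k unfreezes exactly the last k layers per branch", {
  cfg <- fusion_config(mode = "fine_tune_last_k", k = 20L)
  model <- build_fusion_model(cfg, seed = 1)
  for (br in 1:2) {
    walk <- layer_trainability(model, br)
    expect_equal(sum(walk$trainable), 20L)
    n <- nrow(walk)
    expect_true(all(walk$trainable[(n - 19):n]))      # a contiguous tail
    expect_false(any(walk$trainable[seq_len(n - 20)]))
  }
  frozen <- build_fusion_model(fusion_config(mode = "frozen"), seed = 1)
  expect_gt(n_trainable_params(model), n_trainable_params(frozen))
})

test_that("k larger than the backbone depth is rejected", {
  cfg <- fusion_config(mode = "fine_tune_last_k", k = 50L)
  expect_error(build_fusion_model(cfg), "exceeds backbone depth")
})

test_that("fused feature width is the sum of the branch widths", {
  model <- build_fusion_model(tiny_pair(), seed = 2)
  a <- model$backbones[[1]]$feature_dim
  b <- model$backbones[[2]]$feature_dim
  expect_equal(model$fused_dim, a + b)
  expect_equal(nrow(model$head[[1]]$W), a + b)  # head consumes the fused vector
})

test_that("predicted probability rows sum to 1 and labels are the argmax", {
  model <- build_fusion_model(tiny_pair(), seed = 3)
  frames <- replicate(7, rand_frame(32, seed = NULL), simplify = FALSE)
  pred <- predict_fusion_model(model, frames)
  expect_equal(rowSums(pred$probs), rep(1, 7), tolerance = 1e-6)
  expect_true(all(pred$probs >= 0))
  expect_identical(pred$labels, max.col(pred$probs, ties.method = "first"))
})

test_that("backbone and input validation reject unsupported configurations", {
  expect_error(backbone_spec("tiny", pretrained = TRUE), "pretrained")
  expect_error(backbone_spec("tiny", input_size = c(30L, 30L, 1L)), "divisible")
  expect_error(fusion_config(backbones = list(backbone_spec("tiny"))), "two backbone")
  expect_error(fusion_config(dropout_rate = 1), "dropout_rate")
})

test_that("frozen training leaves every backbone weight untouched", {
  d <- small_dataset(8)
  model <- build_fusion_model(fusion_config(mode = "frozen"), seed = 4)
  before <- backbone_checksum(model)
  fit <- train_fusion_model(model, d$tr_x, d$tr_y, d$va_x, d$va_y,
                            train_config(max_epochs = 3L, seed = 6))
  expect_identical(backbone_checksum(fit$model), before)
})

test_that("fine-tuning changes only the unfrozen tail of each branch", {
  d <- small_dataset(8)
  model <- build_fusion_model(fusion_config(mode = "fine_tune_last_k", k = 6L), seed = 4)
  frozen_w_before <- model$backbones[[1]]$layers[[1]]$W     # below the tail
  types <- vapply(model$backbones[[1]]$layers, `[[`, character(1), "type")
  tail_idx <- max(which(types == "conv"))                    # a trainable conv
  tail_w_before <- model$backbones[[1]]$layers[[tail_idx]]$W
  fit <- train_fusion_model(model, d$tr_x, d$tr_y, d$va_x, d$va_y,
                            train_config(max_epochs = 3L, seed = 6))
  expect_identical(fit$model$backbones[[1]]$layers[[1]]$W, frozen_w_before)
  expect_false(identical(fit$model$backbones[[1]]$layers[[tail_idx]]$W,
                         tail_w_before))
})

test_that("training history is reproducible under the same seed", {
  d <- small_dataset(8)
  run <- function() {
    m <- build_fusion_model(tiny_pair(), seed = 11)
    train_fusion_model(m, d$tr_x, d$tr_y, d$va_x, d$va_y,
                       train_config(max_epochs = 3L, seed = 12))$history
  }
  expect_equal(run(), run())
})

test_that("labels outside the class range are rejected", {
  d <- small_dataset(4)
  model <- build_fusion_model(tiny_pair(), seed = 1)
  expect_error(
    train_fusion_model(model, d$tr_x, rep(5L, length(d$tr_x)), d$va_x, d$va_y,
                       train_config(max_epochs = 1L)),
    "labels")
  expect_error(
    train_fusion_model(model, list(), integer(0), d$va_x, d$va_y,
                       train_config(max_epochs = 1L)),
    "non-empty")
})

test_that("early stopping halts a diverging run before max_epochs", {
  d <- small_dataset(8)
  model <- build_fusion_model(tiny_pair(), seed = 13)
  # a poisoned learning rate makes validation loss worsen immediately
  fit <- train_fusion_model(model, d$tr_x, d$tr_y, d$va_x, d$va_y,
                            train_config(learning_rate = 5, max_epochs = 30L,
                                         patience = 3L, seed = 14))
  expect_true(fit$stopped_early)
  expect_lt(nrow(fit$history), 30)
})

test_that("checkpoints reload to identical predictions", {
  d <- small_dataset(6)
  model <- build_fusion_model(tiny_pair(), seed = 21)
  fit <- train_fusion_model(model, d$tr_x, d$tr_y, d$va_x, d$va_y,
                            train_config(max_epochs = 2L, seed = 22))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  reloaded <- load_checkpoint(path)
  p1 <- predict_fusion_model(fit$model, d$va_x)
  p2 <- predict_fusion_model(reloaded, d$va_x)
  expect_identical(p1$labels, p2$labels)
  expect_equal(p1$probs, p2$probs)
})
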