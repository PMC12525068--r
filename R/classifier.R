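# Dual-backbone feature-fusion classifier.
#
# Two convolutional backbones extract complementary features from the same
# input frame; their globally average-pooled feature vectors are fused by
# concatenation and passed to a small fully connected head with dropout and a
# softmax output. Transfer modes mirror the two standard scenarios: "frozen"
# (backbone weights fixed, only the head trains) and "fine_tune_last_k"
# (exactly the last k entries of each backbone's layer list are unfrozen,
# default k = 20, plus the head).

#' Backbone specification
#'
#' The built-in backbones are small convolutional stacks that build with no
#' downloads and train on one CPU at desk scale:
#' * `"tiny"` — 4 blocks of (conv3x3, ReLU, conv3x3, ReLU, avgpool), widths
#'   8/12/16/24, global average pooling; 21 layers, 24 features.
#' * `"tiny_wide"` — same depth, widths 12/16/24/32; 32 features. Its larger
#'   channel budget plays the "deeper/global-context" role opposite `"tiny"`
#'   in the default fusion pair.
#'
#' @param name `"tiny"` or `"tiny_wide"`.
#' @param input_size `c(height, width, channels)`; height and width must be
#'   divisible by 16 (four 2x2 poolings).
#' @param pretrained Must be `FALSE`: no pretrained weights ship with the
#'   package.
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = c("tiny", "tiny_wide"),
                          input_size = c(32L, 32L, 1L),
                          pretrained = FALSE) {
  name <- match.arg(name)
  if (isTRUE(pretrained)) {
    stop("no pretrained weights are available for the built-in backbones", call. = FALSE)
  }
  input_size <- as.integer(input_size)
  if (length(input_size) != 3L || any(input_size < 1L)) {
    stop("`input_size` must be c(height, width, channels)", call. = FALSE)
  }
  if (input_size[1] %% 16L != 0L || input_size[2] %% 16L != 0L) {
    stop("input height and width must be divisible by 16", call. = FALSE)
  }
  structure(list(name = name, input_size = input_size, pretrained = FALSE),
            class = "backbone_spec")
}

backbone_widths <- function(name) {
  switch(name,
         tiny = c(8L, 12L, 16L, 24L),
         tiny_wide = c(12L, 16L, 24L, 32L),
         stop("unknown backbone: ", name, call. = FALSE))
}

build_backbone <- function(spec) {
  widths <- backbone_widths(spec$name)
  c_in <- spec$input_size[3]
  layers <- list()
  prev <- c_in
  for (wd in widths) {
    layers <- c(layers, list(
      nn_layer_conv(prev, wd),
      nn_layer_simple("relu"),
      nn_layer_conv(wd, wd),
      nn_layer_simple("relu"),
      nn_layer_simple("pool")
    ))
    prev <- wd
  }
  layers <- c(layers, list(nn_layer_simple("gap")))
  list(layers = layers, feature_dim = prev, spec = spec)
}

#' Fusion model configuration
#'
#' @param backbones List of exactly two [backbone_spec()] objects; both must
#'   share the same input size (one decode/resize path feeds both branches).
#' @param fc_sizes Integer widths of the fully connected hidden layers
#'   (default one layer of 32).
#' @param dropout_rate Dropout rate in \[0, 1) applied before the classifier.
#' @param n_classes Number of output classes (default 3).
#' @param mode `"frozen"` or `"fine_tune_last_k"`.
#' @param k Number of trailing backbone layers unfrozen in
#'   `fine_tune_last_k` mode (default 20).
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(backbones = list(backbone_spec("tiny"),
                                           backbone_spec("tiny_wide")),
                          fc_sizes = 32L, dropout_rate = 0.3,
                          n_classes = 3L,
                          mode = c("frozen", "fine_tune_last_k"),
                          k = 20L) {
  mode <- match.arg(mode)
  if (length(backbones) != 2L ||
      !all(vapply(backbones, inherits, logical(1), "backbone_spec"))) {
    stop("`backbones` must be a list of two backbone_spec objects", call. = FALSE)
  }
  if (!identical(backbones[[1]]$input_size, backbones[[2]]$input_size)) {
    stop("both backbones must accept the same input size", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must be in [0, 1)", call. = FALSE)
  }
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  structure(list(backbones = backbones, fc_sizes = as.integer(fc_sizes),
                 dropout_rate = dropout_rate, n_classes = as.integer(n_classes),
                 mode = mode, k = as.integer(k)),
            class = "fusion_config")
}

#' Training configuration
#'
#' Defaults follow the fixed-hyperparameter protocol used for all compared
#' runs: Adam, learning rate 0.001, batch size 32, at most 30 epochs, early
#' stopping on validation loss (patience 5, best weights restored).
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience on validation loss.
#' @param seed Integer seed controlling shuffling, dropout, and batching.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32L,
                         max_epochs = 30L, patience = 5L, seed = 1L) {
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

set_trainable <- function(layers, mode, k) {
  n <- length(layers)
  if (mode == "frozen") {
    flags <- rep(FALSE, n)
  } else {
    if (k > n) {
      stop(sprintf("k = %d exceeds backbone depth (%d layers)", k, n), call. = FALSE)
    }
    flags <- c(rep(FALSE, n - k), rep(TRUE, k))
  }
  for (i in seq_len(n)) layers[[i]]$trainable <- flags[i]
  layers
}

#' Build the dual-backbone fusion model
#'
#' Instantiates both backbones and the fused head. The fused feature width is
#' the sum of the two branch widths (concatenation). In `"frozen"` mode every
#' backbone layer is non-trainable; in `"fine_tune_last_k"` mode exactly the
#' last `k` entries of each backbone's layer list are trainable, plus the
#' head (which always trains).
#'
#' @param config A [fusion_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `fusion_model`.
#' @export
build_fusion_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "fusion_config"))
  withr::with_seed(as.integer(seed), {
    bb <- lapply(config$backbones, build_backbone)
    for (i in 1:2) {
      bb[[i]]$layers <- set_trainable(bb[[i]]$layers, config$mode, config$k)
    }
    fused <- sum(vapply(bb, function(b) b$feature_dim, numeric(1)))
    head <- list()
    prev <- fused
    for (wd in config$fc_sizes) {
      head <- c(head, list(nn_layer_dense(prev, wd), nn_layer_simple("relu")))
      prev <- wd
    }
    if (config$dropout_rate > 0) {
      head <- c(head, list(nn_layer_simple("dropout", rate = config$dropout_rate)))
    }
    head <- c(head, list(nn_layer_dense(prev, config$n_classes)))
    model <- list(backbones = bb, head = head, config = config,
                  fused_dim = fused, cache = new.env(parent = emptyenv()))
    model$cache$idx <- list()
    class(model) <- "fusion_model"
    model
  })
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("Fusion model: %s + %s, fused feature width %d, mode %s\n",
              x$backbones[[1]]$spec$name, x$backbones[[2]]$spec$name,
              x$fused_dim, x$config$mode))
  cat(sprintf("  trainable parameters: %d (backbones %d, head %d)\n",
              n_trainable_params(x),
              n_trainable_params(x, part = "backbones"),
              n_trainable_params(x, part = "head")))
  invisible(x)
}

count_params <- function(layers, trainable_only = TRUE) {
  sum(vapply(layers, function(ly) {
    if (is.null(ly$W)) return(0)
    if (trainable_only && !isTRUE(ly$trainable)) return(0)
    length(ly$W) + length(ly$b)
  }, numeric(1)))
}

#' Count (trainable) parameters of a fusion model
#'
#' @param model A `fusion_model`.
#' @param part `"all"`, `"backbones"`, or `"head"`.
#' @param trainable_only Count only layers flagged trainable.
#' @return Integer parameter count.
#' @export
n_trainable_params <- function(model, part = c("all", "backbones", "head"),
                               trainable_only = TRUE) {
  part <- match.arg(part)
  n <- 0
  if (part %in% c("all", "backbones")) {
    n <- n + sum(vapply(model$backbones, function(b) {
      count_params(b$layers, trainable_only)
    }, numeric(1)))
  }
  if (part %in% c("all", "head")) n <- n + count_params(model$head, trainable_only)
  as.integer(n)
}

#' Per-layer trainability of a backbone branch
#'
#' Walks the flat layer list of one branch and reports each layer's type and
#' trainable flag — the audit trail for the fine-tune-last-k contract.
#'
#' @param model A `fusion_model`.
#' @param branch 1 or 2.
#' @return Data frame with columns `layer`, `type`, `trainable`, `n_params`.
#' @export
layer_trainability <- function(model, branch = 1L) {
  layers <- model$backbones[[branch]]$layers
  data.frame(
    layer = seq_along(layers),
    type = vapply(layers, `[[`, character(1), "type"),
    trainable = vapply(layers, function(l) isTRUE(l$trainable), logical(1)),
    n_params = vapply(layers, function(l) {
      if (is.null(l$W)) 0L else length(l$W) + length(l$b)
    }, integer(1))
  )
}

# Frames (list of matrices, [0, 255]) -> batch array (h, w, 1, n).
# Standard preprocessing: per-image standardization (zero mean, unit sd),
# which removes global brightness/illumination variation before the
# backbones see the frame.
frames_to_batch <- function(frames, input_size) {
  h <- input_size[1]; w <- input_size[2]
  n <- length(frames)
  x <- array(0, dim = c(h, w, 1L, n))
  for (i in seq_len(n)) {
    f <- to_grayscale(frames[[i]])
    if (!identical(dim(f), c(h, w))) f <- resize_frame(f, c(h, w))
    s <- stats::sd(f)
    x[, , 1L, i] <- (f - mean(f)) / if (s > 0) s else 1
  }
  x
}

model_forward <- function(model, x, training = FALSE) {
  fa <- nn_forward(model$backbones[[1]]$layers, x, model$cache, training)
  fb <- nn_forward(model$backbones[[2]]$layers, x, model$cache, training)
  feat <- cbind(fa$out, fb$out)  # concatenation fusion
  hd <- nn_forward(model$head, feat, model$cache, training)
  list(logits = hd$out, probs = softmax_rows(hd$out),
       ctx = list(fa = fa, fb = fb, hd = hd))
}

check_labels <- function(y, n_classes) {
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (any(is.na(y)) || any(y < 1L) || any(y > n_classes)) {
    stop(sprintf("labels must be integers in 1..%d (or a factor with that many levels)",
                 n_classes), call. = FALSE)
  }
  y
}

#' Train a fusion model
#'
#' Mini-batch Adam training with shuffling, dropout, and early stopping on
#' validation loss (best weights restored). Deterministic given
#' `config$seed`: the same seed on the same machine reproduces the same
#' history.
#'
#' @param model A `fusion_model` from [build_fusion_model()].
#' @param train_frames,val_frames Lists of frames (matrices in \[0, 255\]),
#'   resized internally to the model input size.
#' @param train_labels,val_labels Integer labels in `1..n_classes` or
#'   factors.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (trained), `history` (data frame: epoch,
#'   train_loss, train_acc, val_loss, val_acc), and `stopped_early`.
#' @export
train_fusion_model <- function(model, train_frames, train_labels,
                               val_frames, val_labels,
                               config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "fusion_model"), inherits(config, "train_config"))
  if (length(train_frames) == 0L || length(val_frames) == 0L) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  nc <- model$config$n_classes
  ytr <- check_labels(train_labels, nc)
  yva <- check_labels(val_labels, nc)
  input_size <- model$backbones[[1]]$spec$input_size
  xtr <- frames_to_batch(train_frames, input_size)
  xva <- frames_to_batch(val_frames, input_size)
  n <- length(ytr)
  onehot <- diag(nc)[ytr, , drop = FALSE]

  ft_a <- first_trainable(model$backbones[[1]]$layers)
  ft_b <- first_trainable(model$backbones[[2]]$layers)
  bb_frozen <- c(ft_a > length(model$backbones[[1]]$layers),
                 ft_b > length(model$backbones[[2]]$layers))

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_loss = numeric(),
                        val_acc = numeric())
  best_val <- Inf; best_model <- model; wait <- 0L; t_step <- 0L
  stopped_early <- FALSE

  eval_set <- function(m, x, y) {
    fw <- model_forward(m, x, training = FALSE)
    p <- pmax(fw$probs, 1e-12)
    loss <- -mean(log(p[cbind(seq_along(y), y)]))
    acc <- mean(max.col(fw$probs, ties.method = "first") == y)
    list(loss = loss, acc = acc)
  }

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0; ep_correct <- 0
      for (b in batches) {
        xb <- xtr[, , , b, drop = FALSE]
        yb <- ytr[b]
        fw <- model_forward(model, xb, training = TRUE)
        p <- pmax(fw$probs, 1e-12)
        ep_loss <- ep_loss - sum(log(p[cbind(seq_along(yb), yb)]))
        ep_correct <- ep_correct + sum(max.col(fw$probs, ties.method = "first") == yb)
        dlogits <- (fw$probs - onehot[b, , drop = FALSE]) / length(b)
        t_step <- t_step + 1L
        bh <- nn_backward(model$head, dlogits, fw$ctx$hd$ctxs)
        model$head <- nn_adam_step(model$head, bh$grads, config$learning_rate, t_step)
        da <- bh$dx[, seq_len(model$backbones[[1]]$feature_dim), drop = FALSE]
        db <- bh$dx[, model$backbones[[1]]$feature_dim + seq_len(model$backbones[[2]]$feature_dim), drop = FALSE]
        if (!bb_frozen[1]) {
          ba <- nn_backward(model$backbones[[1]]$layers, da, fw$ctx$fa$ctxs, stop_at = ft_a)
          model$backbones[[1]]$layers <- nn_adam_step(model$backbones[[1]]$layers,
                                                      ba$grads, config$learning_rate, t_step)
        }
        if (!bb_frozen[2]) {
          bbk <- nn_backward(model$backbones[[2]]$layers, db, fw$ctx$fb$ctxs, stop_at = ft_b)
          model$backbones[[2]]$layers <- nn_adam_step(model$backbones[[2]]$layers,
                                                      bbk$grads, config$learning_rate, t_step)
        }
      }
      val <- eval_set(model, xva, yva)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
        val_loss = val$loss, val_acc = val$acc))
      if (verbose) {
        message(sprintf("epoch %2d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                        epoch, ep_loss / n, ep_correct / n, val$loss, val$acc))
      }
      if (val$loss < best_val - 1e-9) {
        best_val <- val$loss; best_model <- model; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) { stopped_early <- TRUE; break }
      }
    }
  })
  list(model = best_model, history = history, stopped_early = stopped_early)
}

#' Predict class labels and probabilities
#'
#' Softmax probabilities with argmax labels; exact ties break toward the
#' lower class index.
#'
#' @param model A trained `fusion_model`.
#' @param frames List of frames.
#' @return List with `labels` (integer vector) and `probs` (n x n_classes
#'   matrix, rows summing to 1).
#' @export
predict_fusion_model <- function(model, frames) {
  x <- frames_to_batch(frames, model$backbones[[1]]$spec$input_size)
  fw <- model_forward(model, x, training = FALSE)
  list(labels = max.col(fw$probs, ties.method = "first"), probs = fw$probs)
}

#' Checksum of all backbone weights
#'
#' Used to verify the frozen-training contract: the checksum is unchanged by
#' training in frozen mode.
#'
#' @param model A `fusion_model`.
#' @return A single numeric digest of every backbone parameter.
#' @export
backbone_checksum <- function(model) {
  vals <- unlist(lapply(model$backbones, function(b) {
    lapply(b$layers, function(ly) c(ly$W, ly$b))
  }))
  sum(vals * seq_along(vals) %% 97)
}

#' Save / load a fusion model checkpoint
#'
#' @param model A `fusion_model`.
#' @param path Checkpoint file path (RDS).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model with a fresh index cache.
#' @export
save_checkpoint <- function(model, path) {
  m <- model
  m$cache <- NULL
  saveRDS(m, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  m$cache <- new.env(parent = emptyenv())
  m$cache$idx <- list()
  class(m) <- "fusion_model"
  m
}

#' Write a training history as CSV
#'
#' @param history Data frame from [train_fusion_model()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
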