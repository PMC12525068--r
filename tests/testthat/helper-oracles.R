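# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately share no code with the implementation
# paths they check.

# --- frames ---------------------------------------------------------------

rand_frame <- function(h = 16, w = h, seed = NULL, lo = 0, hi = 255) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(h * w, lo, hi), h, w)
}

const_frame <- function(v, h = 16, w = h) matrix(v, h, w)

# --- SSIM oracle ----------------------------------------------------------

# Explicitly enumerates every window position and evaluates the per-window
# formula with weighted moments; mean over windows.
ssim_oracle <- function(a, b, params = ssim_params()) {
  n <- params$window_size
  k <- if (params$window_kind == "uniform") {
    rep(1 / n, n)
  } else {
    r <- seq_len(n) - (n + 1) / 2
    w <- exp(-r^2 / (2 * params$gaussian_sigma^2))
    w / sum(w)
  }
  W2 <- outer(k, k)
  C1 <- (params$K1 * params$L)^2
  C2 <- (params$K2 * params$L)^2
  vals <- c()
  for (i in seq_len(nrow(a) - n + 1)) {
    for (j in seq_len(ncol(a) - n + 1)) {
      wa <- a[i:(i + n - 1), j:(j + n - 1)]
      wb <- b[i:(i + n - 1), j:(j + n - 1)]
      mx <- sum(W2 * wa); my <- sum(W2 * wb)
      vx <- sum(W2 * (wa - mx)^2); vy <- sum(W2 * (wb - my)^2)
      cxy <- sum(W2 * (wa - mx) * (wb - my))
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}

# --- metric oracles -------------------------------------------------------

# One-vs-rest TP/FP/FN/TN by direct counting over label pairs.
prf_oracle <- function(y_true, y_pred, n_classes) {
  out <- data.frame(precision = numeric(n_classes), recall = numeric(n_classes),
                    f1 = numeric(n_classes))
  for (c in seq_len(n_classes)) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    out$precision[c] <- p
    out$recall[c] <- r
    out$f1[c] <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  out
}

# Multiclass MCC as the Pearson correlation between one-hot truth and
# prediction indicator vectors, an algebraically different route from the
# confusion-matrix formula.
mcc_oracle <- function(y_true, y_pred, n_classes) {
  n <- length(y_true)
  T <- matrix(0, n, n_classes); P <- matrix(0, n, n_classes)
  T[cbind(seq_len(n), y_true)] <- 1
  P[cbind(seq_len(n), y_pred)] <- 1
  Tc <- scale(T, scale = FALSE); Pc <- scale(P, scale = FALSE)
  num <- sum(Tc * Pc)
  den <- sqrt(sum(Tc^2)) * sqrt(sum(Pc^2))
  if (den == 0) 0 else num / den
}

# AUC by exhaustive positive-negative pair counting (ties count 1/2).
auc_oracle <- function(pos_scores, neg_scores) {
  tot <- 0
  for (p in pos_scores) {
    for (q in neg_scores) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos_scores) * length(neg_scores))
}

# Random labels/predictions drawn so every confusion cell count stays small.
rand_cm_case <- function(n_classes, max_count, seed) {
  set.seed(seed)
  cm <- matrix(sample(0:max_count, n_classes^2, replace = TRUE),
               n_classes, n_classes)
  y_true <- rep(rep(seq_len(n_classes), each = n_classes), as.vector(t(cm)))
  y_pred <- rep(rep(seq_len(n_classes), times = n_classes), as.vector(t(cm)))
  list(cm = cm, y_true = y_true, y_pred = y_pred)
}

# --- independent bilinear resize oracle (explicit per-pixel loop) ---------

resize_oracle <- function(x, h2, w2) {
  h1 <- nrow(x); w1 <- ncol(x)
  out <- matrix(0, h2, w2)
  for (i in seq_len(h2)) {
    for (j in seq_len(w2)) {
      yc <- min(max((i - 0.5) * h1 / h2 + 0.5, 1), h1)
      xc <- min(max((j - 0.5) * w1 / w2 + 0.5, 1), w1)
      y0 <- min(floor(yc), h1 - 1); x0 <- min(floor(xc), w1 - 1)
      if (h1 == 1) y0 <- 1
      if (w1 == 1) x0 <- 1
      y1 <- min(y0 + 1, h1); x1 <- min(x0 + 1, w1)
      dy <- yc - y0; dx <- xc - x0
      out[i, j] <- (1 - dy) * (1 - dx) * x[y0, x0] + dy * (1 - dx) * x[y1, x0] +
        (1 - dy) * dx * x[y0, x1] + dy * dx * x[y1, x1]
    }
  }
  out
}

# Manifest builder for split tests (no files on disk needed).
make_manifest <- function(n_per_class, classes = c("healthy", "nodule", "polyp"),
                          patients_per_class = 1L) {
  rows <- do.call(rbind, lapply(classes, function(cl) {
    pid <- sprintf("%s_p%02d", cl, rep_len(seq_len(patients_per_class), n_per_class))
    data.frame(file_path = sprintf("%s_%03d.png", cl, seq_len(n_per_class)),
               video_id = pid, patient_id = pid, class_label = cl,
               frame_index = seq_len(n_per_class), split = "none",
               stringsAsFactors = FALSE)
  }))
  class(rows) <- c("dataset_manifest", "data.frame")
  rows
}
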