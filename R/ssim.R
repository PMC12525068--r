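# Structural similarity (SSIM) between video frames.
#
# Frames are plain numeric matrices (grayscale, height x width) or
# height x width x 3 arrays (RGB), with intensities in [0, L] (L = 255 for
# 8-bit sources). Frame indices are 1-based everywhere in this package.

#' SSIM parameters
#'
#' Windowing and stabilization constants for the structural similarity index.
#' Defaults follow the reference configuration of the original SSIM
#' formulation: an 11x11 Gaussian window with sigma 1.5 and stabilization
#' fractions K1 = 0.01, K2 = 0.03 on an 8-bit dynamic range (L = 255), giving
#' C1 = (K1 L)^2 and C2 = (K2 L)^2.
#'
#' @param window_size Odd integer >= 3; side length of the local window in
#'   pixels.
#' @param window_kind `"gaussian"` (default) or `"uniform"` window weights.
#' @param gaussian_sigma Positive standard deviation of the Gaussian window,
#'   in pixels. Ignored for uniform windows.
#' @param K1,K2 Small positive stabilization fractions.
#' @param L Dynamic range of the pixel values (255 for 8-bit images).
#' @return An object of class `ssim_params`.
#' @examples
#' p <- ssim_params()
#' p$window_size
#' @export
ssim_params <- function(window_size = 11L,
                        window_kind = c("gaussian", "uniform"),
                        gaussian_sigma = 1.5,
                        K1 = 0.01, K2 = 0.03, L = 255) {
  window_kind <- match.arg(window_kind)
  window_size <- as.integer(window_size)
  if (length(window_size) != 1L || is.na(window_size) ||
      window_size < 3L || window_size %% 2L == 0L) {
    stop("`window_size` must be an odd integer >= 3", call. = FALSE)
  }
  if (!is.numeric(gaussian_sigma) || gaussian_sigma <= 0) {
    stop("`gaussian_sigma` must be positive", call. = FALSE)
  }
  if (!is.numeric(K1) || K1 <= 0 || !is.numeric(K2) || K2 <= 0) {
    stop("`K1` and `K2` must be positive", call. = FALSE)
  }
  if (!is.numeric(L) || L <= 0) stop("`L` must be positive", call. = FALSE)
  structure(
    list(window_size = window_size, window_kind = window_kind,
         gaussian_sigma = gaussian_sigma, K1 = K1, K2 = K2, L = L),
    class = "ssim_params"
  )
}

#' @export
print.ssim_params <- function(x, ...) {
  cat(sprintf("SSIM parameters: %dx%d %s window", x$window_size,
              x$window_size, x$window_kind))
  if (x$window_kind == "gaussian") cat(sprintf(" (sigma %.3g)", x$gaussian_sigma))
  cat(sprintf("; K1 = %g, K2 = %g, L = %g\n", x$K1, x$K2, x$L))
  invisible(x)
}

# Normalized 1-D window weights (the 2-D window is separable).
ssim_window_1d <- function(params) {
  n <- params$window_size
  if (params$window_kind == "uniform") {
    rep(1 / n, n)
  } else {
    r <- seq_len(n) - (n + 1) / 2
    w <- exp(-r^2 / (2 * params$gaussian_sigma^2))
    w / sum(w)
  }
}

# Separable valid-window filtering: correlate each axis with the 1-D kernel,
# keeping only windows fully inside the image (no padding). Output is smaller
# than the input by window_size - 1 per axis.
ssim_filter_valid <- function(x, k) {
  n <- length(k)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h - n + 1L, w)
  for (j in seq_len(n)) out <- out + k[j] * x[j:(h - n + j), , drop = FALSE]
  res <- matrix(0, h - n + 1L, w - n + 1L)
  for (j in seq_len(n)) res <- res + k[j] * out[, j:(w - n + j), drop = FALSE]
  res
}

check_frame <- function(x, arg = "frame") {
  if (!is.numeric(x) || !(is.matrix(x) || (is.array(x) && length(dim(x)) == 3L))) {
    stop(sprintf("`%s` must be a numeric matrix or height x width x channels array", arg),
         call. = FALSE)
  }
  d <- dim(x)
  if (d[1] < 8L || d[2] < 8L) {
    stop(sprintf("`%s` must be at least 8x8 pixels", arg), call. = FALSE)
  }
  invisible(x)
}

#' Convert a frame to grayscale
#'
#' Three-channel (RGB) frames are reduced with BT.601 luma weights
#' (0.299, 0.587, 0.114); single-channel frames are returned unchanged.
#' The dynamic range of the input is preserved since the weights sum to 1.
#'
#' @param frame Numeric matrix (grayscale) or height x width x 3 array (RGB).
#' @param weights Length-3 luma weights; must sum to 1.
#' @return A numeric matrix.
#' @examples
#' rgb <- array(128, dim = c(8, 8, 3))
#' gray <- to_grayscale(rgb)
#' range(gray)
#' @export
to_grayscale <- function(frame, weights = c(0.299, 0.587, 0.114)) {
  if (is.matrix(frame)) return(frame)
  if (!is.array(frame) || length(dim(frame)) != 3L) {
    stop("`frame` must be a matrix or a 3-D array", call. = FALSE)
  }
  nc <- dim(frame)[3]
  if (nc == 1L) return(frame[, , 1L])
  if (nc != 3L) {
    stop(sprintf("frame has %d channels; expected 1 or 3", nc), call. = FALSE)
  }
  if (length(weights) != 3L || abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must be three values summing to 1", call. = FALSE)
  }
  weights[1] * frame[, , 1L] + weights[2] * frame[, , 2L] + weights[3] * frame[, , 3L]
}

#' Structural similarity index between two frames
#'
#' Computes the SSIM of two grayscale frames of identical size. Each local
#' window contributes
#' \deqn{SSIM(x, y) = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'                        {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' with window-weighted means, variances and covariance, and the overall score
#' is the arithmetic mean over all windows. Only windows fully inside the image
#' are evaluated (valid-window convention, no padding), so the SSIM map is
#' smaller than the image by `window_size - 1` per axis.
#'
#' The score is 1 exactly when the frames are pixel-identical, is symmetric in
#' its arguments, and lies in \eqn{[-1, 1]} (strictly positive for non-negative
#' images with the default constants). The formula itself can be negative for
#' anti-correlated structure; no clamping to \eqn{[0, 1]} is applied.
#'
#' @param a,b Grayscale frames (numeric matrices) of identical dimensions and
#'   dynamic range. Convert RGB input with [to_grayscale()] first.
#' @param params An [ssim_params()] object.
#' @param mode `"windowed"` (local windows, mean-pooled; default) or
#'   `"global"` (a single uniform window spanning the whole image, useful for
#'   small test images).
#' @param return_map If `TRUE`, attach the per-window SSIM map.
#' @return A list of class `ssim_result` with elements `score` and, when
#'   requested, `map`; `score` equals `mean(map)`.
#' @examples
#' x <- matrix(runif(256, 0, 255), 16, 16)
#' ssim(x, x)$score
#' @export
ssim <- function(a, b, params = ssim_params(),
                 mode = c("windowed", "global"), return_map = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(params, "ssim_params")) stop("`params` must be an `ssim_params` object", call. = FALSE)
  check_frame(a, "a"); check_frame(b, "b")
  if (!is.matrix(a) || !is.matrix(b)) {
    stop("`a` and `b` must be grayscale matrices; use to_grayscale() first", call. = FALSE)
  }
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("frame dimensions differ: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  }
  C1 <- (params$K1 * params$L)^2
  C2 <- (params$K2 * params$L)^2

  if (mode == "global") {
    mu_x <- mean(a); mu_y <- mean(b)
    var_x <- mean(a^2) - mu_x^2
    var_y <- mean(b^2) - mu_y^2
    cov_xy <- mean(a * b) - mu_x * mu_y
    score <- ((2 * mu_x * mu_y + C1) * (2 * cov_xy + C2)) /
      ((mu_x^2 + mu_y^2 + C1) * (var_x + var_y + C2))
    map <- matrix(score, 1L, 1L)
  } else {
    n <- params$window_size
    if (nrow(a) < n || ncol(a) < n) {
      stop(sprintf("image (%dx%d) is smaller than the %dx%d SSIM window",
                   nrow(a), ncol(a), n, n), call. = FALSE)
    }
    k <- ssim_window_1d(params)
    mu_x <- ssim_filter_valid(a, k)
    mu_y <- ssim_filter_valid(b, k)
    # weighted second moments; tiny negative variances from rounding are zeroed
    var_x <- pmax(ssim_filter_valid(a * a, k) - mu_x^2, 0)
    var_y <- pmax(ssim_filter_valid(b * b, k) - mu_y^2, 0)
    cov_xy <- ssim_filter_valid(a * b, k) - mu_x * mu_y
    map <- ((2 * mu_x * mu_y + C1) * (2 * cov_xy + C2)) /
      ((mu_x^2 + mu_y^2 + C1) * (var_x + var_y + C2))
    score <- mean(map)
  }
  out <- list(score = score)
  if (return_map) out$map <- map
  class(out) <- "ssim_result"
  out
}

#' @export
print.ssim_result <- function(x, ...) {
  cat(sprintf("SSIM score: %.6f\n", x$score))
  invisible(x)
}

#' Consecutive-frame SSIM trace
#'
#' SSIM between every pair of consecutive frames of a clip: entry `i` of the
#' trace is the SSIM between frame `i` and frame `i + 1`. This is the
#' similarity signal that keyframe extraction thresholds.
#'
#' @param frames List of grayscale frames (numeric matrices), all the same
#'   size; RGB arrays are converted with [to_grayscale()].
#' @param params An [ssim_params()] object.
#' @param mode Passed to [ssim()].
#' @return Numeric vector of length `length(frames) - 1`; entry `i` compares
#'   frames `i` and `i + 1`.
#' @examples
#' f <- replicate(3, matrix(runif(256, 0, 255), 16, 16), simplify = FALSE)
#' consecutive_ssim_trace(f)
#' @export
consecutive_ssim_trace <- function(frames, params = ssim_params(),
                                   mode = c("windowed", "global")) {
  mode <- match.arg(mode)
  if (!is.list(frames) || length(frames) < 2L) {
    stop("`frames` must be a list of at least 2 frames", call. = FALSE)
  }
  frames <- lapply(frames, to_grayscale)
  d1 <- dim(frames[[1L]])
  same <- vapply(frames, function(f) identical(dim(f), d1), logical(1))
  if (!all(same)) stop("all frames must have identical dimensions", call. = FALSE)
  n <- length(frames)
  scores <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    scores[i] <- ssim(frames[[i]], frames[[i + 1L]], params, mode = mode)$score
  }
  scores
}
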