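# Keyframe selection by thresholding consecutive-frame SSIM.

#' Extract keyframes from a frame sequence
#'
#' A frame is kept as a keyframe when its SSIM to the immediately preceding
#' frame falls strictly below `threshold` (high similarity means redundant
#' content; a drop signals new content worth keeping). The first frame is
#' always a keyframe, so every summary is non-empty: for a constant clip the
#' selection is exactly frame 1.
#'
#' Ties (SSIM exactly equal to the threshold) are not keyframes. With the
#' default `anchor = "previous"` each frame is compared to the preceding raw
#' frame; `anchor = "last_keyframe"` instead compares to the most recently
#' selected keyframe, a stricter semantics that accumulates slow drift until
#' it crosses the threshold.
#'
#' @param frames List of frames (grayscale matrices or RGB arrays), all the
#'   same size.
#' @param threshold SSIM threshold in (0, 1); a "90%" threshold is written
#'   as 0.90.
#' @param params An [ssim_params()] object.
#' @param mode SSIM pooling mode, see [ssim()].
#' @param anchor `"previous"` (default) or `"last_keyframe"`.
#' @param trace Optional precomputed consecutive-frame SSIM trace (as returned
#'   by [consecutive_ssim_trace()]); only valid with `anchor = "previous"`.
#'   Used by [threshold_sweep()] to compute each clip's trace once.
#' @return An object of class `keyframe_selection`: a list with `threshold`,
#'   `keyframe_indices` (strictly increasing, 1-based, always containing 1),
#'   `n_total`, and `ssim_trace`.
#' @examples
#' f <- replicate(5, matrix(100, 16, 16), simplify = FALSE)
#' extract_keyframes(f, 0.9)$keyframe_indices  # constant clip -> just frame 1
#' @export
extract_keyframes <- function(frames, threshold, params = ssim_params(),
                              mode = c("windowed", "global"),
                              anchor = c("previous", "last_keyframe"),
                              trace = NULL) {
  mode <- match.arg(mode)
  anchor <- match.arg(anchor)
  if (!is.list(frames) || length(frames) == 0L) {
    stop("`frames` must be a non-empty list of frames", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be a single value in (0, 1)", call. = FALSE)
  }
  n <- length(frames)
  if (n == 1L) {
    sel <- list(threshold = threshold, keyframe_indices = 1L,
                n_total = 1L, ssim_trace = numeric(0))
    class(sel) <- "keyframe_selection"
    return(sel)
  }
  if (anchor == "previous") {
    if (is.null(trace)) {
      trace <- consecutive_ssim_trace(frames, params, mode = mode)
    } else if (length(trace) != n - 1L) {
      stop("`trace` length must be length(frames) - 1", call. = FALSE)
    }
    keep <- c(1L, which(trace < threshold) + 1L)
  } else {
    frames <- lapply(frames, to_grayscale)
    trace <- numeric(n - 1L)
    keep <- 1L
    last <- 1L
    for (i in 2L:n) {
      s <- ssim(frames[[last]], frames[[i]], params, mode = mode)$score
      trace[i - 1L] <- s
      if (s < threshold) {
        keep <- c(keep, i)
        last <- i
      }
    }
  }
  sel <- list(threshold = threshold, keyframe_indices = keep,
              n_total = n, ssim_trace = trace)
  class(sel) <- "keyframe_selection"
  sel
}

#' @export
print.keyframe_selection <- function(x, ...) {
  cat(sprintf("Keyframe selection: %d of %d frames kept at threshold %.3g (reduction %.1f%%)\n",
              length(x$keyframe_indices), x$n_total, x$threshold,
              100 * (1 - length(x$keyframe_indices) / x$n_total)))
  invisible(x)
}

#' Eliminated frames of a selection
#'
#' Complement of the keyframe set: together with `keyframe_indices` it
#' partitions `1:n_total`.
#'
#' @param selection A `keyframe_selection`.
#' @return Integer vector of dropped frame indices.
#' @export
eliminated_frames <- function(selection) {
  stopifnot(inherits(selection, "keyframe_selection"))
  setdiff(seq_len(selection$n_total), selection$keyframe_indices)
}

#' Summarization statistics across SSIM thresholds
#'
#' Runs keyframe extraction at each threshold over a labeled cohort of clips
#' and tabulates keyframe counts and reduction fractions per class and
#' overall. Each clip's consecutive-frame SSIM trace is computed once and
#' reused across thresholds, so the per-threshold selections are nested:
#' raising the threshold can only add keyframes, which is why total counts are
#' non-decreasing in the threshold.
#'
#' @param frames_by_class Named list mapping class label to a list of clips
#'   (each clip a list of frames).
#' @param thresholds Numeric vector of thresholds in (0, 1). The default
#'   sweep is `c(0.90, 0.95, 0.98)`.
#' @param params An [ssim_params()] object.
#' @param mode SSIM pooling mode, see [ssim()].
#' @return A data frame of class `summary_report` with columns `threshold`,
#'   `class` (including a `"total"` row per threshold), `n_videos`,
#'   `n_frames_total`, `n_keyframes`, `reduction_fraction`
#'   (`1 - kept/total`).
#' @examples
#' clip <- replicate(4, matrix(50, 16, 16), simplify = FALSE)
#' threshold_sweep(list(healthy = list(clip)), thresholds = c(0.9, 0.95))
#' @export
threshold_sweep <- function(frames_by_class, thresholds = c(0.90, 0.95, 0.98),
                            params = ssim_params(),
                            mode = c("windowed", "global")) {
  mode <- match.arg(mode)
  if (!is.list(frames_by_class) || length(frames_by_class) == 0L ||
      is.null(names(frames_by_class)) || any(names(frames_by_class) == "")) {
    stop("`frames_by_class` must be a non-empty named list of clip lists", call. = FALSE)
  }
  if (length(thresholds) == 0L || any(thresholds <= 0 | thresholds >= 1)) {
    stop("`thresholds` must be non-empty, each in (0, 1)", call. = FALSE)
  }
  classes <- names(frames_by_class)
  traces <- lapply(frames_by_class, function(clips) {
    lapply(clips, function(clip) {
      if (length(clip) < 2L) numeric(0)
      else consecutive_ssim_trace(clip, params, mode = mode)
    })
  })
  n_frames <- lapply(frames_by_class, function(clips) {
    vapply(clips, length, integer(1))
  })
  rows <- list()
  for (t in sort(thresholds)) {
    per_class <- lapply(classes, function(cl) {
      counts <- mapply(function(tr, nf) {
        if (nf == 0L) 0L else 1L + sum(tr < t)
      }, traces[[cl]], n_frames[[cl]])
      data.frame(threshold = t, class = cl,
                 n_videos = length(counts),
                 n_frames_total = sum(n_frames[[cl]]),
                 n_keyframes = sum(counts),
                 stringsAsFactors = FALSE)
    })
    per_class <- do.call(rbind, per_class)
    total <- data.frame(threshold = t, class = "total",
                        n_videos = sum(per_class$n_videos),
                        n_frames_total = sum(per_class$n_frames_total),
                        n_keyframes = sum(per_class$n_keyframes),
                        stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- rbind(per_class, total)
  }
  report <- do.call(rbind, rows)
  report$reduction_fraction <- ifelse(report$n_frames_total > 0,
                                      1 - report$n_keyframes / report$n_frames_total,
                                      0)
  rownames(report) <- NULL
  class(report) <- c("summary_report", "data.frame")
  report
}

#' Write a summarization report as CSV
#'
#' @param report A `summary_report` from [threshold_sweep()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_report <- function(report, path) {
  stopifnot(inherits(report, "summary_report"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
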