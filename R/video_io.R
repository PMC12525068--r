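# Frame input/output, keyframe export with dataset manifests, resizing, and
# train/validation splits.
#
# A "source" is a directory of image frames in strict lexicographic order
# (the exporter zero-pads indices to 6 digits so lexicographic = temporal).
# PNG is the native lossless format; TIFF is read when the `tiff` package is
# available. Container video formats (.mp4/.avi) need an external decoder
# that this package does not bundle; decode such files to a frame directory
# first.

frame_file_regex <- "\\.(png|tif|tiff)$"

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the `tiff` package", call. = FALSE)
    }
    px <- tiff::readTIFF(path)
  } else if (ext %in% c("mp4", "avi", "mov", "mkv")) {
    stop(sprintf("'%s': container video formats are not supported; decode to a directory of PNG frames first", path),
         call. = FALSE)
  } else {
    stop(sprintf("'%s': unsupported image format '.%s'", path, ext), call. = FALSE)
  }
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]  # drop alpha
  if (length(dim(px)) == 3L && dim(px)[3] == 1L) px <- px[, , 1L]
  px * 255
}

#' Read video frames from a directory
#'
#' Reads all image frames of a directory in lexicographic filename order and
#' returns them as a list of numeric arrays with intensities in \[0, 255\],
#' in temporal order (frame 1 first).
#'
#' @param source Path to a directory of image frames (PNG, optionally TIFF),
#'   or a character vector of image file paths taken in the given order.
#' @return List of frames (matrices or height x width x 3 arrays); the
#'   1-based frame index of each element is its list position, also recorded
#'   in the `frame_index` attribute of the list.
#' @export
read_frames <- function(source) {
  if (length(source) == 1L && dir.exists(source)) {
    files <- sort(list.files(source, pattern = frame_file_regex,
                             full.names = TRUE, ignore.case = TRUE))
    if (length(files) == 0L) {
      stop(sprintf("'%s' contains no readable image frames", source), call. = FALSE)
    }
  } else {
    files <- source
    missing <- !file.exists(files)
    if (any(missing)) {
      stop(sprintf("input not found: %s", paste(files[missing], collapse = ", ")),
           call. = FALSE)
    }
  }
  frames <- lapply(files, read_one_image)
  attr(frames, "frame_index") <- seq_along(frames)
  attr(frames, "files") <- files
  frames
}

#' Export selected keyframes as images with a dataset manifest
#'
#' Writes one lossless PNG per keyframe, named
#' `<video_id>_f<frame index, zero-padded to 6 digits>.png`, and returns a
#' manifest data frame with one row per exported file.
#'
#' @param frames List of frames (as from [read_frames()] or the synthetic
#'   generator), values in \[0, 255\].
#' @param selection A `keyframe_selection` from [extract_keyframes()], or an
#'   integer vector of frame indices.
#' @param out_dir Output directory (created if needed).
#' @param class_label Class of the clip (`"healthy"`, `"nodule"`, `"polyp"`).
#' @param video_id,patient_id Identifiers recorded in the manifest and (for
#'   `video_id`) in file names.
#' @return A `dataset_manifest` data frame with columns `file_path`,
#'   `video_id`, `patient_id`, `class_label`, `frame_index`, `split`
#'   (initially `"none"`); the selection threshold is kept in the
#'   `threshold` attribute.
#' @export
export_keyframes <- function(frames, selection, out_dir, class_label,
                             video_id, patient_id = video_id) {
  idx <- if (inherits(selection, "keyframe_selection")) selection$keyframe_indices else as.integer(selection)
  if (length(idx) == 0L) stop("empty keyframe selection", call. = FALSE)
  if (any(idx < 1L) || any(idx > length(frames))) {
    stop("selection indices outside the frame sequence", call. = FALSE)
  }
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  }
  paths <- file.path(out_dir, sprintf("%s_f%06d.png", video_id, idx))
  for (j in seq_along(idx)) {
    px <- frames[[idx[j]]] / 255
    png::writePNG(pmin(pmax(px, 0), 1), paths[j])
  }
  manifest <- data.frame(
    file_path = paths,
    video_id = video_id,
    patient_id = patient_id,
    class_label = class_label,
    frame_index = idx,
    split = "none",
    stringsAsFactors = FALSE
  )
  if (inherits(selection, "keyframe_selection")) {
    attr(manifest, "threshold") <- selection$threshold
  }
  class(manifest) <- c("dataset_manifest", "data.frame")
  manifest
}

#' Combine manifests from several videos
#'
#' @param ... `dataset_manifest` data frames (or a single list of them).
#' @return A combined `dataset_manifest`; file paths must be unique.
#' @export
bind_manifests <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) && !is.data.frame(parts[[1L]])) {
    parts <- parts[[1L]]
  }
  out <- do.call(rbind, lapply(parts, as.data.frame))
  if (anyDuplicated(out$file_path)) {
    stop("duplicate file paths across manifests", call. = FALSE)
  }
  class(out) <- c("dataset_manifest", "data.frame")
  out
}

#' Write / read a dataset manifest as CSV
#'
#' @param manifest A `dataset_manifest`.
#' @param path CSV path (UTF-8, with header).
#' @return `write_manifest` returns `path` invisibly; `read_manifest` returns
#'   the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  class(m) <- c("dataset_manifest", "data.frame")
  m
}

#' Resize a frame by bilinear interpolation
#'
#' Resamples with the half-pixel-center convention (output pixel centers are
#' mapped uniformly into the input grid; border samples clamp to the edge).
#' Resizing to the input size returns the frame unchanged; constant frames
#' stay constant because the four interpolation weights sum to 1.
#'
#' @param frame Matrix or height x width x channels array.
#' @param target Integer vector `c(height, width)`, both positive.
#' @return The resized frame with dimensions exactly `target`.
#' @export
resize_frame <- function(frame, target) {
  if (length(target) != 2L || any(target < 1)) {
    stop("`target` must be two positive integers (height, width)", call. = FALSE)
  }
  h2 <- as.integer(target[1]); w2 <- as.integer(target[2])
  if (is.matrix(frame)) return(resize_bilinear_2d(frame, h2, w2))
  if (is.array(frame) && length(dim(frame)) == 3L) {
    out <- array(0, dim = c(h2, w2, dim(frame)[3]))
    for (c in seq_len(dim(frame)[3])) {
      out[, , c] <- resize_bilinear_2d(frame[, , c], h2, w2)
    }
    return(out)
  }
  stop("`frame` must be a matrix or 3-D array", call. = FALSE)
}

resize_bilinear_2d <- function(x, h2, w2) {
  h1 <- nrow(x); w1 <- ncol(x)
  if (h1 == h2 && w1 == w2) return(x)
  yc <- pmin(pmax((seq_len(h2) - 0.5) * (h1 / h2) + 0.5, 1), h1)
  xc <- pmin(pmax((seq_len(w2) - 0.5) * (w1 / w2) + 0.5, 1), w1)
  y0 <- pmin(floor(yc), h1 - 1L); y0[h1 == 1L] <- 1L
  x0 <- pmin(floor(xc), w1 - 1L); x0[w1 == 1L] <- 1L
  y1 <- pmin(y0 + 1L, h1); x1 <- pmin(x0 + 1L, w1)
  wy <- yc - y0; wx <- xc - x0
  WY <- matrix(wy, h2, w2); WX <- matrix(wx, h2, w2, byrow = TRUE)
  (1 - WY) * (1 - WX) * x[y0, x0, drop = FALSE] +
    WY * (1 - WX) * x[y1, x0, drop = FALSE] +
    (1 - WY) * WX * x[y0, x1, drop = FALSE] +
    WY * WX * x[y1, x1, drop = FALSE]
}

#' Assign train/validation splits to a manifest
#'
#' Default mode reproduces a frame-level stratified random split: within each
#' class, a fraction `val_fraction` of frames (rounded, so within one record
#' of the exact ratio) is assigned to validation and the rest to training.
#' Frame-level splitting can place frames of the same patient in both splits;
#' `group_by_patient = TRUE` instead assigns whole patients to a split
#' (leakage-safe, at the cost of a coarser match to `val_fraction`).
#'
#' @param manifest A `dataset_manifest`.
#' @param val_fraction Fraction in (0, 1) assigned to validation (default
#'   0.2, i.e. an 80/20 split).
#' @param seed Integer seed; the assignment is deterministic given the seed
#'   and does not disturb the caller's RNG state.
#' @param group_by_patient Keep all frames of a patient in one split.
#' @return The manifest with its `split` column set to `"train"`/`"val"`.
#' @export
split_dataset <- function(manifest, val_fraction = 0.2, seed = 1L,
                          group_by_patient = FALSE) {
  if (!is.numeric(val_fraction) || val_fraction <= 0 || val_fraction >= 1) {
    stop("`val_fraction` must be in (0, 1)", call. = FALSE)
  }
  m <- as.data.frame(manifest)
  m$split <- "train"
  withr::with_seed(as.integer(seed), {
    for (cl in unique(m$class_label)) {
      rows <- which(m$class_label == cl)
      if (length(rows) == 0L) {
        warning(sprintf("class '%s' has no records; stratum skipped", cl))
        next
      }
      if (group_by_patient) {
        pats <- sample(unique(m$patient_id[rows]))
        if (length(pats) == 1L) {
          warning(sprintf("class '%s' has a single patient; all frames kept in training", cl))
          next
        }
        sizes <- vapply(pats, function(p) sum(m$patient_id[rows] == p), integer(1))
        target <- val_fraction * length(rows)
        # whole patients, in shuffled order, until validation reaches target
        n_take <- which(cumsum(sizes) >= target)[1L]
        if (is.na(n_take)) n_take <- length(pats) - 1L
        n_take <- min(max(n_take, 1L), length(pats) - 1L)
        val_pat <- pats[seq_len(n_take)]
        m$split[rows][m$patient_id[rows] %in% val_pat] <- "val"
      } else {
        n_val <- round(val_fraction * length(rows))
        n_val <- min(max(n_val, 0L), length(rows))
        val_rows <- sample(rows, n_val)
        m$split[val_rows] <- "val"
      }
    }
  })
  class(m) <- c("dataset_manifest", "data.frame")
  m
}
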