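# Keyframe selection and the threshold sweep report.

test_that("constant and alternating clips bracket the selection behaviour", {
  const <- replicate(50, const_frame(80), simplify = FALSE)
  sel <- extract_keyframes(const, 0.90)
  expect_identical(sel$keyframe_indices, 1L)  # all consecutive SSIM = 1

  alt <- rep(list(const_frame(0), const_frame(255)), 5)
  sel2 <- extract_keyframes(alt, 0.90)
  expect_identical(sel2$keyframe_indices, 1:10)  # every transition ~1e-4

  single <- list(const_frame(1))
  expect_identical(extract_keyframes(single, 0.5)$keyframe_indices, 1L)
})

test_that("selection invariants hold: first frame, strict order, partition", {
  set.seed(42)
  for (rep_i in 1:5) {
    frames <- lapply(1:12, function(i) rand_frame(16, seed = 50 * rep_i + i))
    sel <- extract_keyframes(frames, 0.95)
    k <- sel$keyframe_indices
    expect_equal(k[1], 1L)
    expect_true(all(diff(k) > 0))
    expect_true(all(k >= 1 & k <= sel$n_total))
    # keyframes + eliminated frames partition the input
    expect_setequal(c(k, eliminated_frames(sel)), seq_len(sel$n_total))
    # strict "<" at the threshold: trace entries >= threshold are dropped
    expect_identical(k[-1], which(sel$ssim_trace < 0.95) + 1L)
  }
})

test_that("ties at the threshold are not keyframes", {
  frames <- replicate(3, const_frame(10), simplify = FALSE)
  trace <- c(0.9, 0.95)  # second transition exactly at threshold
  sel <- extract_keyframes(frames, 0.95, trace = trace)
  expect_identical(sel$keyframe_indices, c(1L, 2L))
})

test_that("selection is deterministic and idempotent", {
  v <- generate_video(video_spec(15, event_indices = c(6L, 11L), seed = 8))
  s1 <- extract_keyframes(v$frames, 0.9)
  s2 <- extract_keyframes(v$frames, 0.9)
  expect_identical(s1, s2)
})

test_that("subset monotonicity across thresholds", {
  set.seed(7)
  for (sd in 1:6) {
    spec <- video_spec(18, event_indices = sort(sample(3:18, 2)), seed = sd)
    frames <- generate_video(spec)$frames
    tr <- consecutive_ssim_trace(frames)
    prev <- integer(0)
    for (t in c(0.5, 0.9, 0.95, 0.99)) {
      k <- extract_keyframes(frames, t, trace = tr)$keyframe_indices
      expect_true(all(prev %in% k))
      prev <- k
    }
  }
})

test_that("input validation rejects bad thresholds and empty input", {
  f <- replicate(3, const_frame(1), simplify = FALSE)
  expect_error(extract_keyframes(list(), 0.9), "non-empty")
  expect_error(extract_keyframes(f, 0), "in \\(0, 1\\)")
  expect_error(extract_keyframes(f, 1), "in \\(0, 1\\)")
  expect_error(extract_keyframes(f, 0.9, trace = c(1)), "length")
})

test_that("compare-to-last-keyframe anchor accumulates drift", {
  # ramp of constant frames: consecutive pairs are similar, but drift from
  # the last keyframe accumulates until it crosses the threshold
  vals <- seq(0, 150, by = 15)
  frames <- lapply(vals, const_frame)
  prev_sel <- extract_keyframes(frames, 0.6, anchor = "previous")
  anchored <- extract_keyframes(frames, 0.6, anchor = "last_keyframe")
  expect_gte(length(anchored$keyframe_indices), length(prev_sel$keyframe_indices))
  expect_equal(anchored$keyframe_indices[1], 1L)
})

test_that("threshold sweep reports nested counts and exact bookkeeping", {
  cohort <- list(
    healthy = lapply(1:2, function(s) generate_video(video_spec(
      14, event_indices = c(5L, 9L), class_label = "healthy", seed = s))$frames),
    nodule = list(generate_video(video_spec(
      14, event_indices = c(7L), class_label = "nodule", seed = 11))$frames)
  )
  th <- c(0.90, 0.95, 0.98)
  rep <- threshold_sweep(cohort, th)

  expect_s3_class(rep, "summary_report")
  expect_equal(nrow(rep), 3 * 3)  # (2 classes + total) x 3 thresholds
  expect_true(all(rep$reduction_fraction >= 0 & rep$reduction_fraction <= 1))
  expect_equal(rep$reduction_fraction, 1 - rep$n_keyframes / rep$n_frames_total)

  totals <- rep$n_keyframes[rep$class == "total"]
  expect_true(all(diff(totals) >= 0))  # monotone non-decreasing in threshold

  # counts match per-video extraction run independently
  for (i in seq_len(nrow(rep))) {
    if (rep$class[i] == "total") next
    clips <- cohort[[rep$class[i]]]
    manual <- sum(vapply(clips, function(cl) {
      length(extract_keyframes(cl, rep$threshold[i])$keyframe_indices)
    }, numeric(1)))
    expect_equal(rep$n_keyframes[i], manual)
  }
})

test_that("sweep of a constant video yields one keyframe at every threshold", {
  cohort <- list(healthy = list(replicate(10, const_frame(42), simplify = FALSE)))
  rep <- threshold_sweep(cohort, c(0.90, 0.95, 0.98))
  expect_equal(rep$n_keyframes[rep$class == "healthy"], c(1L, 1L, 1L))
})

test_that("sweep validates inputs and writes CSV", {
  expect_error(threshold_sweep(list(), 0.9), "named list")
  cohort <- list(healthy = list(replicate(3, const_frame(1), simplify = FALSE)))
  expect_error(threshold_sweep(cohort, numeric(0)), "non-empty")
  expect_error(threshold_sweep(cohort, c(0.5, 1.2)), "in \\(0, 1\\)")

  rep <- threshold_sweep(cohort, 0.9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_report(rep, path)
  back <- read.csv(path)
  expect_equal(back$n_keyframes, rep$n_keyframes)
  expect_named(back, c("threshold", "class", "n_videos", "n_frames_total",
                       "n_keyframes", "reduction_fraction"))
})
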