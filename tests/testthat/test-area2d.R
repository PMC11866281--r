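spec2d_noiseless <- function(...) {
  args <- utils::modifyList(
    list(shot_noise = FALSE, read_sd = 0, seed = 1L), list(...))
  do.call(phantom_spec_2d, args)
}

test_that("frame classification recovers the true strip area", {
  fs <- generate_area_lapse(phantom_spec_2d(seed = 12L), keep_truth = TRUE)
  truth <- attr(fs, "truth")
  for (i in c(1, 31, 61)) {
    m <- classify_frame(fs$frames[[i]])
    expect_lt(abs(sum(m) / sum(truth[[i]]) - 1), 0.02)
  }
})

test_that("the polarity flag handles inverted-contrast frames", {
  fs <- generate_area_lapse(spec2d_noiseless(), keep_truth = TRUE)
  f <- fs$frames[[1]]
  m_norm <- classify_frame(f)
  m_inv <- classify_frame(max(f) - f, dark_foreground = TRUE)
  expect_identical(m_inv, m_norm)
})

test_that("a constant frame cannot be classified", {
  expect_error(classify_frame(matrix(7, 50, 50)), "constant")
})

test_that("the seeded classifier mode recovers the strip from scribbles", {
  fs <- generate_area_lapse(phantom_spec_2d(seed = 30L), keep_truth = TRUE)
  truth <- attr(fs, "truth")[[1]]
  fg_px <- sample(which(truth), 60)
  bg_px <- sample(which(!truth), 60)
  m <- classify_frame(fs$frames[[1]],
                      scribbles = list(fg = fg_px, bg = bg_px))
  expect_lt(abs(sum(m) / sum(truth) - 1), 0.05)
})

test_that("area doubles by 30 s under the default growth law", {
  fs <- generate_area_lapse(phantom_spec_2d(seed = 5L))
  traj <- area_trajectory(fs)
  expect_equal(traj$area_ratio[1], 1)
  at30 <- traj$area_ratio[traj$timestamp == 30]
  expect_lt(abs(at30 - 2.0), 0.1)
  gt <- area_ground_truth(fs$spec)
  expect_equal(gt$area_ratio[gt$timestamp == 30], 2.0, tolerance = 1e-9)
})

test_that("a zero-growth phantom keeps its area", {
  fs <- generate_area_lapse(
    phantom_spec_2d(f_left = 1, f_right = 1, timestamps = 0:20, seed = 2L))
  traj <- area_trajectory(fs)
  expect_true(all(abs(traj$area_ratio - 1) < 0.02))
})

test_that("asymmetric expansion is recovered per side of the margin", {
  spec <- phantom_spec_2d(f_left = 1.2, f_right = 1.8,
                          timestamps = 0:90, seed = 7L)
  fs <- generate_area_lapse(spec)
  traj <- area_trajectory(fs)
  last <- nrow(traj)
  gt <- area_ground_truth(spec)
  expect_lt(abs(traj$ratio_left[last] / gt$ratio_left[last] - 1), 0.05)
  expect_lt(abs(traj$ratio_right[last] / gt$ratio_right[last] - 1), 0.05)
  expect_gt(traj$ratio_right[last], traj$ratio_left[last])
})

test_that("area ratios ignore global illumination scaling", {
  fs <- generate_area_lapse(spec2d_noiseless(timestamps = c(0, 15, 30)))
  dim_fs <- fs
  dim_fs$frames <- lapply(fs$frames, function(f) 0.3 * f)
  t1 <- area_trajectory(fs)
  t2 <- area_trajectory(dim_fs)
  expect_equal(t2$area_ratio, t1$area_ratio, tolerance = 1e-12)
})

test_that("10 s interval maps tile the total expansion exactly", {
  fs <- generate_area_lapse(spec2d_noiseless(timestamps = 0:60))
  traj <- area_trajectory(fs)
  im <- interval_maps(traj, interval = 10)
  masks <- attr(traj, "masks")
  total <- masks[[length(masks)]] & !masks[[1]]
  tiled <- Reduce(`|`, im$maps)
  expect_identical(tiled, total)
  # intervals are disjoint for monotone growth
  counts <- Reduce(`+`, lapply(im$maps, function(m) m * 1))
  expect_lte(max(counts), 1)
})

test_that("frame series round-trip through TIFF frames and manifest", {
  fs <- generate_area_lapse(phantom_spec_2d(timestamps = 0:5, seed = 3L))
  dir <- withr::local_tempdir()
  mpath <- write_frame_series(fs, dir)
  back <- read_frame_series(mpath)
  expect_equal(back$timestamps, fs$timestamps)
  for (i in seq_along(fs$frames))
    expect_identical(back$frames[[i]], fs$frames[[i]])
})
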