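test_that("a written series reads back bit-exactly with manifest timestamps", {
  ser <- generate_stack_series(tiny_spec(timestamps = c(2, 9, 17, 30, 41)))
  dir <- withr::local_tempdir()
  mpath <- write_stack_series(ser, dir)
  back <- read_series(mpath)
  expect_length(back$stacks, 5)
  expect_equal(back$timestamps, c(2, 9, 17, 30, 41))
  for (i in seq_along(ser$stacks)) {
    expect_identical(back$stacks[[i]]$forward, ser$stacks[[i]]$forward)
    expect_identical(back$stacks[[i]]$epi, ser$stacks[[i]]$epi)
  }
  expect_equal(back$spacing, ser$spacing)
})

test_that("manifest row order is irrelevant: series sorts by timestamp", {
  ser <- generate_stack_series(tiny_spec(timestamps = c(3, 12, 25)))
  dir <- withr::local_tempdir()
  mpath <- write_stack_series(ser, dir)
  man <- read.csv(mpath)
  write.csv(man[c(3, 1, 2), ], mpath, row.names = FALSE)
  back <- read_series(mpath)
  expect_equal(back$timestamps, c(3, 12, 25))
  expect_identical(back$stacks[[2]]$forward, ser$stacks[[2]]$forward)
})

test_that("mixed stack depths within one series are a hard failure", {
  # depths may differ between samples (each its own series), never within
  ser61 <- generate_stack_series(tiny_spec(nz = 36, timestamps = c(3, 10)))
  ser91 <- generate_stack_series(tiny_spec(nz = 44, timestamps = c(20, 30)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_stack_series(ser61, d1)
  m2 <- write_stack_series(ser91, d2)
  a <- read.csv(m1); b <- read.csv(m2)
  b$path_forward <- file.path(d2, b$path_forward)
  b$path_epi <- file.path(d2, b$path_epi)
  write.csv(rbind(a, b), m1, row.names = FALSE)
  expect_error(read_series(m1), "48x36.*48x44|48x44.*48x36")
})

test_that("missing stack files are reported by name", {
  ser <- generate_stack_series(tiny_spec(timestamps = c(3, 10)))
  dir <- withr::local_tempdir()
  mpath <- write_stack_series(ser, dir)
  unlink(file.path(dir, "stack_t002_epi.tif"))
  expect_error(read_series(mpath), "stack_t002_epi")
})

test_that("feature tables round-trip exactly and carry run metadata", {
  ser <- generate_stack_series(tiny_spec(mode = "dilution"))
  traj <- build_trajectory(ser)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(traj, path, seed = 99L)
  back <- read_features(path)
  expect_true(any(grepl("seed: 99", attr(back, "metadata"))))
  expect_true(any(grepl("config_hash", attr(back, "metadata"))))
  df <- as.data.frame(traj)
  for (f in c("w", "V", "dIbar_f_pct")) {
    got <- back$value[back$feature == f]
    expect_identical(got[order(back$timestamp[back$feature == f])],
                     df[[f]][order(df$timestamp)])
  }
})

test_that("an empty trajectory is refused, not written as an empty file", {
  empty <- structure(data.frame(), class = c("feature_trajectory", "data.frame"))
  path <- withr::local_tempfile(fileext = ".csv")
  expect_error(write_features(empty, path), "empty")
  expect_false(file.exists(path))
})

test_that("non-integer stacks survive the float TIFF path", {
  ser <- generate_stack_series(noiseless(stripe_contrast = 0.3,
                                         timestamps = c(0, 10)))
  expect_false(all(ser$stacks[[1]]$forward ==
                     round(ser$stacks[[1]]$forward)))
  dir <- withr::local_tempdir()
  back <- read_series(write_stack_series(ser, dir))
  expect_equal(back$stacks[[1]]$forward, ser$stacks[[1]]$forward,
               tolerance = 1e-6)
})
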