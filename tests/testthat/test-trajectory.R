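test_that("the crop rule keeps a record at exactly the limit and drops beyond", {
  ser <- generate_stack_series(
    tiny_spec(amplitude = 0.2, timestamps = c(3, 20, 45, 50, 55)))
  traj <- build_trajectory(ser, traj_config(crop_limit = 50))
  expect_equal(traj$timestamp, c(3, 20, 45, 50))
  om <- attr(traj, "omitted")
  expect_length(om, 1)
  expect_equal(om[[1]]$timestamp, 55)
  expect_match(om[[1]]$reason, "crop limit")
})

test_that("percent changes are zero against the baseline record", {
  ser <- generate_stack_series(noiseless(amplitude = 0))
  traj <- build_trajectory(ser)
  for (col in c("dV_pct", "dw_pct", "dh_pct", "dIbar_f_pct", "dIsum_f_pct"))
    expect_true(all(abs(traj[[col]]) < 2), info = col)
  expect_equal(traj$dw_pct[1], 0)
})

test_that("a swelling trajectory tracks the saturating-exponential law", {
  spec <- phantom_spec(amplitude = 0.5, tau_s = 10,
                       timestamps = seq(0, 40, by = 8), seed = 2L)
  traj <- build_trajectory(generate_stack_series(spec))
  truth <- 50 * (1 - exp(-traj$timestamp / 10))
  expect_true(all(abs(traj$dw_pct - truth) < 5))
  expect_true(all(abs(traj$dh_pct) < 3))
})

test_that("correlation paths carry the conservation signature", {
  ser <- generate_stack_series(
    noiseless(mode = "dilution", amplitude = 0.5, tau_s = 6,
              timestamps = seq(0, 40, by = 8)))
  traj <- build_trajectory(ser)
  cum <- correlate_features(traj, "dw_pct", "dIsum_f_pct")
  expect_lt(abs(cum$slope), 0.05)           # cumulative signal conserved
  mean_ <- correlate_features(traj, "dw_pct", "dIbar_f_pct")
  # dilution closed form: at dw = +50, dIbar = -33.3
  i <- nrow(traj)
  expect_gt(traj$dw_pct[i], 45)
  expect_equal(traj$dIbar_f_pct[i],
               -100 * traj$dw_pct[i] / (100 + traj$dw_pct[i]),
               tolerance = 0.15)
  expect_lt(mean_$slope, 0)
  # time-ordered path with the baseline at the origin
  expect_equal(mean_$path$x[1], 0)
  expect_equal(mean_$path$y[1], 0)
})

test_that("channels correlate perfectly when epi is a scaled forward copy", {
  ser <- generate_stack_series(noiseless(beta = 0.45, mode = "dilution"))
  traj <- build_trajectory(ser)
  fe <- correlate_features(traj, "Ibar_f", "Ibar_epi")
  expect_equal(fe$pearson, 1.0, tolerance = 1e-9)
  expect_equal(traj$Ibar_epi / traj$Ibar_f, rep(0.45, nrow(traj)),
               tolerance = 1e-9)
})

test_that("destruction without swelling hugs the intensity axis", {
  spec <- phantom_spec(mode = "destruction", amplitude = 0, tau_d = 8,
                       timestamps = seq(0, 24, by = 6), seed = 4L)
  traj <- build_trajectory(generate_stack_series(spec))
  expect_lt(max(abs(traj$dw_pct)), 3)
  expect_lt(min(traj$dIbar_f_pct), -50)
  expect_error(
    correlate_features(
      build_trajectory(generate_stack_series(
        noiseless(mode = "destruction", amplitude = 0, tau_d = 8,
                  timestamps = seq(0, 24, by = 6)))),
      "dw_pct", "dIbar_f_pct"),
    "zero-variance")
})

test_that("the damage-mode classifier separates the three regimes", {
  mk <- function(mode, A, seed)
    classify_mode(build_trajectory(generate_stack_series(
      tiny_spec(mode = mode, amplitude = A, tau_s = 8, tau_d = 10,
                timestamps = seq(0, 40, by = 8), seed = seed))))
  inert <- mk("inert", 0, 21L)
  drift <- mk("dilution", 0.5, 22L)
  destr <- mk("destruction", 0.5, 23L)
  expect_equal(inert$label, "inert")
  expect_equal(drift$label, "bundle_drifting")
  expect_equal(destr$label, "intrinsic_destruction")
  expect_gt(drift$R, 0.85); expect_gt(drift$W, 10)
  expect_lt(destr$R, 0.85)
  # the label is a pure function of (R, W, thresholds)
  expect_equal(drift$tau_R, 0.15)
  expect_equal(drift$tau_W, 10)
})

test_that("percent-change columns ignore global intensity rescaling", {
  ser <- generate_stack_series(tiny_spec(mode = "dilution", seed = 9L))
  scaled <- stack_series(lapply(ser$stacks, function(s)
    voxel_stack(2.5 * s$forward, 2.5 * s$epi, s$spacing, s$timestamp)))
  t1 <- build_trajectory(ser)
  t2 <- build_trajectory(scaled)
  for (col in c("dV_pct", "dw_pct", "dh_pct", "dIbar_f_pct", "dIsum_f_pct"))
    expect_equal(t2[[col]], t1[[col]], tolerance = 1e-9, info = col)
})

test_that("fewer than two usable time points is an error", {
  ser <- generate_stack_series(tiny_spec(timestamps = c(3, 60)))
  expect_error(build_trajectory(ser, traj_config(crop_limit = 50)),
               "trajectory undefined")
})
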