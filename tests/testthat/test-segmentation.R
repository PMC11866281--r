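test_that("noiseless phantom mask matches the true envelope volume", {
  ser <- generate_stack_series(noiseless(), keep_truth = TRUE)
  env <- attr(ser, "envelope")[[1]]
  tm <- segment_tissue(ser$stacks[[1]])
  expect_lt(abs(sum(tm$mask) / sum(env) - 1), 0.02)
  expect_s3_class(tm, "tissue_mask")
  expect_identical(dim(tm$mask), dim(ser$stacks[[1]]$forward))
  # provenance records the policy that produced the mask
  expect_true(all(c("threshold", "otsu", "background_floor",
                    "components_merged", "cavity_voxels_filled") %in%
                    names(tm$provenance)))
})

test_that("segmentation is invariant to global intensity rescaling", {
  ser <- generate_stack_series(tiny_spec(seed = 3L))
  s <- ser$stacks[[1]]
  m0 <- segment_tissue(s)$mask
  for (c_fac in c(0.5, 3.7)) {
    sc <- voxel_stack(c_fac * s$forward, c_fac * s$epi, s$spacing,
                      s$timestamp)
    expect_identical(segment_tissue(sc)$mask, m0)
  }
})

test_that("enclosed voids are filled: mask tracks envelope, not emitting volume", {
  ser <- generate_stack_series(
    noiseless(mode = "dilution", void_rate = 0.6,
              timestamps = c(0, 20, 40)),
    keep_truth = TRUE)
  env <- attr(ser, "envelope")[[3]]
  emitting <- attr(ser, "expected")[[3]] > 0
  expect_gt(sum(env) - sum(emitting), 0)  # voids exist inside the envelope
  tm <- segment_tissue(ser$stacks[[3]])
  expect_gt(tm$provenance$cavity_voxels_filled, 0)
  expect_lt(abs(sum(tm$mask) / sum(env) - 1), 0.05)
})

test_that("fragments are merged at the distance rule boundary", {
  d <- seg_params()$merge_dist        # 5 um
  near <- segment_tissue(two_slab_stack(gap = d - 1))
  at <- segment_tissue(two_slab_stack(gap = d))
  far <- segment_tissue(two_slab_stack(gap = d + 3))
  main_only <- 24 * 20 * 14           # main slab voxels
  frag <- 24 * 10 * 14
  expect_gte(near$provenance$components_merged, 1)
  expect_gt(sum(near$mask), main_only + 0.9 * frag)
  expect_gte(at$provenance$components_merged, 1)  # <= d merges
  expect_equal(far$provenance$components_merged, 0)
  expect_lt(sum(far$mask), main_only + 0.5 * frag)
})

test_that("per-timepoint thresholding survives global dimming", {
  # destruction-mode phantom whose envelope is constant: the mask must
  # track the envelope until the signal sinks toward the noise floor
  spec <- tiny_spec(mode = "destruction", amplitude = 0, tau_d = 12,
                    timestamps = c(0, 10, 20), seed = 8L)
  ser <- generate_stack_series(spec, keep_truth = TRUE)
  envs <- attr(ser, "envelope")
  for (i in seq_along(envs)) {
    # mean SNR ~ sqrt(I): 10, 6.5, 4.3 across these time points
    tm <- segment_tissue(ser$stacks[[i]])
    expect_lt(abs(sum(tm$mask) / sum(envs[[i]]) - 1), 0.1)
  }
})

test_that("losing the sample flags, not crashes, the time point", {
  # signal gone: only sparse dark counts remain
  set.seed(1)
  noise_only <- array(rpois(40 * 40 * 20, 0.05), c(40, 40, 20))
  s <- voxel_stack(noise_only, noise_only, unit_spacing, 12)
  expect_error(segment_tissue(s), class = "shg4d_empty_mask")
  expect_error(segment_tissue(s), "left imaging volume|signal lost")
})

test_that("mask overlap is the Jaccard fraction", {
  a <- solid_slab_mask(20, 30, 12, wvox = 10, hvox = 6)
  expect_equal(mask_overlap(a, a), 1.0)
  b <- array(FALSE, dim(a)); b[1:2, 1:2, 1] <- TRUE
  expect_equal(mask_overlap(a, b), 0.0)
  # half-shifted slab against an exhaustive voxel count
  shift <- 5
  c_ <- array(FALSE, dim(a))
  c_[, (1:30) %in% ((1:30) + shift), ] <- FALSE
  idx <- which(a, arr.ind = TRUE)
  idx[, 2] <- idx[, 2] + shift
  c_[idx] <- TRUE
  inter <- sum(a & c_); uni <- sum(a | c_)
  expect_equal(mask_overlap(a, c_), inter / uni)
  expect_lt(mask_overlap(a, c_), 1)
  expect_error(mask_overlap(a, array(FALSE, c(2, 2, 2))), "shape")
})
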