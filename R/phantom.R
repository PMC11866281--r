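#' Specification of a synthetic 4D SHG phantom
#'
#' Describes a tilted thin-slab phantom emulating a collagenous thin
#' section mounted flat and imaged as a two-channel z-stack time series.
#' The slab has its length along y (glued ends, spanning the whole
#' field), its width along x (the swelling axis, outer to inner dura
#' surface) and its height along z (the cut thickness, ~30 um). Width
#' swells as a saturating exponential
#' `w(t) = w0 * (1 + A * (1 - exp(-t / tau_s)))` while height stays
#' constant; the grid must keep a safety margin around the tilted slab,
#' mirroring how stack depths are chosen at the microscope.
#'
#' Three intensity regimes are available:
#' \describe{
#'   \item{`inert`}{constant per-voxel emission (water-like control).}
#'   \item{`dilution`}{total emission inside the slab envelope is held
#'     constant while ellipsoidal voids of zero emission appear
#'     progressively: fiber bundles drift apart, the mean signal per
#'     voxel falls, the cumulative signal is conserved.}
#'   \item{`destruction`}{per-voxel emission decays as
#'     `exp(-t / tau_d)`: the collagen loses its SHG-generating order, so
#'     mean and cumulative signal fall together.}
#' }
#'
#' @param nx,ny,nz grid size in voxels along x (width), y (length), z
#'   (height).
#' @param dx,dy,dz voxel spacing in micrometres.
#' @param w0 baseline slab width (um).
#' @param h0 slab height (cut thickness, um).
#' @param tilt_x,tilt_y tilt angles in degrees (rotations about the x-
#'   and y-axis; `tilt_y` tips the slab within the x-z plane, the usual
#'   mounting tilt).
#' @param amplitude fractional width increase A at saturation (>= 0).
#' @param tau_s swelling time constant (min).
#' @param mode intensity regime, one of `"inert"`, `"dilution"`,
#'   `"destruction"`.
#' @param tau_d emission decay time constant (min; destruction mode).
#' @param void_rate expected void appearances per minute (dilution mode).
#' @param void_size range of void semi-axes (um), `c(min, max)`.
#' @param stripe_period,stripe_contrast sinusoidal fiber texture along
#'   the slab length (period in um, contrast in [0, 1)); cosmetic, for
#'   segmentation robustness.
#' @param beta epi/forward expectation ratio (> 0).
#' @param i0 baseline expected forward emission per voxel (counts). The
#'   default of 100 counts puts the baseline shot-noise SNR near 10.
#' @param shot_noise logical, apply Poisson shot noise.
#' @param shot_gain counts per photon for the shot-noise model.
#' @param read_sd Gaussian read-noise standard deviation (counts).
#' @param timestamps acquisition times in minutes, strictly increasing.
#' @param seed integer random seed; generation is fully deterministic
#'   given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(nx = 96, ny = 64, nz = 48,
                         dx = 1, dy = 1, dz = 1,
                         w0 = 40, h0 = 30,
                         tilt_x = 0, tilt_y = 10,
                         amplitude = 0.5, tau_s = 10,
                         mode = c("inert", "dilution", "destruction"),
                         tau_d = 15,
                         void_rate = 0.4, void_size = c(2, 4),
                         stripe_period = 8, stripe_contrast = 0.3,
                         beta = 0.5, i0 = 100,
                         shot_noise = TRUE, shot_gain = 1, read_sd = 2,
                         timestamps = seq(3, 48, by = 5),
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(amplitude >= 0, tau_s > 0, tau_d > 0, beta > 0,
            w0 > 0, h0 > 0, i0 > 0, all(void_size > 0),
            stripe_contrast >= 0, stripe_contrast < 1,
            read_sd >= 0, shot_gain > 0)
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) < 1 || any(diff(timestamps) <= 0) ||
      any(timestamps < 0))
    stop("timestamps must be nonnegative and strictly increasing")
  spec <- structure(
    list(nx = nx, ny = ny, nz = nz, dx = dx, dy = dy, dz = dz,
         w0 = w0, h0 = h0, tilt_x = tilt_x, tilt_y = tilt_y,
         amplitude = amplitude, tau_s = tau_s, mode = mode, tau_d = tau_d,
         void_rate = void_rate, void_size = void_size,
         stripe_period = stripe_period, stripe_contrast = stripe_contrast,
         beta = beta, i0 = i0, shot_noise = shot_noise,
         shot_gain = shot_gain, read_sd = read_sd,
         timestamps = timestamps, seed = as.integer(seed)),
    class = "phantom_spec")
  # safety-margin check at the saturated width (analytic, both tilts)
  wmax <- w0 * (1 + amplitude)
  ty <- tilt_y * pi / 180; tx <- tilt_x * pi / 180
  ext_x <- wmax * abs(cos(ty)) + h0 * abs(sin(ty))
  ext_z <- wmax * abs(sin(ty)) + h0 * abs(cos(ty)) +
    ny * dy * abs(tan(tx))
  if (ext_x > nx * dx - 2 * dx || ext_z > nz * dz - 2 * dz)
    stop(sprintf(
      paste("tilted slab at saturated width (%.1f um) does not fit the",
            "grid with a safety margin (needs %.1f x %.1f um of %.0f x %.0f)"),
      wmax, ext_x, ext_z, nx * dx, nz * dz))
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s mode, grid %dx%dx%d, w0 = %g um, A = %g, tau_s = %g min, %d time points\n",
    x$mode, x$nx, x$ny, x$nz, x$w0, x$amplitude, x$tau_s,
    length(x$timestamps)))
  invisible(x)
}

# slab width at time t (um)
.phantom_width <- function(spec, t) {
  spec$w0 * (1 + spec$amplitude * (1 - exp(-t / spec$tau_s)))
}

# rotation taking slab-frame coords to lab coords: R = Ry(tilt_y) Rx(tilt_x)
.phantom_rotation <- function(spec) {
  tx <- spec$tilt_x * pi / 180
  ty <- spec$tilt_y * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(tx), -sin(tx)), c(0, sin(tx), cos(tx)))
  Ry <- rbind(c(cos(ty), 0, sin(ty)), c(0, 1, 0), c(-sin(ty), 0, cos(ty)))
  Ry %*% Rx
}

# lab coordinates (um, grid-centred) of every voxel centre, plus their
# slab-frame coordinates. Returned once and reused across timestamps.
.phantom_frame <- function(spec) {
  xs <- (seq_len(spec$nx) - (spec$nx + 1) / 2) * spec$dx
  ys <- (seq_len(spec$ny) - (spec$ny + 1) / 2) * spec$dy
  zs <- (seq_len(spec$nz) - (spec$nz + 1) / 2) * spec$dz
  # array dims are (y, x, z)
  Y <- rep(ys, times = spec$nx * spec$nz)
  X <- rep(rep(xs, each = spec$ny), times = spec$nz)
  Z <- rep(zs, each = spec$ny * spec$nx)
  lab <- cbind(x = X, y = Y, z = Z)
  R <- .phantom_rotation(spec)
  slab <- lab %*% R  # t(R) applied from the right: lab -> slab frame
  list(lab = lab, slab = slab,
       dims = c(spec$ny, spec$nx, spec$nz))
}

# voids are drawn once per spec; each has an appearance time and a
# position expressed in fractions of the (time-varying) slab cross-section
.phantom_voids <- function(spec, t_max) {
  if (spec$mode != "dilution" || spec$void_rate <= 0)
    return(NULL)
  k <- rpois(1, spec$void_rate * t_max)
  if (k == 0) return(NULL)
  ly <- spec$ny * spec$dy
  ax <- runif(k, spec$void_size[1], spec$void_size[2])
  ay <- 2 * runif(k, spec$void_size[1], spec$void_size[2])
  # voids stay clear of the imaged window's y-faces so every cavity is
  # fully enclosed in the grid, as the hole-filling policy assumes
  data.frame(
    t_app = runif(k, 0, t_max),
    ux = runif(k, -1, 1),
    yc = runif(k, -pmax(ly / 2 - ay - 2, 0), pmax(ly / 2 - ay - 2, 0)),
    uz = runif(k, -0.7, 0.7),
    ax = ax,
    ay = ay,
    az = pmin(runif(k, spec$void_size[1], spec$void_size[2]),
              spec$h0 / 4))
}

# logical envelope + expected forward emission for one timestamp
.phantom_expected <- function(spec, frame, voids, t, s_ref = NULL) {
  w <- .phantom_width(spec, t)
  slab <- frame$slab
  env <- abs(slab[, 1]) <= w / 2 & abs(slab[, 3]) <= spec$h0 / 2
  tex <- 1 + spec$stripe_contrast *
    sin(2 * pi * slab[, 2] / spec$stripe_period)
  emit <- env
  if (!is.null(voids)) {
    act <- voids[voids$t_app <= t, , drop = FALSE]
    if (nrow(act)) {
      vx <- slab[, 1]; vy <- slab[, 2]; vz <- slab[, 3]
      inside_any <- rep(FALSE, length(vx))
      # voids stay strictly inside the envelope (2-2.5 um shell) so the
      # mask pipeline sees enclosed cavities, not surface bays
      for (v in seq_len(nrow(act))) {
        xc <- act$ux[v] * max(0, w / 2 - act$ax[v] - 2.5)
        zc <- act$uz[v] * max(0, spec$h0 / 2 - act$az[v] - 2)
        q <- ((vx - xc) / act$ax[v])^2 + ((vy - act$yc[v]) / act$ay[v])^2 +
          ((vz - zc) / act$az[v])^2
        inside_any <- inside_any | (q <= 1)
      }
      emit <- env & !inside_any
    }
  }
  ef <- numeric(length(env))
  ef[emit] <- spec$i0 * tex[emit]
  if (spec$mode == "dilution") {
    # enforce exact conservation of the total expected envelope signal
    if (!is.null(s_ref) && sum(ef) > 0) ef <- ef * (s_ref / sum(ef))
  } else if (spec$mode == "destruction") {
    ef <- ef * exp(-t / spec$tau_d)
  }
  list(env = array(env, frame$dims), expected = array(ef, frame$dims),
       width = w)
}

#' Generate a synthetic stack series from a phantom spec
#'
#' Renders one two-channel [voxel_stack()] per timestamp. The epi-channel
#' expectation is `beta` times the forward expectation; noise (Poisson
#' shot noise plus Gaussian read noise, clamped at zero and rounded to
#' integer counts) is applied last and independently per channel.
#' Generation is bit-reproducible given the spec (which includes the
#' seed).
#'
#' @param spec a [phantom_spec()].
#' @param keep_truth if `TRUE`, attach the true envelope masks (list of
#'   logical arrays, one per timestamp) and the noiseless expected
#'   forward intensities as attributes `"envelope"` and `"expected"`.
#' @return A [stack_series()]; errors if the tilted, swollen slab touches
#'   the x- or z-faces of the grid at any timestamp (the sample must not
#'   leave the imaging volume).
#' @export
generate_stack_series <- function(spec, keep_truth = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  frame <- .phantom_frame(spec)
  t_max <- max(spec$timestamps)
  voids <- .phantom_voids(spec, t_max)
  # reference total signal: t = 0 envelope (baseline width, no voids)
  s_ref <- NULL
  if (spec$mode == "dilution") {
    e0 <- .phantom_expected(
      within_mode(spec, "inert"), frame, NULL, 0)
    s_ref <- sum(e0$expected)
  }
  stacks <- vector("list", length(spec$timestamps))
  envs <- vector("list", length(spec$timestamps))
  exps <- vector("list", length(spec$timestamps))
  d <- frame$dims
  for (i in seq_along(spec$timestamps)) {
    t <- spec$timestamps[i]
    ex <- .phantom_expected(spec, frame, voids, t, s_ref)
    env <- ex$env
    # the sample must stay inside the imaging volume in x and z
    touches <- any(env[, c(1, d[2]), ]) || any(env[, , c(1, d[3])])
    if (touches)
      stop(sprintf(
        "slab exceeds the grid in x or z at timestamp %g min (width %.1f um); enlarge the grid or reduce tilt/swelling",
        t, ex$width))
    ef <- ex$expected
    ee <- spec$beta * ef
    if (spec$shot_noise || spec$read_sd > 0) {
      n <- length(ef)
      noisy <- function(e) {
        v <- as.numeric(e)
        if (spec$shot_noise)
          v <- rpois(n, v * spec$shot_gain) / spec$shot_gain
        if (spec$read_sd > 0)
          v <- v + rnorm(n, 0, spec$read_sd)
        array(pmax(0, round(v)), dim(e))
      }
      ef_out <- noisy(ef)
      ee_out <- noisy(ee)
    } else {
      ef_out <- ef
      ee_out <- ee
    }
    stacks[[i]] <- voxel_stack(ef_out, ee_out,
                               .spacing_vec(spec$dx, spec$dy, spec$dz), t)
    if (keep_truth) {
      envs[[i]] <- env
      exps[[i]] <- ef
    }
  }
  out <- stack_series(stacks, metadata = list(phantom = spec))
  if (keep_truth) {
    attr(out, "envelope") <- envs
    attr(out, "expected") <- exps
  }
  out
}

# copy of a spec with a different intensity mode (internal)
within_mode <- function(spec, mode) {
  spec$mode <- mode
  spec
}

#' Analytic ground truth for a phantom spec
#'
#' Closed-form feature curves against which measured trajectories are
#' validated: width `w*(t) = w0 (1 + A (1 - exp(-t/tau_s)))`, constant
#' height `h*(t) = h0`, volume `V* = w* h0 L` with `L` the grid length,
#' mean intensity `I*` per regime (constant; diluted as `w0 / w*`; or
#' decaying as `exp(-t/tau_d)`) and cumulative intensity
#' `sum I* = I* V* / voxel volume`. Epi-channel curves are `beta` times
#' the forward curves.
#'
#' @param spec a [phantom_spec()].
#' @param timestamps times (min) at which to evaluate; defaults to the
#'   spec's own timestamps.
#' @return A data.frame with columns `timestamp`, `w`, `h`, `V`,
#'   `Ibar_f`, `Isum_f`, `Ibar_epi`, `Isum_epi`, `mode`, plus
#'   percent-change columns `dw_pct`, `dh_pct`, `dV_pct`, `dIbar_f_pct`,
#'   `dIsum_f_pct` relative to `t = 0`.
#' @export
ground_truth <- function(spec, timestamps = spec$timestamps) {
  stopifnot(inherits(spec, "phantom_spec"))
  t <- as.numeric(timestamps)
  w <- .phantom_width(spec, t)
  h <- rep(spec$h0, length(t))
  L <- spec$ny * spec$dy
  V <- w * spec$h0 * L
  ibar <- switch(spec$mode,
    inert = rep(spec$i0, length(t)),
    dilution = spec$i0 * spec$w0 / w,
    destruction = spec$i0 * exp(-t / spec$tau_d))
  voxvol <- spec$dx * spec$dy * spec$dz
  isum <- ibar * V / voxvol
  pct <- function(x, x0) 100 * (x - x0) / x0
  data.frame(
    timestamp = t, w = w, h = h, V = V,
    Ibar_f = ibar, Isum_f = isum,
    Ibar_epi = spec$beta * ibar, Isum_epi = spec$beta * isum,
    mode = spec$mode,
    dw_pct = pct(w, spec$w0), dh_pct = pct(h, spec$h0),
    dV_pct = pct(V, spec$w0 * spec$h0 * L),
    dIbar_f_pct = pct(ibar, spec$i0),
    dIsum_f_pct = pct(isum, spec$i0 * spec$w0 * spec$h0 * L / voxvol))
}
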