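#' Specification of a 2D area-swelling phantom
#'
#' Emulates the light-microscopy view of a thin section in the first
#' minute after drug addition, sampled at 1 frame per second: a bright
#' vertical strip (the sample seen from above) on a darker background
#' whose width — and hence area — grows as a saturating exponential.
#' Growth may be laterally inhomogeneous: the half-widths left and right
#' of the original margin expand by independent factors, emulating
#' asymmetric swelling of the outer versus inner dura surface. The
#' default symmetric factors are chosen so the area doubles by t = 30 s,
#' the magnitude observed for highly concentrated vancomycin.
#'
#' Per-side half-width law:
#' `wS(t) = hw0 * (1 + (fS - 1) * (1 - exp(-t / tau_s)))`, S in {L, R};
#' the true area ratio is the mean of the two per-side ratios.
#'
#' @param nx,ny frame size in pixels (columns x, rows y).
#' @param pixel_size pixel pitch (um).
#' @param hw0 baseline half-width of the strip (px to each side of the
#'   margin).
#' @param center_x column of the original margin (strip centre line);
#'   defaults to the frame centre.
#' @param f_left,f_right saturated expansion factor of the left/right
#'   half-width.
#' @param tau_s growth time constant (s). The default
#'   `30 / log(6) ~ 16.7 s` together with factor 2.2 makes the area
#'   ratio exactly 2 at t = 30 s.
#' @param timestamps frame times in seconds (default 0..60 s at 1 fps).
#' @param i0,bg foreground/background expected intensity (counts).
#' @param shot_noise,read_sd noise model as in [phantom_spec()].
#' @param dark_foreground if `TRUE` frames are generated with inverted
#'   contrast (sample darker than background).
#' @param seed integer random seed.
#' @return An object of class `phantom_spec_2d`.
#' @export
phantom_spec_2d <- function(nx = 160, ny = 120, pixel_size = 2,
                            hw0 = 20, center_x = NULL,
                            f_left = 2.2, f_right = 2.2,
                            tau_s = 30 / log(6),
                            timestamps = 0:60,
                            i0 = 100, bg = 5,
                            shot_noise = TRUE, read_sd = 2,
                            dark_foreground = FALSE,
                            seed = 1L) {
  stopifnot(hw0 > 0, f_left >= 1, f_right >= 1, tau_s > 0,
            i0 > bg, bg >= 0)
  timestamps <- as.numeric(timestamps)
  if (any(diff(timestamps) <= 0) || any(timestamps < 0))
    stop("timestamps must be nonnegative and strictly increasing")
  if (is.null(center_x)) center_x <- (nx + 1) / 2
  spec <- structure(
    list(nx = nx, ny = ny, pixel_size = pixel_size, hw0 = hw0,
         center_x = center_x, f_left = f_left, f_right = f_right,
         tau_s = tau_s, timestamps = timestamps, i0 = i0, bg = bg,
         shot_noise = shot_noise, read_sd = read_sd,
         dark_foreground = dark_foreground, seed = as.integer(seed)),
    class = "phantom_spec_2d")
  wl <- hw0 * f_left; wr <- hw0 * f_right
  if (center_x - wl < 2 || center_x + wr > nx - 1)
    stop("strip leaves the frame at saturated width; enlarge the frame")
  spec
}

.area2d_halfwidths <- function(spec, t) {
  g <- 1 - exp(-t / spec$tau_s)
  list(left = spec$hw0 * (1 + (spec$f_left - 1) * g),
       right = spec$hw0 * (1 + (spec$f_right - 1) * g))
}

.area2d_truth_mask <- function(spec, t) {
  hw <- .area2d_halfwidths(spec, t)
  cols <- seq_len(spec$nx)
  inside <- cols >= spec$center_x - hw$left & cols <= spec$center_x + hw$right
  matrix(rep(inside, each = spec$ny), spec$ny, spec$nx)
}

#' Generate a 2D time-lapse frame series from a 2D phantom spec
#'
#' @param spec a [phantom_spec_2d()].
#' @param keep_truth attach the list of true foreground masks as
#'   attribute `"truth"`.
#' @return An object of class `frame_series_2d`: list with `frames`
#'   (list of numeric matrices), `timestamps` (s) and `pixel_size` (um).
#' @export
generate_area_lapse <- function(spec, keep_truth = FALSE) {
  stopifnot(inherits(spec, "phantom_spec_2d"))
  set.seed(spec$seed)
  frames <- vector("list", length(spec$timestamps))
  truth <- vector("list", length(spec$timestamps))
  for (i in seq_along(spec$timestamps)) {
    m <- .area2d_truth_mask(spec, spec$timestamps[i])
    e <- matrix(spec$bg, spec$ny, spec$nx)
    e[m] <- spec$i0
    if (spec$dark_foreground) e <- spec$i0 + spec$bg - e
    if (spec$shot_noise || spec$read_sd > 0) {
      v <- as.numeric(e)
      if (spec$shot_noise) v <- rpois(length(v), v)
      if (spec$read_sd > 0) v <- v + rnorm(length(v), 0, spec$read_sd)
      e <- matrix(pmax(0, round(v)), spec$ny, spec$nx)
    }
    frames[[i]] <- e
    truth[[i]] <- m
  }
  out <- structure(
    list(frames = frames, timestamps = spec$timestamps,
         pixel_size = spec$pixel_size, spec = spec),
    class = "frame_series_2d")
  if (keep_truth) attr(out, "truth") <- truth
  out
}

#' Analytic ground truth for a 2D phantom
#'
#' @param spec a [phantom_spec_2d()].
#' @param timestamps evaluation times (s).
#' @return data.frame with `timestamp`, `area_ratio`, `ratio_left`,
#'   `ratio_right` (per-side half-width ratios).
#' @export
area_ground_truth <- function(spec, timestamps = spec$timestamps) {
  hw <- .area2d_halfwidths(spec, timestamps)
  data.frame(
    timestamp = timestamps,
    area_ratio = (hw$left + hw$right) / (2 * spec$hw0),
    ratio_left = hw$left / spec$hw0,
    ratio_right = hw$right / spec$hw0)
}

#' Write / read a 2D frame series as numbered TIFFs plus a manifest
#'
#' @param series a `frame_series_2d`.
#' @param dir output directory.
#' @return Manifest path, invisibly.
#' @export
write_frame_series <- function(series, dir) {
  stopifnot(inherits(series, "frame_series_2d"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(series$frames))
  for (i in seq_along(series$frames)) {
    p <- sprintf("frame_%04d.tif", i)
    f <- series$frames[[i]]
    sc <- .write_channel_tiff(array(f, c(dim(f), 1)), file.path(dir, p))
    rows[[i]] <- data.frame(path = p, timestamp_s = series$timestamps[i],
                            pixel_size = series$pixel_size, scale = sc)
  }
  mpath <- file.path(dir, "frames_manifest.csv")
  write.csv(do.call(rbind, rows), mpath, row.names = FALSE)
  invisible(mpath)
}

#' @rdname write_frame_series
#' @param manifest_path manifest CSV written by [write_frame_series()].
#' @export
read_frame_series <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  frames <- lapply(seq_len(nrow(man)), function(i) {
    sc <- if ("scale" %in% names(man)) man$scale[i] else 1
    arr <- .read_channel_tiff(file.path(base, man$path[i]), sc)
    arr[, , 1]
  })
  ord <- order(man$timestamp_s)
  structure(
    list(frames = frames[ord], timestamps = man$timestamp_s[ord],
         pixel_size = man$pixel_size[1], spec = NULL),
    class = "frame_series_2d")
}

#' Classify sample versus background in one frame
#'
#' Transparent stand-in for interactive pixel-classification tools: the
#' frame is Gaussian-smoothed, thresholded by Otsu, reduced to its
#' largest 8-connected component, and hole-filled (the 2D version of the
#' 3D tissue-segmentation policy). An optional seeded mode fits a
#' logistic classifier on intensity and local-variance features from a
#' small set of labelled scribbles, for textured real images where a
#' global threshold fails.
#'
#' @param frame numeric matrix.
#' @param smooth_sigma Gaussian smoothing sd in pixels.
#' @param dark_foreground set `TRUE` when the sample is darker than the
#'   background; the frame polarity is flipped before thresholding.
#' @param scribbles optional list with integer index vectors `fg` and
#'   `bg` marking training pixels for the seeded mode.
#' @return Logical matrix (the sample mask). Errors on constant frames
#'   and on empty classification results.
#' @export
classify_frame <- function(frame, smooth_sigma = 1,
                           dark_foreground = FALSE, scribbles = NULL) {
  stopifnot(is.matrix(frame))
  if (max(frame) == min(frame))
    stop("frame is constant; nothing to classify")
  f <- if (dark_foreground) max(frame) - frame else frame
  sm <- as.matrix(EBImage::gblur(EBImage::Image(f), sigma = smooth_sigma))
  if (is.null(scribbles)) {
    mx <- max(sm)
    thr <- as.numeric(EBImage::otsu(EBImage::Image(sm / mx),
                                    range = c(0, 1), levels = 256L)) * mx
    fg <- sm > thr
  } else {
    loc_var <- .local_variance(sm, radius = 2L)
    feats <- data.frame(int = as.numeric(sm), lv = as.numeric(loc_var))
    train <- rbind(
      cbind(feats[scribbles$fg, , drop = FALSE], y = 1),
      cbind(feats[scribbles$bg, , drop = FALSE], y = 0))
    fit <- suppressWarnings(glm(y ~ int + lv, binomial(), data = train))
    prob <- predict(fit, newdata = feats, type = "response")
    fg <- matrix(prob > 0.5, nrow(frame), ncol(frame))
  }
  # largest 8-connected component, then 2D hole fill
  lab <- .label2d(fg)
  if (max(lab) == 0) stop("empty classification result; frame flagged")
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  .fill_holes2d(mask)
}

# 2D labelling/fill reuse the 3D kernels on a single-slice array
.label2d <- function(mask) {
  arr <- array(mask, c(dim(mask), 1))
  .label3d(arr, 26L)[, , 1]
}

.fill_holes2d <- function(mask) {
  d <- dim(mask)
  bg <- .label2d(!mask)
  border_labels <- unique(c(bg[c(1, d[1]), ], bg[, c(1, d[2])]))
  border_labels <- border_labels[border_labels > 0]
  hole <- !mask & !(bg %in% border_labels)
  dim(hole) <- d
  mask | hole
}

.local_variance <- function(m, radius = 2L) {
  k <- matrix(1, 2 * radius + 1, 2 * radius + 1)
  k <- k / sum(k)
  mi <- EBImage::Image(m)
  mu <- as.matrix(EBImage::filter2(mi, k))
  mu2 <- as.matrix(EBImage::filter2(mi^2, k))
  pmax(mu2 - mu^2, 0)
}

#' Area trajectory of a 2D time-lapse
#'
#' Classifies every frame, converts pixel counts to areas, and reports
#' each frame's area ratio to the first frame, overall and per side of
#' the original margin. The margin is the outline of the frame-1 mask;
#' "left" and "right" are defined relative to the margin's principal
#' (long) axis: a pixel is left/right according to the sign of its
#' coordinate along the short axis through the margin centroid.
#'
#' @param frames a `frame_series_2d`.
#' @param smooth_sigma,dark_foreground passed to [classify_frame()].
#' @param max_flagged_frac maximum tolerated fraction of frames whose
#'   classification fails before the whole trajectory errors out.
#' @return An object of class `area_trajectory`: data.frame with
#'   `timestamp`, `area_um2`, `area_ratio`, `ratio_left`, `ratio_right`,
#'   `flagged`; the frame-1 margin mask in attribute `"margin"` and the
#'   per-frame masks in attribute `"masks"`.
#' @export
area_trajectory <- function(frames, smooth_sigma = 1,
                            dark_foreground = FALSE,
                            max_flagged_frac = 0.2) {
  stopifnot(inherits(frames, "frame_series_2d"))
  nf <- length(frames$frames)
  if (nf < 2) stop("need at least 2 frames")
  masks <- vector("list", nf)
  flagged <- logical(nf)
  for (i in seq_len(nf)) {
    masks[[i]] <- tryCatch(
      classify_frame(frames$frames[[i]], smooth_sigma, dark_foreground),
      error = function(e) NULL)
    flagged[i] <- is.null(masks[[i]])
  }
  if (mean(flagged) > max_flagged_frac)
    stop(sprintf("%.0f%% of frames failed classification (> %.0f%% allowed)",
                 100 * mean(flagged), 100 * max_flagged_frac))
  if (flagged[1]) stop("first frame failed classification; no baseline")
  m1 <- masks[[1]]
  # per-side split along the margin's principal axis
  idx <- which(m1, arr.ind = TRUE)
  ctr <- colMeans(idx)
  cv <- stats::cov(idx)
  eg <- eigen(cv, symmetric = TRUE)
  short_axis <- eg$vectors[, 2]  # minor axis: the left/right direction
  if (short_axis[which.max(abs(short_axis))] < 0)
    short_axis <- -short_axis
  side_of <- function(mask) {
    id <- which(mask, arr.ind = TRUE)
    s <- sweep(id, 2, ctr) %*% short_axis
    c(left = sum(s < 0), right = sum(s >= 0))
  }
  px_area <- frames$pixel_size^2
  s1 <- side_of(m1)
  rows <- lapply(seq_len(nf), function(i) {
    if (flagged[i])
      return(data.frame(timestamp = frames$timestamps[i],
                        area_um2 = NA_real_, area_ratio = NA_real_,
                        ratio_left = NA_real_, ratio_right = NA_real_,
                        flagged = TRUE))
    si <- side_of(masks[[i]])
    data.frame(timestamp = frames$timestamps[i],
               area_um2 = sum(masks[[i]]) * px_area,
               area_ratio = sum(masks[[i]]) / sum(m1),
               ratio_left = si[["left"]] / s1[["left"]],
               ratio_right = si[["right"]] / s1[["right"]],
               flagged = FALSE)
  })
  df <- do.call(rbind, rows)
  structure(df, class = c("area_trajectory", "data.frame"),
            margin = m1, masks = masks)
}

#' Interval maps of newly covered area
#'
#' Splits the expansion into maps of newly covered pixels per time
#' interval (default 10 s), the building blocks of a colour-coded
#' swelling-inhomogeneity visualisation. For a monotonically growing
#' sample the interval maps tile `final mask \ first mask` exactly.
#'
#' @param trajectory an [area_trajectory()] result.
#' @param interval interval length in seconds.
#' @return A list with `maps` (list of logical matrices, one per
#'   interval), `breaks` (interval boundary times) and `margin` (frame-1
#'   mask).
#' @export
interval_maps <- function(trajectory, interval = 10) {
  stopifnot(inherits(trajectory, "area_trajectory"))
  masks <- attr(trajectory, "masks")
  ts <- trajectory$timestamp
  ok <- !trajectory$flagged
  breaks <- seq(min(ts), max(ts), by = interval)
  if (max(ts) > max(breaks)) breaks <- c(breaks, max(ts))
  maps <- list()
  prev_i <- which(ok)[1]
  for (b in breaks[-1]) {
    cand <- which(ok & ts <= b)
    i <- cand[length(cand)]
    maps[[length(maps) + 1]] <- masks[[i]] & !masks[[prev_i]]
    prev_i <- i
  }
  list(maps = maps, breaks = breaks, margin = attr(trajectory, "margin"))
}
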