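#' Segmentation parameters
#'
#' Parameters of the joint-tissue-volume segmentation. Defaults follow
#' the package's reference policy: smooth at one voxel, floor the
#' threshold with a border-background model, per-time-point Otsu,
#' 26-connected components with a 5 um merge distance for drifting
#' fragments, a 2-voxel morphological closing and 3D cavity filling
#' (enclosed voids count as sample volume).
#'
#' @param smooth_sigma Gaussian smoothing scale in voxels.
#' @param bg_k multiplier k of the background floor
#'   `mean + k * sd` computed on the lowest-intensity quartile of border
#'   voxels.
#' @param merge_dist distance (um) within which a secondary connected
#'   component is merged into the principal one as a drifting fragment.
#' @param close_radius morphological closing radius in voxels.
#' @param fill_cavities fill voids fully enclosed in 3D.
#' @param min_voxels minimum mask size; below it the time point is
#'   flagged as "sample left imaging volume or signal lost".
#' @param min_separability minimum Otsu effectiveness (between-class
#'   variance fraction, in [0, 1]) of the smoothed forward channel. A
#'   stack containing tissue is strongly bimodal (effectiveness > 0.9
#'   even near SNR 2); pure noise fields sit near 0.6, where Otsu would
#'   carve arbitrary masks out of smoothed noise. Below the floor the
#'   time point is flagged as signal lost. Scale-invariant, like every
#'   other thresholding ingredient.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(smooth_sigma = 1, bg_k = 4, merge_dist = 5,
                       close_radius = 2, fill_cavities = TRUE,
                       min_voxels = 500, min_separability = 0.75) {
  structure(list(smooth_sigma = smooth_sigma, bg_k = bg_k,
                 merge_dist = merge_dist, close_radius = close_radius,
                 fill_cavities = fill_cavities, min_voxels = min_voxels,
                 min_separability = min_separability),
            class = "seg_params")
}

# Gaussian kernel, radius 3 sigma, normalised
.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable 3D Gaussian smoothing (reflect boundary), sigma in voxels
.smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  k <- .gauss_kernel(sigma)
  d <- dim(arr)
  array(.sep_conv_3d(as.numeric(arr), as.integer(d), k, k, k), d)
}

# one global Otsu threshold over all voxels, on this time point's
# smoothed forward channel
.otsu3d <- function(arr) {
  mx <- max(arr)
  if (mx <= 0) return(0)
  v <- as.numeric(arr) / mx
  img <- EBImage::Image(matrix(v, ncol = 1L))
  as.numeric(EBImage::otsu(img, range = c(0, 1), levels = 256L)) * mx
}

# Otsu effectiveness: maximum between-class variance over total
# variance of the (256-bin) intensity histogram; ~1 for well-separated
# bimodal data, markedly lower for unimodal noise
.otsu_effectiveness <- function(arr) {
  v <- as.numeric(arr)
  mx <- max(v)
  if (mx <= 0) return(0)
  v <- v / mx
  counts <- tabulate(pmin(floor(v * 256) + 1L, 256L), 256L)
  p <- counts / sum(counts)
  mids <- (seq_len(256) - 0.5) / 256
  mu_t <- sum(p * mids)
  var_t <- sum(p * (mids - mu_t)^2)
  if (var_t <= 0) return(0)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  max(sb) / var_t
}

# robust background floor from the grid faces: lowest-intensity quartile
# of border voxels (tissue may touch the y-faces; the quartile keeps the
# estimate on background)
.background_floor <- function(arr, k) {
  d <- dim(arr)
  border <- c(arr[c(1, d[1]), , ], arr[, c(1, d[2]), ], arr[, , c(1, d[3])])
  q <- quantile(border, 0.25, names = FALSE)
  low <- border[border <= q]
  mean(low) + k * sd(low)
}

.label3d <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  array(.cc_label_3d(as.logical(mask), as.integer(d),
                     as.integer(connectivity)), d)
}

.dilate3d <- function(mask, rvox) {
  d <- dim(mask)
  array(.binary_dilate_3d(as.logical(mask), as.integer(d),
                          as.numeric(rvox)), d)
}

.erode3d <- function(mask, rvox) {
  d <- dim(mask)
  array(.binary_erode_3d(as.logical(mask), as.integer(d),
                         as.numeric(rvox)), d)
}

# fill background components not connected (6-conn) to the grid border
.fill_cavities3d <- function(mask) {
  d <- dim(mask)
  bg <- .label3d(!mask, 6L)
  border_labels <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ],
                            bg[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0]
  cavity <- !mask & !(bg %in% border_labels)
  dim(cavity) <- d
  list(mask = mask | cavity, n_filled = sum(cavity))
}

.empty_mask_condition <- function(t, n) {
  structure(
    class = c("shg4d_empty_mask", "error", "condition"),
    list(message = sprintf(
      paste("sample left imaging volume or signal lost at t = %g min",
            "(mask of %d voxels below the minimum-size floor)"), t, n),
      call = NULL))
}

#' Segment the joint tissue volume of one z-stack
#'
#' Produces the boolean "sample volume" mask over which all dimensional
#' and intensity features are computed. The pipeline, in order:
#' \enumerate{
#'   \item Gaussian smoothing of the forward channel (geometry is always
#'     derived from the forward signal).
#'   \item A background floor from the lowest-intensity quartile of
#'     border voxels (`mean + k sd`).
#'   \item Threshold = max(background floor, Otsu value of this time
#'     point's smoothed forward channel). Per-time-point Otsu keeps the
#'     segmentation stable while the overall SHG intensity drifts with
#'     the drug interaction; the floor prevents Otsu collapse once the
#'     foreground fades into noise.
#'   \item 26-connected components; the largest is kept, plus every
#'     component lying within the merge distance of it (drifting tissue
#'     fractions still belong to the sample).
#'   \item Morphological closing, then filling of cavities fully
#'     enclosed in 3D: enclosed voids count as sample volume.
#' }
#' Every choice is recorded in the returned provenance.
#'
#' @param stack a [voxel_stack()].
#' @param params a [seg_params()].
#' @return An object of class `tissue_mask`: list with `mask` (logical
#'   array) and `provenance` (threshold, background floor, Otsu value,
#'   smoothing scale, components merged, cavity voxels filled).
#'   Throws a condition of class `shg4d_empty_mask` when the mask falls
#'   below the minimum-size floor (sample left the imaging volume or the
#'   signal was lost).
#' @export
segment_tissue <- function(stack, params = seg_params()) {
  stopifnot(inherits(stack, "voxel_stack"))
  fwd <- stack$forward
  if (max(fwd) == min(fwd))
    stop("forward channel is constant; nothing to segment")
  sm <- .smooth3d(fwd, params$smooth_sigma)
  eta <- .otsu_effectiveness(sm)
  if (eta < params$min_separability)
    stop(.empty_mask_condition(stack$timestamp, 0))
  floor_thr <- .background_floor(sm, params$bg_k)
  otsu_thr <- .otsu3d(sm)
  thr <- max(floor_thr, otsu_thr)
  fg <- sm > thr
  labels <- .label3d(fg, 26L)
  if (max(labels) == 0)
    stop(.empty_mask_condition(stack$timestamp, 0))
  sizes <- tabulate(labels[labels > 0])
  main <- which.max(sizes)
  # the size floor gauges whether a sample is present at all, so it is
  # applied to the principal component before closing can inflate a
  # scattered noise field into a large spurious mask
  if (sizes[main] < params$min_voxels)
    stop(.empty_mask_condition(stack$timestamp, sizes[main]))
  mask <- labels == main
  n_merged <- 0L
  if (max(labels) > 1 && params$merge_dist > 0) {
    # merge distance is surface-to-surface: voxel centres of two
    # fragments whose faces are d apart differ by d + 1 voxel pitch
    rvox <- params$merge_dist / .axis_spacing(stack$spacing) + 1
    near <- .dilate3d(mask, rvox)
    cand <- unique(labels[near & labels > 0 & labels != main])
    if (length(cand)) {
      mask <- mask | (labels %in% cand)
      dim(mask) <- dim(fwd)
      n_merged <- length(cand)
    }
  }
  if (params$close_radius > 0) {
    r <- rep(params$close_radius, 3)
    mask <- .erode3d(.dilate3d(mask, r), r)
  }
  n_filled <- 0L
  if (params$fill_cavities) {
    fc <- .fill_cavities3d(mask)
    mask <- fc$mask
    n_filled <- fc$n_filled
  }
  n <- sum(mask)
  if (n < params$min_voxels)
    stop(.empty_mask_condition(stack$timestamp, n))
  structure(
    list(mask = mask,
         provenance = list(
           threshold = thr, otsu = otsu_thr, separability = eta,
           background_floor = floor_thr,
           smooth_sigma = params$smooth_sigma, bg_k = params$bg_k,
           merge_dist = params$merge_dist,
           close_radius = params$close_radius,
           fill_cavities = params$fill_cavities,
           components_merged = n_merged, cavity_voxels_filled = n_filled,
           mask_voxels = n, timestamp = stack$timestamp)),
    class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<tissue_mask> %d voxels (thr %.3g; %d fragment(s) merged, %d cavity voxels filled)\n",
    p$mask_voxels, p$threshold, p$components_merged,
    p$cavity_voxels_filled))
  invisible(x)
}

#' Overlap (Jaccard) fraction of two masks
#'
#' Intersection over union, used as a QC statistic for inter-time-point
#' segmentation jumps.
#'
#' @param maskA,maskB logical arrays of identical shape (or
#'   `tissue_mask` objects).
#' @return `|A n B| / |A u B|` in [0, 1]; 1 when both masks are empty.
#' @export
mask_overlap <- function(maskA, maskB) {
  if (inherits(maskA, "tissue_mask")) maskA <- maskA$mask
  if (inherits(maskB, "tissue_mask")) maskB <- maskB$mask
  if (!identical(dim(maskA), dim(maskB)))
    stop("masks must have identical shape")
  u <- sum(maskA | maskB)
  if (u == 0) return(1)
  sum(maskA & maskB) / u
}

#' Export a mask as an 8-bit multi-page TIFF for visual inspection
#'
#' @param mask a `tissue_mask` or logical array.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, "tissue_mask")) mask <- mask$mask
  arr <- array(as.numeric(mask), dim(mask))
  .write_channel_tiff(arr * 255, path)
}
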