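#' Principal axes of a tissue mask
#'
#' Eigen-decomposition of the second-moment tensor of the mask voxel
#' coordinates (in micrometres). Axes are signed and assigned to their
#' nearest grid axis and returned in the order (axis 1 ~ y length,
#' axis 2 ~ x width, axis 3 ~ z height); for an ordinary thin section
#' this equals ordering by descending extent (length > width > height),
#' and the proximity assignment keeps the labels correct when a wide,
#' strongly tilted sample's width exceeds the field-of-view-truncated
#' length. Degenerate spectra (e.g. a cube) are tie-broken
#' deterministically by aligning the degenerate subspace with the
#' preferred grid axes, so an untilted object always yields the identity
#' rotation.
#'
#' @param mask a `tissue_mask` or logical 3D array.
#' @param spacing named spacing vector `c(dx, dy, dz)` (um).
#' @return A list with `rotation` (3x3 matrix, columns = principal axes
#'   expressed in (y, x, z) grid coordinates), `tilt_deg` (angle of each
#'   axis from its grid axis) and `extents` (eigenvalue-derived spread,
#'   um).
#' @export
principal_axes <- function(mask, spacing) {
  if (inherits(mask, "tissue_mask")) mask <- mask$mask
  coords <- .mask_coords_um(mask, spacing)
  if (nrow(coords) < 2)
    stop("mask is degenerate (fewer than two voxels); principal axes undefined")
  cov <- stats::cov(coords)
  eg <- eigen(cov, symmetric = TRUE)
  vecs <- eg$vectors
  vals <- eg$values
  # grid axes in (y, x, z) coordinate order; preferred assignment is
  # axis1 -> y, axis2 -> x, axis3 -> z
  pref <- diag(3)
  # Resolve (near-)degenerate eigenvalue blocks by aligning the block's
  # subspace with the preferred grid axes: within such a block the
  # in-plane orientation is statistically unidentifiable (small shape
  # perturbations rotate the eigenvectors freely), so the deterministic
  # choice is the grid projection, which for a slab whose length and
  # width extents approach each other recovers the true axes exactly.
  rel <- abs(diff(vals)) / pmax(vals[1:2], .Machine$double.eps)
  blocks <- split(1:3, cumsum(c(TRUE, rel > 0.2)))
  for (b in blocks) {
    if (length(b) == 1) next
    B <- vecs[, b, drop = FALSE]       # orthonormal basis of the block
    P <- B %*% t(B)                    # projector onto the subspace
    new <- matrix(0, 3, length(b))
    got <- 0
    for (a in b) {                     # project preferred axes in order
      cand <- P %*% pref[, a]
      if (got > 0)
        cand <- cand - new[, 1:got, drop = FALSE] %*%
          crossprod(new[, 1:got, drop = FALSE], cand)
      nc <- sqrt(sum(cand^2))
      if (nc > 1e-8) {
        got <- got + 1
        new[, got] <- cand / nc
      }
    }
    if (got == length(b)) vecs[, b] <- new
  }
  # sign each axis toward its nearest grid axis
  for (a in 1:3) {
    dots <- as.numeric(crossprod(pref, vecs[, a]))
    s <- sign(dots[which.max(abs(dots))])
    if (s < 0) vecs[, a] <- -vecs[, a]
  }
  # Label axes by grid proximity (greedy best-|dot| assignment) and order
  # them (length ~ y, width ~ x, height ~ z). For an ordinary thin
  # section this coincides with descending extent; proximity keeps the
  # labels right when a wide sample's width exceeds the field-of-view-
  # truncated length.
  M <- abs(vecs)  # rows = grid axes (y, x, z), cols = eigen axes
  perm <- integer(3)
  for (step in 1:3) {
    i <- which(M == max(M), arr.ind = TRUE)[1, ]
    perm[i[1]] <- i[2]
    M[i[1], ] <- -1; M[, i[2]] <- -1
  }
  vecs <- vecs[, perm]
  vals <- vals[perm]
  tilt <- acos(pmin(1, abs(vapply(1:3, function(a)
    sum(vecs[, a] * pref[, a]), numeric(1))))) * 180 / pi
  list(rotation = vecs, tilt_deg = tilt, extents = 2 * sqrt(3 * vals))
}

# coordinates (um) of mask voxels in (y, x, z) order
.mask_coords_um <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  sp <- .axis_spacing(spacing)
  cbind(y = idx[, 1] * sp[1], x = idx[, 2] * sp[2], z = idx[, 3] * sp[3])
}

#' Tilt-corrected dimensional features of a tissue mask
#'
#' Volume is exact voxel counting (`V = n dx dy dz`). Width and height
#' are measured in the principal frame: the mean width is the mean, over
#' occupied (length, height) bins, of the occupied extent along the
#' width axis, and the mean height the mean over (length, width) bins of
#' the extent along the height axis. Bin size is the voxel pitch of the
#' grid axis nearest each principal axis, and a bin's extent uses the
#' closed convention `max - min + 1 voxel`. Per-bin mean extents are
#' robust to ragged segmentation edges, where bounding boxes would
#' inflate.
#'
#' @param mask a `tissue_mask` or logical 3D array.
#' @param spacing named spacing vector `c(dx, dy, dz)` (um).
#' @param rotation optional 3x3 rotation from [principal_axes()]; when
#'   `NULL` it is estimated from this mask.
#' @return A list of class `geometry_features`: `V` (um^3), `w`, `h`
#'   (um), `rotation`, `tilt_deg`, `n_voxels`.
#' @export
measure_geometry <- function(mask, spacing, rotation = NULL) {
  if (inherits(mask, "tissue_mask")) mask <- mask$mask
  n <- sum(mask)
  if (n == 0) stop("cannot measure geometry of an empty mask")
  if (is.null(rotation)) {
    pa <- principal_axes(mask, spacing)
    rotation <- pa$rotation
    tilt <- pa$tilt_deg
  } else {
    pref <- diag(3)
    tilt <- acos(pmin(1, abs(vapply(1:3, function(a)
      sum(rotation[, a] * pref[, a]), numeric(1))))) * 180 / pi
  }
  V <- n * .voxel_volume(spacing)
  coords <- .mask_coords_um(mask, spacing)
  ctr <- colMeans(coords)
  rot <- sweep(coords, 2, ctr) %*% rotation  # principal-frame coords
  sp <- .axis_spacing(spacing)
  # pitch along the grid axis nearest each principal axis
  nearest <- vapply(1:3, function(a) which.max(abs(rotation[, a])),
                    integer(1))
  pitch <- sp[nearest]
  # Bins whose voxels touch a grid face are truncated by the field of
  # view (e.g. the glued slab ends cut obliquely when tilted); their
  # extents understate the sample and are excluded from the means. If
  # everything touches a face (pathological mask) all bins are used.
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  fov_cut <- idx[, 1] == 1L | idx[, 1] == d[1] |
    idx[, 2] == 1L | idx[, 2] == d[2] |
    idx[, 3] == 1L | idx[, 3] == d[3]
  dt <- data.table::data.table(
    len = rot[, 1], wid = rot[, 2], hei = rot[, 3], cut = fov_cut)
  dt[, `:=`(lb = floor(len / pitch[1]), wb = floor(wid / pitch[2]),
            hb = floor(hei / pitch[3]))]
  wtab <- dt[, .(ext = max(wid) - min(wid) + pitch[2],
                 cut = any(cut)), by = .(lb, hb)]
  htab <- dt[, .(ext = max(hei) - min(hei) + pitch[3],
                 cut = any(cut)), by = .(lb, wb)]
  if (any(!wtab$cut)) wtab <- wtab[!wtab$cut, ]
  if (any(!htab$cut)) htab <- htab[!htab$cut, ]
  structure(
    list(V = V, w = mean(wtab$ext), h = mean(htab$ext),
         rotation = rotation, tilt_deg = tilt, n_voxels = n),
    class = "geometry_features")
}

#' @export
print.geometry_features <- function(x, ...) {
  cat(sprintf(
    "<geometry_features> V = %.4g um^3, w = %.4g um, h = %.4g um (tilt %.1f/%.1f/%.1f deg)\n",
    x$V, x$w, x$h, x$tilt_deg[1], x$tilt_deg[2], x$tilt_deg[3]))
  invisible(x)
}

#' Mean and cumulative SHG intensity over the sample volume
#'
#' For each channel, the mean voxel intensity over the mask and the
#' cumulative (summed) intensity. Cavity voxels filled by the
#' segmentation are part of the mask and contribute their (near-zero)
#' signal, which is what makes the mean fall while the sum is conserved
#' when fiber bundles drift apart. The identity
#' `sum I = Ibar * n_voxels` holds exactly by construction and is
#' asserted on every call.
#'
#' @param stack a [voxel_stack()].
#' @param mask a `tissue_mask` or logical array of the same shape.
#' @return A list of class `intensity_features`: `Ibar_f`, `Isum_f`,
#'   `Ibar_epi`, `Isum_epi`, `n_voxels`.
#' @export
measure_intensity <- function(stack, mask) {
  stopifnot(inherits(stack, "voxel_stack"))
  if (inherits(mask, "tissue_mask")) mask <- mask$mask
  if (!identical(dim(mask), dim(stack$forward)))
    stop("mask and stack shapes differ")
  n <- sum(mask)
  if (n == 0) stop("cannot measure intensity over an empty mask")
  isum_f <- sum(stack$forward[mask])
  isum_e <- sum(stack$epi[mask])
  ibar_f <- isum_f / n
  ibar_e <- isum_e / n
  stopifnot(isTRUE(all.equal(isum_f, ibar_f * n)),
            isTRUE(all.equal(isum_e, ibar_e * n)))
  structure(
    list(Ibar_f = ibar_f, Isum_f = isum_f,
         Ibar_epi = ibar_e, Isum_epi = isum_e, n_voxels = n),
    class = "intensity_features")
}
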