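# Shared fixtures: all synthetic, generated at test time.

# small, fast phantom grid used by most tests
tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(nx = 48, ny = 32, nz = 36, dx = 1, dy = 1, dz = 1,
                   w0 = 16, h0 = 14, tilt_y = 8, amplitude = 0.5,
                   tau_s = 10, i0 = 100,
                   timestamps = seq(0, 40, by = 8), seed = 42L)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

noiseless <- function(...) {
  tiny_spec(shot_noise = FALSE, read_sd = 0, ...)
}

# axis-aligned solid slab mask in a (ny, nx, nz) grid, centred
solid_slab_mask <- function(ny, nx, nz, wvox, hvox, lvox = ny) {
  m <- array(FALSE, c(ny, nx, nz))
  xs <- floor((nx - wvox) / 2) + seq_len(wvox)
  zs <- floor((nz - hvox) / 2) + seq_len(hvox)
  ys <- floor((ny - lvox) / 2) + seq_len(lvox)
  m[ys, xs, zs] <- TRUE
  m
}

# two-slab stack (for the fragment-merge rule): main slab plus a smaller
# fragment separated by `gap` voxels along x; uniform foreground, zero
# background, no noise
two_slab_stack <- function(gap, fg = 100) {
  ny <- 24; nx <- 64; nz <- 24
  arr <- array(0, c(ny, nx, nz))
  arr[, 8:27, 6:19] <- fg             # main slab, 20 voxels wide
  arr[, (28 + gap):(37 + gap), 6:19] <- fg  # fragment, 10 voxels wide
  voxel_stack(arr, 0.5 * arr, c(dx = 1, dy = 1, dz = 1), 0)
}

unit_spacing <- c(dx = 1, dy = 1, dz = 1)

# independent per-bin extent scan (oracle for measure_geometry's w/h):
# plain loops over occupied bins in the unrotated grid frame
brute_force_extents <- function(mask, spacing = unit_spacing) {
  idx <- which(mask, arr.ind = TRUE)
  dy <- spacing[["dy"]]; dx <- spacing[["dx"]]; dz <- spacing[["dz"]]
  y <- idx[, 1] * dy; x <- idx[, 2] * dx; z <- idx[, 3] * dz
  yc <- y - mean(y); xc <- x - mean(x); zc <- z - mean(z)
  lb <- floor(yc / dy); wb <- floor(xc / dx); hb <- floor(zc / dz)
  wext <- c(); key <- paste(lb, hb)
  for (k in unique(key)) {
    sel <- key == k
    wext <- c(wext, max(xc[sel]) - min(xc[sel]) + dx)
  }
  hext <- c(); key <- paste(lb, wb)
  for (k in unique(key)) {
    sel <- key == k
    hext <- c(hext, max(zc[sel]) - min(zc[sel]) + dz)
  }
  list(w = mean(wext), h = mean(hext))
}
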