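#' Two-channel SHG z-stack at one time point
#'
#' Bundles the forward- and epi-detected intensity grids of a single
#' z-stack together with its voxel spacing and acquisition timestamp.
#' Arrays are stored as `y x x x z` (rows = y, columns = x, pages = z),
#' matching the on-disk TIFF layout (pages = z-slices).
#'
#' @param forward,epi numeric 3D arrays of nonnegative intensities, same
#'   shape.
#' @param spacing named numeric vector `c(dx, dy, dz)` in micrometres.
#' @param timestamp acquisition time in minutes since drug addition
#'   (t = 0 at drug addition).
#' @return An object of class `voxel_stack`.
#' @export
voxel_stack <- function(forward, epi, spacing, timestamp) {
  stopifnot(is.array(forward), length(dim(forward)) == 3L)
  if (!identical(dim(forward), dim(epi)))
    stop("forward and epi channels must have identical shape")
  spacing <- .spacing_vec(spacing[["dx"]], spacing[["dy"]], spacing[["dz"]])
  if (any(spacing <= 0)) stop("voxel spacings must be positive")
  if (min(forward) < 0 || min(epi) < 0)
    stop("intensities must be nonnegative")
  structure(
    list(forward = forward, epi = epi, spacing = spacing,
         timestamp = as.numeric(timestamp)),
    class = "voxel_stack"
  )
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$forward)
  cat(sprintf(
    "<voxel_stack> t = %.2f min, grid %d x %d x %d (y,x,z), spacing %.3g/%.3g/%.3g um\n",
    x$timestamp, d[1], d[2], d[3],
    x$spacing[["dx"]], x$spacing[["dy"]], x$spacing[["dz"]]))
  invisible(x)
}

#' Time series of z-stacks
#'
#' An ordered sequence of [voxel_stack()] objects sharing one grid shape
#' and voxel spacing, sorted by strictly increasing timestamp.
#'
#' @param stacks list of `voxel_stack` objects.
#' @param metadata optional named list of acquisition metadata.
#' @return An object of class `stack_series`.
#' @export
stack_series <- function(stacks, metadata = list()) {
  if (length(stacks) == 0) stop("a stack series needs at least one stack")
  ts <- vapply(stacks, function(s) s$timestamp, numeric(1))
  ord <- order(ts)
  stacks <- stacks[ord]
  ts <- ts[ord]
  if (any(diff(ts) <= 0))
    stop("timestamps must be strictly increasing (duplicates found)")
  shapes <- vapply(stacks, function(s) paste(dim(s$forward), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L)
    stop("all stacks in a series must share one grid shape; found: ",
         paste(unique(shapes), collapse = ", "))
  sp <- vapply(stacks, function(s) paste(signif(s$spacing, 10), collapse = "/"),
               character(1))
  if (length(unique(sp)) != 1L)
    stop("all stacks in a series must share one voxel spacing; found: ",
         paste(unique(sp), collapse = ", "))
  structure(
    list(stacks = stacks, spacing = stacks[[1]]$spacing,
         timestamps = ts, metadata = metadata),
    class = "stack_series"
  )
}

#' @export
length.stack_series <- function(x) length(x$stacks)

#' @export
print.stack_series <- function(x, ...) {
  cat(sprintf("<stack_series> %d time points, t = %s min\n",
              length(x$stacks),
              paste(signif(x$timestamps, 4), collapse = ", ")))
  invisible(x)
}

# Write one channel as a multi-page TIFF (pages = z, rows = y, cols = x).
# Integer data up to 65535 are stored losslessly as 16-bit (scale 1);
# other data are rescaled to [0, 1] and stored as 32-bit samples, with
# the scale factor returned for the caller's manifest.
.write_channel_tiff <- function(arr, path) {
  nz <- dim(arr)[3]
  pages <- lapply(seq_len(nz), function(k) arr[, , k, drop = TRUE])
  is_int <- max(arr) <= 65535 && all(arr == round(arr))
  if (is_int) {
    tiff::writeTIFF(lapply(pages, function(p) p / 65535),
                    path, bits.per.sample = 16L, compression = "none")
    return(invisible(1))
  }
  scale <- max(arr)
  tiff::writeTIFF(lapply(pages, function(p) p / scale),
                  path, bits.per.sample = 32L, compression = "none")
  invisible(scale)
}

.read_channel_tiff <- function(path, scale = 1) {
  if (scale == 1) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
  }
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr * scale
}

#' Write a stack series to disk as TIFFs plus a manifest
#'
#' Each time point becomes a pair of multi-page TIFFs (forward and epi
#' channel; pages = z-slices, rows = y, columns = x) and one row of a CSV
#' manifest with columns `path_forward`, `path_epi`, `timestamp_min`,
#' `dx`, `dy`, `dz`. Timestamps live in the manifest, not in TIFF
#' metadata.
#'
#' @param series a [stack_series()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix for the TIFFs.
#' @return Path of the written manifest, invisibly.
#' @export
write_stack_series <- function(series, dir, prefix = "stack") {
  stopifnot(inherits(series, "stack_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(series$stacks))
  for (i in seq_along(series$stacks)) {
    s <- series$stacks[[i]]
    pf <- sprintf("%s_t%03d_f.tif", prefix, i)
    pe <- sprintf("%s_t%03d_epi.tif", prefix, i)
    sf <- .write_channel_tiff(s$forward, file.path(dir, pf))
    se <- .write_channel_tiff(s$epi, file.path(dir, pe))
    rows[[i]] <- data.frame(
      path_forward = pf, path_epi = pe, timestamp_min = s$timestamp,
      dx = s$spacing[["dx"]], dy = s$spacing[["dy"]], dz = s$spacing[["dz"]],
      scale_forward = sf, scale_epi = se)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a stack series from a manifest
#'
#' Loads the TIFF pairs listed in a manifest CSV and assembles a
#' [stack_series()]. Rows may appear in any order: the series is sorted by
#' the manifest's `timestamp_min` column, never by file order. All stacks
#' must share one grid shape and spacing; differing slice counts across
#' *samples* are fine (each sample is its own series), but within a series
#' the geometry must be constant.
#'
#' @param manifest_path path to a manifest CSV with columns
#'   `path_forward`, `path_epi`, `timestamp_min`, `dx`, `dy`, `dz`.
#'   Relative TIFF paths resolve against the manifest's directory.
#' @return A [stack_series()].
#' @export
read_series <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("path_forward", "path_epi", "timestamp_min", "dx", "dy", "dz")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  stacks <- vector("list", nrow(man))
  shapes <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    pf <- resolve(man$path_forward[i])
    pe <- resolve(man$path_epi[i])
    for (p in c(pf, pe)) if (!file.exists(p))
      stop("stack file referenced by manifest is missing: ", p)
    sf <- if ("scale_forward" %in% names(man)) man$scale_forward[i] else 1
    se <- if ("scale_epi" %in% names(man)) man$scale_epi[i] else 1
    fwd <- .read_channel_tiff(pf, sf)
    epi <- .read_channel_tiff(pe, se)
    shapes[i] <- paste(dim(fwd), collapse = "x")
    stacks[[i]] <- voxel_stack(
      fwd, epi, .spacing_vec(man$dx[i], man$dy[i], man$dz[i]),
      man$timestamp_min[i])
  }
  if (length(unique(shapes)) != 1L) {
    bad <- split(man$path_forward, shapes)
    stop("stacks in one series must share one geometry; found shapes ",
         paste(names(bad), collapse = " vs "), " (",
         paste(vapply(bad, function(x) x[1], character(1)),
               collapse = ", "), ")")
  }
  stack_series(stacks, metadata = list(manifest = manifest_path))
}

#' Write a feature trajectory to CSV
#'
#' Emits a tidy table (one row per time point and feature) preceded by
#' `#`-prefixed metadata lines recording the package version, the run
#' seed, and a hash of the configuration used.
#'
#' @param trajectory a [build_trajectory()] result.
#' @param path output CSV path.
#' @param seed optional integer recorded in the header.
#' @return `path`, invisibly.
#' @export
write_features <- function(trajectory, path, seed = NA_integer_) {
  stopifnot(inherits(trajectory, "feature_trajectory"))
  df <- as.data.frame(trajectory)
  if (nrow(df) == 0) stop("refusing to write an empty trajectory")
  df[] <- lapply(df, as.numeric)
  long <- data.table::melt(
    data.table::as.data.table(df), id.vars = "timestamp",
    variable.name = "feature", value.name = "value",
    variable.factor = FALSE)
  long <- long[order(long$timestamp, long$feature), ]
  cfg <- attr(trajectory, "config")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# shg4d_version: %s",
            as.character(utils::packageVersion("shg4d"))),
    sprintf("# seed: %s", seed),
    sprintf("# config_hash: %s", config_hash(cfg)),
    sprintf("# crop_limit_min: %s", attr(trajectory, "crop_limit"))
  ), con)
  utils::write.table(
    data.frame(timestamp = format(long$timestamp, digits = 17, trim = TRUE),
               feature = long$feature,
               value = format(long$value, digits = 17, trim = TRUE)),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a feature table written by [write_features()]
#'
#' @param path CSV path.
#' @return A data.frame with columns `timestamp`, `feature`, `value`, with
#'   the header metadata in attribute `"metadata"`.
#' @export
read_features <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                 stringsAsFactors = FALSE)
  df$timestamp <- as.numeric(df$timestamp)
  df$value <- suppressWarnings(as.numeric(df$value))
  attr(df, "metadata") <- sub("^# ", "", meta)
  df
}

#' Hash of a configuration object
#'
#' MD5 of the deparsed configuration, used to stamp output tables so a run
#' can be matched to the exact parameter set that produced it.
#'
#' @param config any R object (typically a parameter list).
#' @return A character MD5 digest.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config), tf)
  unname(tools::md5sum(tf))
}
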