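#' Trajectory configuration
#'
#' @param crop_limit upper time border in minutes; records at exactly the
#'   limit are retained, later ones dropped. All series are cropped to
#'   one window so drugs can be compared like for like.
#' @param seg a [seg_params()] parameter set.
#' @param tau_R cumulative-retention tolerance of the mode classifier: a
#'   sample whose median cumulative-signal retention falls below
#'   `1 - tau_R` is called intrinsically destructive.
#' @param tau_W width-gain threshold (percent points) above which a
#'   sample counts as swollen.
#' @return A list of class `traj_config`.
#' @export
traj_config <- function(crop_limit = 50, seg = seg_params(),
                        tau_R = 0.15, tau_W = 10) {
  structure(list(crop_limit = crop_limit, seg = seg,
                 tau_R = tau_R, tau_W = tau_W),
            class = "traj_config")
}

#' Build a baseline-normalised feature trajectory from a stack series
#'
#' Runs segmentation and feature extraction per time point, drops time
#' points flagged as lost (sample left the imaging volume or signal
#' gone), crops the series to the configured window, and computes
#' percent changes `100 (x(t) - x(t0)) / x(t0)` of every feature against
#' the first retained record. The baseline is the first *retained*
#' record, matching an acquisition reality where the first stack lands a
#' few minutes after drug addition: swelling faster than the mounting
#' time is invisible here and is the 2D area module's job.
#'
#' @param series a [stack_series()].
#' @param config a [traj_config()].
#' @return An object of class `feature_trajectory`: a data.frame with one
#'   row per retained time point (absolute features, percent-change
#'   columns, QC columns `overlap_prev` and `tilt_w_deg`), with dropped
#'   records and their reasons in attribute `"omitted"` and the config in
#'   attribute `"config"`.
#' @export
build_trajectory <- function(series, config = traj_config()) {
  stopifnot(inherits(series, "stack_series"))
  keep <- series$timestamps <= config$crop_limit
  stacks <- series$stacks[keep]
  omitted <- list()
  if (any(!keep))
    omitted <- lapply(series$timestamps[!keep], function(t)
      list(timestamp = t, reason = sprintf(
        "beyond crop limit of %g min", config$crop_limit)))
  rows <- list()
  prev_mask <- NULL
  for (s in stacks) {
    res <- tryCatch({
      tm <- segment_tissue(s, config$seg)
      geo <- measure_geometry(tm, s$spacing)
      ity <- measure_intensity(s, tm)
      ov <- if (is.null(prev_mask)) NA_real_ else
        mask_overlap(prev_mask, tm)
      prev_mask <- tm$mask
      data.frame(
        timestamp = s$timestamp, V = geo$V, w = geo$w, h = geo$h,
        Ibar_f = ity$Ibar_f, Isum_f = ity$Isum_f,
        Ibar_epi = ity$Ibar_epi, Isum_epi = ity$Isum_epi,
        n_voxels = geo$n_voxels, overlap_prev = ov,
        tilt_len_deg = geo$tilt_deg[1], tilt_w_deg = geo$tilt_deg[2],
        tilt_h_deg = geo$tilt_deg[3])
    }, shg4d_empty_mask = function(e) {
      omitted[[length(omitted) + 1]] <<- list(
        timestamp = s$timestamp, reason = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  if (length(rows) < 2)
    stop("trajectory undefined: fewer than 2 usable time points")
  df <- do.call(rbind, rows)
  pct <- function(x) 100 * (x - x[1]) / x[1]
  for (f in c("V", "w", "h", "Ibar_f", "Isum_f", "Ibar_epi", "Isum_epi"))
    df[[paste0("d", f, "_pct")]] <- pct(df[[f]])
  structure(df,
            class = c("feature_trajectory", "data.frame"),
            omitted = omitted, config = config,
            crop_limit = config$crop_limit)
}

#' 2D correlation between two feature trajectories
#'
#' Pairs two feature columns as a time-ordered path and summarises it by
#' a least-squares slope through the origin and the Pearson correlation.
#' Intended pairs are the percent-change paths (`dw_pct`, `dIbar_f_pct`),
#' (`dw_pct`, `dIsum_f_pct`) — width gain against mean or cumulative
#' signal loss — and the raw channel pair (`Ibar_f`, `Ibar_epi`). The
#' slope is anchored at the origin because percent-change paths start at
#' (0, 0) by construction.
#'
#' @param trajectory a [build_trajectory()] result.
#' @param x_feature,y_feature column names of the trajectory.
#' @return A list of class `feature_correlation`: `slope` (through the
#'   origin), `pearson`, and `path` (data.frame `timestamp`, `x`, `y`).
#' @export
correlate_features <- function(trajectory, x_feature = "dw_pct",
                               y_feature = "dIbar_f_pct") {
  stopifnot(inherits(trajectory, "feature_trajectory"))
  df <- as.data.frame(trajectory)
  for (f in c(x_feature, y_feature))
    if (!f %in% names(df)) stop("unknown feature column: ", f)
  if (nrow(df) < 3)
    stop("correlation needs at least 3 retained time points")
  x <- df[[x_feature]]; y <- df[[y_feature]]
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0)
    stop("zero-variance x feature: ", x_feature)
  slope <- sum(x * y) / sum(x * x)
  structure(
    list(x_feature = x_feature, y_feature = y_feature,
         slope = slope, pearson = stats::cor(x, y),
         path = data.frame(timestamp = df$timestamp, x = x, y = y)),
    class = "feature_correlation")
}

#' @export
print.feature_correlation <- function(x, ...) {
  cat(sprintf("<feature_correlation> %s vs %s: slope %.3f, r = %.3f (%d points)\n",
              x$y_feature, x$x_feature, x$slope, x$pearson,
              nrow(x$path)))
  invisible(x)
}

#' Classify the damage mode of a trajectory
#'
#' Formalises the two-scenario reasoning behind the width/intensity
#' signatures: if fiber bundles merely drift apart (voids open up inside
#' the sample), the mean SHG signal per voxel falls while the cumulative
#' signal over the sample volume is conserved; if the collagen's
#' molecular order is destroyed, mean and cumulative signal fall
#' together. With the cumulative-retention statistic
#' `R = median_t Isum(t) / Isum(t0)` and the width-gain statistic
#' `W = max dw%`:
#' \itemize{
#'   \item `intrinsic_destruction` if `R < 1 - tau_R` (regardless of W),
#'   \item `bundle_drifting` if `R >= 1 - tau_R` and `W >= tau_W`,
#'   \item `inert` if `R >= 1 - tau_R` and `W < tau_W`.
#' }
#' The default thresholds (`tau_R` = 0.15, `tau_W` = 10 percent points)
#' are calibration choices validated on phantoms.
#'
#' @param trajectory a [build_trajectory()] result.
#' @param tau_R,tau_W classifier thresholds (retention tolerance;
#'   width-gain percent points).
#' @param channel channel for the retention statistic; the forward
#'   channel (the geometry channel) is the default.
#' @return A list of class `mode_of_action`: `label`, `R`, `W`, `slope`
#'   (of mean-signal loss vs width gain), and the thresholds used.
#' @export
classify_mode <- function(trajectory, tau_R = 0.15, tau_W = 10,
                          channel = c("f", "epi")) {
  stopifnot(inherits(trajectory, "feature_trajectory"))
  channel <- match.arg(channel)
  df <- as.data.frame(trajectory)
  isum <- df[[paste0("Isum_", channel)]]
  R <- median(isum / isum[1])
  W <- max(df$dw_pct)
  slope <- if (stats::var(df$dw_pct) > 0)
    sum(df$dw_pct * df$dIbar_f_pct) / sum(df$dw_pct^2) else NA_real_
  label <- if (R < 1 - tau_R) "intrinsic_destruction"
  else if (W >= tau_W) "bundle_drifting"
  else "inert"
  structure(
    list(label = label, R = R, W = W, slope = slope,
         tau_R = tau_R, tau_W = tau_W, channel = channel),
    class = "mode_of_action")
}

#' @export
print.mode_of_action <- function(x, ...) {
  cat(sprintf(
    "<mode_of_action> %s (retention R = %.3f, width gain W = %.1f%%; tau_R = %g, tau_W = %g)\n",
    x$label, x$R, x$W, x$tau_R, x$tau_W))
  invisible(x)
}

#' Feature-versus-time plot of a trajectory
#'
#' Percent-change curves of width, height, volume and mean/cumulative
#' forward signal against interaction time.
#'
#' @param trajectory a [build_trajectory()] result.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory) {
  df <- as.data.frame(trajectory)
  feats <- c("dw_pct", "dh_pct", "dV_pct", "dIbar_f_pct", "dIsum_f_pct")
  long <- data.table::melt(
    data.table::as.data.table(df[, c("timestamp", feats)]),
    id.vars = "timestamp", variable.name = "feature",
    variable.factor = FALSE)
  ggplot2::ggplot(long, ggplot2::aes(
    x = timestamp, y = value, colour = feature)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time after drug addition (min)",
                  y = "change vs baseline (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' 2D correlation-path plot
#'
#' @param correlation a [correlate_features()] result.
#' @return A ggplot object.
#' @export
plot_correlation <- function(correlation) {
  p <- correlation$path
  ggplot2::ggplot(p, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_path() + ggplot2::geom_point() +
    ggplot2::geom_abline(slope = correlation$slope, intercept = 0,
                         linetype = 2, colour = "grey50") +
    ggplot2::labs(x = correlation$x_feature, y = correlation$y_feature) +
    ggplot2::theme_minimal()
}
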