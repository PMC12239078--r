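#' Tracking configuration
#'
#' Acquisition parameters of the particle-tracking videos and the MSD
#' analysis settings. Defaults follow a typical 1 Hz spinning-disk
#' acquisition: 1 s between frames, 0.114 um pixels, 182.83 um frame
#' width.
#'
#' @param frame_interval seconds between frames (lag-time unit).
#' @param pixel_size micrometers per pixel (used when positions arrive in
#'   pixel units).
#' @param frame_width field-of-view width in micrometers.
#' @param analysis_time analyzed window in seconds (`NULL` = full video).
#' @param frame_filter minimum number of detected frames for a trajectory
#'   to enter the analysis.
#' @param msd_fit_fraction fraction of available lags used for the
#'   anomalous-exponent fit (default 0.10, the MSD log-slope convention);
#'   at least 2 lag points are always used.
#' @param dimensionality spatial dimensionality n of the tracking (2 for
#'   planar confocal tracking).
#' @return list of class `tracking_config`.
#' @export
tracking_config <- function(frame_interval = 1.0, pixel_size = 0.114,
                            frame_width = 182.83, analysis_time = NULL,
                            frame_filter = 1L, msd_fit_fraction = 0.10,
                            dimensionality = 2L) {
  check_scalar(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  if (!is.null(analysis_time)) {
    check_scalar(analysis_time, "analysis_time", lower = 0, strict_lower = TRUE)
  }
  check_count(frame_filter, "frame_filter", min = 1L)
  check_scalar(msd_fit_fraction, "msd_fit_fraction", lower = 0, upper = 1, strict_lower = TRUE)
  structure(
    list(
      frame_interval = frame_interval, pixel_size = pixel_size,
      frame_width = frame_width, analysis_time = analysis_time,
      frame_filter = as.integer(frame_filter),
      msd_fit_fraction = msd_fit_fraction,
      dimensionality = as.integer(dimensionality)
    ),
    class = "tracking_config"
  )
}

## canonical long-format trajectory table: particle, frame, x_um, y_um
assert_trajectories <- function(traj) {
  stopifnot(is.data.frame(traj))
  need <- c("particle", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(traj))
  if (length(miss)) {
    stop("trajectory table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(traj$x_um)) || any(!is.finite(traj$y_um))) {
    stop("non-finite positions in trajectory table", call. = FALSE)
  }
  invisible(traj)
}

#' Frame filter: keep trajectories detected in enough frames
#'
#' @param traj long trajectory table (`particle,frame,x_um,y_um`).
#' @param frame_filter minimum number of detected frames (>= 1).
#' @return filtered trajectory table.
#' @export
apply_frame_filter <- function(traj, frame_filter) {
  assert_trajectories(traj)
  check_count(frame_filter, "frame_filter", min = 1L)
  counts <- table(traj$particle)
  keep <- names(counts)[counts >= frame_filter]
  out <- traj[traj$particle %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict trajectories to an analysis-time window
#'
#' Drops every frame whose time `frame * frame_interval` is at or beyond
#' `analysis_time`, so an analysis time of 10 s at 1 s/frame keeps frames
#' 0..9. Shortening the window reduces the error of the MSD log-slope at
#' the cost of fewer displacement pairs.
#'
#' @param traj long trajectory table.
#' @param analysis_time window length in seconds.
#' @param config a [tracking_config()] (supplies `frame_interval`).
#' @return truncated trajectory table.
#' @export
truncate_to_analysis_time <- function(traj, analysis_time, config = tracking_config()) {
  assert_trajectories(traj)
  check_scalar(analysis_time, "analysis_time", lower = 0, strict_lower = TRUE)
  out <- traj[traj$frame * config$frame_interval < analysis_time, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Time-averaged mean-squared displacement of one trajectory
#'
#' For each lag tau = k * frame_interval the MSD is the mean of
#' \deqn{[x(t+\tau)-x(t)]^2 + [y(t+\tau)-y(t)]^2}
#' over all frame pairs (i, i + k) present in the trajectory (overlapping
#' windows, the convention of particle-tracking toolchains). Gapped
#' trajectories contribute only pairs where both frames were detected; no
#' interpolation is performed. Lags with no pairs are omitted.
#'
#' @param traj trajectory table for a single particle (or columns
#'   `frame`, `x_um`, `y_um`).
#' @param config a [tracking_config()].
#' @return data.frame of class `msd_curve` with `lag_s`, `msd_um2`,
#'   `n_pairs`, or an empty curve (attribute `degenerate = TRUE`) for a
#'   single-point trajectory.
#' @export
compute_msd <- function(traj, config = tracking_config()) {
  stopifnot(is.data.frame(traj), all(c("frame", "x_um", "y_um") %in% names(traj)))
  if ("particle" %in% names(traj) && length(unique(traj$particle)) > 1L) {
    stop("`compute_msd` expects a single particle; see `msd_per_particle`", call. = FALSE)
  }
  o <- order(traj$frame)
  frames <- as.integer(traj$frame[o])
  if (anyDuplicated(frames)) stop("duplicated frames in trajectory", call. = FALSE)
  x <- traj$x_um[o]
  y <- traj$y_um[o]
  if (length(frames) < 2L) {
    out <- data.frame(lag_s = numeric(0), msd_um2 = numeric(0), n_pairs = integer(0))
    class(out) <- c("msd_curve", "data.frame")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  span <- max(frames) - min(frames)
  lags_k <- seq_len(span)
  rows <- lapply(lags_k, function(k) {
    j <- match(frames + k, frames)
    ok <- !is.na(j)
    if (!any(ok)) return(NULL)
    d2 <- (x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2
    data.frame(lag_s = k * config$frame_interval, msd_um2 = mean(d2), n_pairs = sum(ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("msd_curve", "data.frame")
  attr(out, "degenerate") <- FALSE
  out
}

#' MSD curves for every particle in a trajectory table
#'
#' @param traj long trajectory table.
#' @param config a [tracking_config()].
#' @return named list of [compute_msd()] curves, one per particle.
#' @export
msd_per_particle <- function(traj, config = tracking_config()) {
  assert_trajectories(traj)
  lapply(split(traj, traj$particle, drop = TRUE), compute_msd, config = config)
}

#' Effective diffusivity from an MSD value
#'
#' D_eff = MSD / (2 n tau) with n the dimensionality. By convention the
#' per-trajectory summary D_eff is evaluated at the first lag.
#'
#' @param msd_value MSD in um^2.
#' @param lag lag time in seconds (> 0).
#' @param config a [tracking_config()] (supplies n).
#' @return effective diffusivity in um^2/s.
#' @export
deff_from_msd <- function(msd_value, lag, config = tracking_config()) {
  if (any(lag <= 0)) stop("`lag` must be positive", call. = FALSE)
  msd_value / (2 * config$dimensionality * lag)
}

#' Stokes-Einstein diffusivity of a sphere in a viscous medium
#'
#' D_w = k_B T / (6 pi eta r): the theoretical free diffusivity used as
#' the unhindered reference for particles of known radius. Water at
#' 37 degC has eta ~= 6.9e-4 Pa s.
#'
#' @param radius particle radius in micrometers.
#' @param viscosity dynamic viscosity in Pa s.
#' @param temperature absolute temperature in kelvin.
#' @return diffusivity in um^2/s.
#' @examples
#' stokes_einstein_dw(0.1)  # 0.2 um bead in water at 37 degC: ~3.3 um^2/s
#' @export
stokes_einstein_dw <- function(radius, viscosity = 6.9e-4,
                               temperature = .default_temperature) {
  check_scalar(radius, "radius", lower = 0, strict_lower = TRUE)
  check_scalar(viscosity, "viscosity", lower = 0, strict_lower = TRUE)
  check_scalar(temperature, "temperature", lower = 0, strict_lower = TRUE)
  d_m2_s <- .kB * temperature / (6 * pi * viscosity * (radius * 1e-6))
  d_m2_s * 1e12
}

#' Hindrance ratio D_w / D_eff
#'
#' Ratio of the theoretical free diffusivity in water to the measured
#' effective diffusivity in the matrix; values above 1 quantify how much
#' the network hinders transport.
#'
#' @param d_w free diffusivity (um^2/s).
#' @param d_eff effective diffusivity in the matrix (um^2/s).
#' @return dimensionless ratio; `Inf` with a warning when `d_eff` is 0.
#' @export
dw_deff_ratio <- function(d_w, d_eff) {
  if (any(d_eff < 0) || any(d_w < 0)) stop("diffusivities must be non-negative", call. = FALSE)
  if (any(d_eff == 0)) {
    warning("zero effective diffusivity: infinite hindrance", call. = FALSE)
  }
  d_w / d_eff
}

#' Anomalous-diffusion fit of an MSD curve
#'
#' Fits the power law \deqn{MSD(\tau) = 4 D_0 \tau^{\alpha}} by ordinary
#' least squares of log10 MSD on log10 tau over the short-lag window
#' (lags up to `msd_fit_fraction` of the maximum available lag, minimum 2
#' lag points). The slope is the anomalous exponent alpha, the intercept
#' gives the generalized diffusivity D_0 = 10^intercept / 4, and the
#' trajectory is classified into a transport mode via
#' [classify_transport()]. D_eff is attached from the first lag.
#'
#' @param msd an [compute_msd()] curve.
#' @param config a [tracking_config()].
#' @return object of class `anomalous_fit` with `alpha`, `d0`, `deff`,
#'   `r2`, `transport_class`, `flags`, `n_lags_used`.
#' @export
fit_alpha <- function(msd, config = tracking_config()) {
  stopifnot(inherits(msd, "msd_curve"))
  degenerate_fit <- function(flag, alpha = NA_real_, class = "unclassified") {
    structure(
      list(
        alpha = alpha, d0 = NA_real_,
        deff = if (nrow(msd)) deff_from_msd(msd$msd_um2[1], msd$lag_s[1], config) else NA_real_,
        r2 = NA_real_, transport_class = class, flags = flag, n_lags_used = 0L
      ),
      class = "anomalous_fit"
    )
  }
  if (nrow(msd) < 2L) return(degenerate_fit("unfit: fewer than 2 lags"))
  n_use <- max(2L, floor(config$msd_fit_fraction * nrow(msd)))
  win <- msd[seq_len(min(n_use, nrow(msd))), , drop = FALSE]
  if (all(win$msd_um2 == 0)) {
    fit <- degenerate_fit("degenerate: all-zero MSD in fit window",
      alpha = 0, class = "immobile"
    )
    return(fit)
  }
  usable <- win$msd_um2 > 0
  if (sum(usable) < 2L) return(degenerate_fit("unfit: fewer than 2 positive-MSD lags"))
  win <- win[usable, , drop = FALSE]
  ols <- lm(log10(msd_um2) ~ log10(lag_s), data = win)
  alpha <- unname(coef(ols)[2])
  d0 <- 10^unname(coef(ols)[1]) / 4
  ss_tot <- sum((log10(win$msd_um2) - mean(log10(win$msd_um2)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(ols)^2) / ss_tot else 1
  cls <- classify_transport(alpha)
  structure(
    list(
      alpha = alpha, d0 = d0,
      deff = deff_from_msd(msd$msd_um2[1], msd$lag_s[1], config),
      r2 = r2, transport_class = cls$class,
      flags = cls$flags, n_lags_used = nrow(win)
    ),
    class = "anomalous_fit"
  )
}

#' @export
print.anomalous_fit <- function(x, ...) {
  cat(sprintf(
    "Anomalous-diffusion fit: alpha = %.3f (%s), D0 = %.4g um^2/s^alpha, D_eff = %.4g um^2/s\n",
    x$alpha, x$transport_class, x$d0, x$deff
  ))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Transport-mode classification of an anomalous exponent
#'
#' Bins the exponent into the four conventional transport modes:
#' immobile (alpha < 0.2), subdiffusive (0.2 <= alpha < 0.9), diffusive
#' (0.9 <= alpha < 1.2), active transport (alpha >= 1.2). The bins are
#' contiguous and half-open (closed on the left) so every finite alpha is
#' assigned deterministically. Negative estimates — a finite-sample
#' artifact of flat MSD curves — clamp to immobile with a flag.
#'
#' @param alpha anomalous exponent (scalar).
#' @return list with `class` and `flags` (character, possibly empty).
#' @export
classify_transport <- function(alpha) {
  if (is.na(alpha) || !is.finite(alpha)) {
    return(list(class = "unclassified", flags = "non-finite alpha"))
  }
  flags <- character(0)
  if (alpha < 0) {
    flags <- "negative alpha clamped to immobile"
    alpha <- 0
  }
  class <- if (alpha < 0.2) "immobile"
  else if (alpha < 0.9) "subdiffusive"
  else if (alpha < 1.2) "diffusive"
  else "active"
  list(class = class, flags = flags)
}

.transport_levels <- c("immobile", "subdiffusive", "diffusive", "active")

#' Transport-mode ratios over an ensemble of fits
#'
#' Percentages of each transport mode over classified particles. With
#' `exclude_active = TRUE` actively transported particles (alpha >= 1.2,
#' typically flow or drift artifacts in a passive gel) are removed before
#' percentages are computed and their count reported.
#'
#' @param fits list of [fit_alpha()] results, or a character vector of
#'   class labels.
#' @param exclude_active drop active-transport particles first?
#' @return list with `percent` (named numeric over modes, summing to
#'   100), `n_retained`, `n_excluded`.
#' @export
transport_mode_ratios <- function(fits, exclude_active = FALSE) {
  classes <- if (is.character(fits)) fits
  else vapply(fits, function(f) f$transport_class, character(1))
  classes <- classes[classes %in% .transport_levels]
  n_excluded <- 0L
  if (exclude_active) {
    n_excluded <- sum(classes == "active")
    classes <- classes[classes != "active"]
  }
  if (!length(classes)) stop("no classified particles retained", call. = FALSE)
  levels_out <- if (exclude_active) setdiff(.transport_levels, "active") else .transport_levels
  tab <- table(factor(classes, levels = levels_out))
  pct <- setNames(100 * as.vector(tab) / sum(tab), levels_out)
  list(percent = pct, n_retained = length(classes), n_excluded = n_excluded)
}

#' Ensemble particle-tracking analysis
#'
#' Runs the standard chain on a long trajectory table: analysis-time
#' truncation, frame filter, per-particle MSD, anomalous-exponent fit and
#' transport classification, plus ensemble summaries (medians are used
#' throughout because D_eff distributions in gels are heavy-tailed).
#'
#' @param traj long trajectory table (`particle,frame,x_um,y_um`).
#' @param config a [tracking_config()]; its `analysis_time` and
#'   `frame_filter` are applied when set.
#' @param exclude_active drop active-transport particles from the ratio
#'   summary?
#' @return object of class `tracking_summary`: list with `per_particle`
#'   (data.frame of alpha, d0, deff, class per particle), `ratios`,
#'   `median_alpha`, `ensemble_class` (transport class of the ensemble
#'   median alpha), `median_deff`, `msd_range`, `deff_range`,
#'   `n_particles`.
#' @export
track_analyze <- function(traj, config = tracking_config(), exclude_active = FALSE) {
  assert_trajectories(traj)
  if (!is.null(config$analysis_time)) {
    traj <- truncate_to_analysis_time(traj, config$analysis_time, config)
  }
  if (config$frame_filter > 1L) traj <- apply_frame_filter(traj, config$frame_filter)
  if (!nrow(traj)) stop("no trajectories retained after filtering", call. = FALSE)
  curves <- msd_per_particle(traj, config)
  fits <- lapply(curves, fit_alpha, config = config)
  per <- data.frame(
    particle = names(fits),
    alpha = vapply(fits, function(f) f$alpha, numeric(1)),
    d0 = vapply(fits, function(f) f$d0, numeric(1)),
    deff = vapply(fits, function(f) f$deff, numeric(1)),
    transport_class = vapply(fits, function(f) f$transport_class, character(1)),
    row.names = NULL
  )
  msd1 <- vapply(curves, function(m) if (nrow(m)) m$msd_um2[1] else NA_real_, numeric(1))
  ratios <- transport_mode_ratios(per$transport_class, exclude_active = exclude_active)
  med_alpha <- median(per$alpha, na.rm = TRUE)
  structure(
    list(
      per_particle = per, ratios = ratios,
      median_alpha = med_alpha,
      ## class of the typical particle: robust to the per-particle spread
      ## of short-window alpha estimates
      ensemble_class = classify_transport(med_alpha)$class,
      median_deff = median(per$deff, na.rm = TRUE),
      msd_range = range(msd1, na.rm = TRUE),
      deff_range = range(per$deff, na.rm = TRUE),
      n_particles = nrow(per),
      config = config
    ),
    class = "tracking_summary"
  )
}

#' @export
print.tracking_summary <- function(x, ...) {
  cat(sprintf("Particle-tracking summary over %d particles\n", x$n_particles))
  cat(sprintf(
    "  median alpha = %.3f (%s), median D_eff = %.4g um^2/s\n",
    x$median_alpha, x$ensemble_class, x$median_deff
  ))
  cat(sprintf(
    "  MSD(first lag) range [%.4g, %.4g] um^2; D_eff range [%.4g, %.4g] um^2/s\n",
    x$msd_range[1], x$msd_range[2], x$deff_range[1], x$deff_range[2]
  ))
  pct <- x$ratios$percent
  cat("  transport modes:", paste(sprintf("%s %.1f%%", names(pct), pct), collapse = ", "))
  if (x$ratios$n_excluded > 0) cat(sprintf(" (%d active excluded)", x$ratios$n_excluded))
  cat("\n")
  invisible(x)
}
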