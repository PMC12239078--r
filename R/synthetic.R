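#' Trajectory simulation specification
#'
#' Parameters of the 2D anomalous-diffusion trajectory generator. The
#' ensemble MSD of mobile particles obeys
#' \deqn{E[\Delta r^2(\tau)] = 4 D_0 \tau^{\alpha}} exactly; alpha = 1
#' gives Brownian motion, alpha < 1 subdiffusion, alpha > 1
#' superdiffusion. Defaults mirror a 1 Hz, 100 s acquisition with
#' 0.114 um pixels and a 182.83 um frame.
#'
#' @param n_particles number of particles.
#' @param n_frames frames per trajectory (>= 2).
#' @param frame_interval seconds between frames.
#' @param pixel_size micrometers per pixel (recorded for pixel-unit
#'   export).
#' @param frame_width field width in micrometers (initial positions are
#'   uniform in it; motion is not clipped at the boundary).
#' @param d0 generalized diffusivity, um^2/s^alpha.
#' @param alpha anomalous exponent in (0, 2).
#' @param loc_noise_sd localization noise sd per coordinate, um. Centroid
#'   trackers report positions with sub-pixel error; noise is added to
#'   positions, not increments.
#' @param immobile_fraction fraction of particles that are pure
#'   localization noise around a fixed point, in [0, 1].
#' @param dropout_prob per-frame detection-loss probability in [0, 1);
#'   removed frames leave gaps with explicit frame indices.
#' @param seed integer seed; identical spec + seed reproduces the output
#'   exactly.
#' @return list of class `trajectory_sim_spec`.
#' @export
trajectory_sim_spec <- function(n_particles = 100L, n_frames = 100L,
                                frame_interval = 1.0, pixel_size = 0.114,
                                frame_width = 182.83, d0 = 0.05, alpha = 1,
                                loc_noise_sd = 0.02, immobile_fraction = 0,
                                dropout_prob = 0, seed = 1L) {
  spec <- list(
    n_particles = check_count(n_particles, "n_particles"),
    n_frames = check_count(n_frames, "n_frames", min = 2L),
    frame_interval = check_scalar(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE),
    pixel_size = check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE),
    frame_width = check_scalar(frame_width, "frame_width", lower = 0, strict_lower = TRUE),
    d0 = check_scalar(d0, "d0", lower = 0, strict_lower = TRUE),
    alpha = check_scalar(alpha, "alpha", lower = 0, upper = 2,
      strict_lower = TRUE, strict_upper = TRUE
    ),
    loc_noise_sd = check_scalar(loc_noise_sd, "loc_noise_sd", lower = 0),
    immobile_fraction = check_scalar(immobile_fraction, "immobile_fraction", lower = 0, upper = 1),
    dropout_prob = check_scalar(dropout_prob, "dropout_prob", lower = 0, upper = 1,
      strict_upper = TRUE
    ),
    seed = check_count(seed, "seed", min = 0L)
  )
  class(spec) <- "trajectory_sim_spec"
  spec
}

## Cholesky factor of the fractional-Gaussian-noise increment covariance
## for m steps with Hurst index H and lag-1 increment variance sigma2:
## cov(inc_i, inc_j) = sigma2/2 (|k+1|^2H - 2|k|^2H + |k-1|^2H), k = |i-j|.
## One factorization serves every particle of the ensemble.
fgn_chol <- function(m, hurst, sigma2) {
  k <- 0:(m - 1)
  gamma_k <- sigma2 / 2 *
    (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) + abs(k - 1)^(2 * hurst))
  cov <- stats::toeplitz(gamma_k)
  chol(cov)
}

#' Generate 2D anomalous-diffusion trajectories
#'
#' Mobile particles follow fractional Brownian motion with Hurst index
#' alpha/2: increments per axis are fractional Gaussian noise with the
#' exact target covariance, synthesized by multiplying standard normals
#' with the Cholesky factor of the increment covariance (exact for any
#' ensemble size; one factorization is shared across particles).
#' Immobile particles sit at a fixed point. Independent Gaussian
#' localization noise is then added to every reported position, and
#' frames are dropped independently with `dropout_prob` to emulate
#' detection loss.
#'
#' @param spec a [trajectory_sim_spec()].
#' @return long-format data.frame `particle, frame, x_um, y_um` (frames
#'   0-based, positions in micrometers), with the spec stored in the
#'   `sim_spec` attribute.
#' @examples
#' traj <- gen_trajectories(trajectory_sim_spec(n_particles = 5, seed = 42))
#' head(traj)
#' @export
gen_trajectories <- function(spec) {
  stopifnot(inherits(spec, "trajectory_sim_spec"))
  with_seed(spec$seed, {
    np <- spec$n_particles
    nf <- spec$n_frames
    m <- nf - 1L
    dt <- spec$frame_interval
    sigma2 <- 2 * spec$d0 * dt^spec$alpha # per-axis lag-1 increment variance
    n_immobile <- round(spec$immobile_fraction * np)
    mobile <- rep(TRUE, np)
    if (n_immobile > 0) mobile[seq_len(n_immobile)] <- FALSE

    x0 <- runif(np, 0, spec$frame_width)
    y0 <- runif(np, 0, spec$frame_width)
    x <- matrix(rep(x0, each = nf), nrow = nf)
    y <- matrix(rep(y0, each = nf), nrow = nf)

    n_mobile <- sum(mobile)
    if (n_mobile > 0) {
      if (spec$alpha == 1) {
        inc_x <- matrix(rnorm(m * n_mobile, sd = sqrt(sigma2)), m)
        inc_y <- matrix(rnorm(m * n_mobile, sd = sqrt(sigma2)), m)
      } else {
        cf <- fgn_chol(m, spec$alpha / 2, sigma2)
        inc_x <- t(matrix(rnorm(n_mobile * m), n_mobile) %*% cf)
        inc_y <- t(matrix(rnorm(n_mobile * m), n_mobile) %*% cf)
      }
      x[-1, mobile] <- x[1, mobile][col(inc_x)] + apply(inc_x, 2, cumsum)
      y[-1, mobile] <- y[1, mobile][col(inc_y)] + apply(inc_y, 2, cumsum)
    }

    if (spec$loc_noise_sd > 0) {
      x <- x + rnorm(nf * np, sd = spec$loc_noise_sd)
      y <- y + rnorm(nf * np, sd = spec$loc_noise_sd)
    }

    keep <- if (spec$dropout_prob > 0) {
      matrix(runif(nf * np) >= spec$dropout_prob, nf)
    } else {
      matrix(TRUE, nf, np)
    }

    out <- data.frame(
      particle = rep(seq_len(np), each = nf)[keep],
      frame = rep(0:(nf - 1), np)[keep],
      x_um = x[keep],
      y_um = y[keep]
    )
    o <- order(out$particle, out$frame)
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "sim_spec") <- spec
    out
  })
}

#' FRAP trace simulation specification
#'
#' @param a0 post-bleach intensity floor (normalized).
#' @param a1 recovery amplitude (a0 + a1 <= 1 + small tolerance).
#' @param d diffusivity, um^2/s.
#' @param w bleach-spot radius, um (a 20 um diameter spot has w = 10).
#' @param t_bleach bleach time, s.
#' @param duration trace length, s (> t_bleach).
#' @param sample_interval sampling step, s.
#' @param acq_decay_rate acquisition-photobleaching rate, 1/s, applied to
#'   the bleach and reference channels.
#' @param noise_sd Gaussian noise sd on all channels (normalized units).
#' @param seed integer seed.
#' @return list of class `frap_sim_spec`.
#' @export
frap_sim_spec <- function(a0 = 0.2, a1 = 0.75, d = 1.0, w = 10, t_bleach = 3,
                          duration = 150, sample_interval = 0.5,
                          acq_decay_rate = 0, noise_sd = 0.01, seed = 1L) {
  check_scalar(a0, "a0", lower = 0)
  check_scalar(a1, "a1", lower = 0)
  if (a0 + a1 > 1 + 1e-6) {
    stop("a0 + a1 must not exceed 1 (normalized recovery)", call. = FALSE)
  }
  spec <- list(
    a0 = a0, a1 = a1,
    d = check_scalar(d, "d", lower = 0, strict_lower = TRUE),
    w = check_scalar(w, "w", lower = 0, strict_lower = TRUE),
    t_bleach = check_scalar(t_bleach, "t_bleach", lower = 0, strict_lower = TRUE),
    duration = check_scalar(duration, "duration", lower = t_bleach, strict_lower = TRUE),
    sample_interval = check_scalar(sample_interval, "sample_interval",
      lower = 0, strict_lower = TRUE
    ),
    acq_decay_rate = check_scalar(acq_decay_rate, "acq_decay_rate", lower = 0),
    noise_sd = check_scalar(noise_sd, "noise_sd", lower = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  class(spec) <- "frap_sim_spec"
  spec
}

#' Generate a FRAP trace
#'
#' The bleach-ROI channel equals 1 before the bleach and follows the
#' circular-spot recovery model ([frap_model()] with tau = w^2/D) after
#' it, multiplied by the acquisition-photobleaching decay
#' exp(-acq_decay_rate t). The reference channel carries the decay
#' alone and the background channel is zero; Gaussian noise of sd
#' `noise_sd` is added to all three. Double normalization therefore
#' recovers the noise-free model curve.
#'
#' @param spec a [frap_sim_spec()].
#' @return a [frap_trace()] with the spec in the `sim_spec` attribute.
#' @export
gen_frap_trace <- function(spec) {
  stopifnot(inherits(spec, "frap_sim_spec"))
  with_seed(spec$seed, {
    t <- seq(0, spec$duration, by = spec$sample_interval)
    tau <- spec$w^2 / spec$d
    post <- t > spec$t_bleach
    signal <- numeric(length(t))
    signal[!post] <- 1
    signal[post] <- frap_model(t[post], spec$a0, spec$a1, tau, spec$t_bleach)
    decay <- exp(-spec$acq_decay_rate * t)
    i_frap <- signal * decay + rnorm(length(t), sd = spec$noise_sd)
    i_ref <- decay + rnorm(length(t), sd = spec$noise_sd)
    i_back <- rnorm(length(t), sd = spec$noise_sd)
    out <- frap_trace(t, i_frap, i_ref, i_back, t_bleach = spec$t_bleach)
    attr(out, "sim_spec") <- spec
    out
  })
}

#' Pore-image simulation specification
#'
#' Binary-contrast micrograph emulation: dark elliptical pores on a
#' bright background, with intensity bands chosen on either side of the
#' fixed pore threshold (75) so the binarization ground truth is exact.
#'
#' @param image_shape c(rows, cols) in pixels.
#' @param scale nanometers per pixel.
#' @param n_pores number of ellipses to place (non-overlapping, by
#'   rejection).
#' @param pore_axes_range c(min, max) ellipse semi-axes in nanometers.
#' @param pore_intensity_range integer gray levels of pore pixels, within
#'   [0, 75].
#' @param background_intensity_range integer gray levels of background,
#'   within (75, 255].
#' @param seed integer seed.
#' @return list of class `pore_image_sim_spec`.
#' @export
pore_image_sim_spec <- function(image_shape = c(512L, 512L), scale = 10,
                                n_pores = 20L, pore_axes_range = c(100, 400),
                                pore_intensity_range = c(0L, 50L),
                                background_intensity_range = c(150L, 255L),
                                seed = 1L) {
  stopifnot(length(image_shape) == 2L, length(pore_axes_range) == 2L)
  if (pore_intensity_range[2] > 75 || pore_intensity_range[1] < 0) {
    stop("pore intensities must lie within [0, 75]", call. = FALSE)
  }
  if (background_intensity_range[1] <= 75 || background_intensity_range[2] > 255) {
    stop("background intensities must lie within (75, 255]", call. = FALSE)
  }
  if (pore_axes_range[1] <= 0 || diff(pore_axes_range) < 0) {
    stop("invalid `pore_axes_range`", call. = FALSE)
  }
  spec <- list(
    image_shape = as.integer(image_shape),
    scale = check_scalar(scale, "scale", lower = 0, strict_lower = TRUE),
    n_pores = check_count(n_pores, "n_pores"),
    pore_axes_range = pore_axes_range,
    pore_intensity_range = as.integer(pore_intensity_range),
    background_intensity_range = as.integer(background_intensity_range),
    seed = check_count(seed, "seed", min = 0L)
  )
  class(spec) <- "pore_image_sim_spec"
  spec
}

#' Generate a synthetic pore micrograph with analytic ground truth
#'
#' Places non-overlapping ellipses (rejection sampling with a bounded
#' retry budget) and rasterizes them into an 8-bit image. The ground
#' truth records the exact analytic Feret diameters of each ellipse:
#' for semi-axes a >= b, Feret max = 2a and Feret min = 2b.
#'
#' @param spec a [pore_image_sim_spec()].
#' @return list with `image` (a [micrograph()]) and `truth` (data.frame
#'   `pore, center_row, center_col, semi_major_nm, semi_minor_nm,
#'   angle_rad, feret_max_nm, feret_min_nm`).
#' @export
gen_pore_image <- function(spec) {
  stopifnot(inherits(spec, "pore_image_sim_spec"))
  with_seed(spec$seed, {
    nr <- spec$image_shape[1]
    nc <- spec$image_shape[2]
    ax_px <- spec$pore_axes_range / spec$scale
    mean_area <- pi * mean(ax_px)^2
    if (spec$n_pores * mean_area > 0.5 * nr * nc) {
      stop("requested pores cover more than half the image: placement infeasible",
        call. = FALSE
      )
    }
    placed <- data.frame(
      pore = integer(0), center_row = numeric(0), center_col = numeric(0),
      semi_major_nm = numeric(0), semi_minor_nm = numeric(0), angle_rad = numeric(0)
    )
    tries <- 0L
    max_tries <- 200L * spec$n_pores
    while (nrow(placed) < spec$n_pores) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("ellipse placement failed after bounded retries", call. = FALSE)
      }
      a <- runif(1, ax_px[1], ax_px[2])
      b <- runif(1, ax_px[1], min(a, ax_px[2]))
      ang <- runif(1, 0, pi)
      r0 <- runif(1, a + 2, nr - a - 2)
      c0 <- runif(1, a + 2, nc - a - 2)
      ## conservative non-overlap: bounding circles separated by 2 px
      if (nrow(placed)) {
        dd <- sqrt((placed$center_row - r0)^2 + (placed$center_col - c0)^2)
        if (any(dd < a + placed$semi_major_nm / spec$scale + 2)) next
      }
      placed <- rbind(placed, data.frame(
        pore = nrow(placed) + 1L, center_row = r0, center_col = c0,
        semi_major_nm = a * spec$scale, semi_minor_nm = b * spec$scale,
        angle_rad = ang
      ))
    }
    img <- matrix(
      sample(spec$background_intensity_range[1]:spec$background_intensity_range[2],
        nr * nc,
        replace = TRUE
      ),
      nr, nc
    )
    rr <- row(img)
    cc <- col(img)
    pore_vals <- spec$pore_intensity_range[1]:spec$pore_intensity_range[2]
    for (i in seq_len(nrow(placed))) {
      a <- placed$semi_major_nm[i] / spec$scale
      b <- placed$semi_minor_nm[i] / spec$scale
      th <- placed$angle_rad[i]
      ## pixel centers at (r - 0.5, c - 0.5) in the corner-point frame
      u <- (rr - 0.5 - placed$center_row[i]) * cos(th) +
        (cc - 0.5 - placed$center_col[i]) * sin(th)
      v <- -(rr - 0.5 - placed$center_row[i]) * sin(th) +
        (cc - 0.5 - placed$center_col[i]) * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      img[inside] <- sample(pore_vals, sum(inside), replace = TRUE)
    }
    placed$feret_max_nm <- 2 * placed$semi_major_nm
    placed$feret_min_nm <- 2 * placed$semi_minor_nm
    list(image = micrograph(img, spec$scale), truth = placed)
  })
}

#' Rheology sweep simulation specification
#'
#' @param g0 modulus scale, Pa (G' at omega = 1 rad/s).
#' @param exponent power-law slope of G' vs omega (weak gels: near 0).
#' @param loss_ratio G''/G' (constant across the sweep; < 1 for a gel).
#' @param freq_range c(min, max) angular frequency, rad/s.
#' @param n_points sweep points (log-spaced).
#' @param k_flow consistency index of the flow curve, Pa s^n.
#' @param n_flow flow index; < 1 gives shear thinning.
#' @param noise_rel relative multiplicative noise on all readings.
#' @param seed integer seed.
#' @return list of class `rheology_sim_spec`.
#' @export
rheology_sim_spec <- function(g0 = 100, exponent = 0.05, loss_ratio = 0.3,
                              freq_range = c(0.63, 60), n_points = 20L,
                              k_flow = 5, n_flow = 0.4, noise_rel = 0.01,
                              seed = 1L) {
  stopifnot(length(freq_range) == 2L, freq_range[1] > 0, diff(freq_range) > 0)
  spec <- list(
    g0 = check_scalar(g0, "g0", lower = 0, strict_lower = TRUE),
    exponent = check_scalar(exponent, "exponent"),
    loss_ratio = check_scalar(loss_ratio, "loss_ratio", lower = 0, strict_lower = TRUE),
    freq_range = freq_range,
    n_points = check_count(n_points, "n_points", min = 2L),
    k_flow = check_scalar(k_flow, "k_flow", lower = 0, strict_lower = TRUE),
    n_flow = check_scalar(n_flow, "n_flow", lower = 0, upper = 1, strict_lower = TRUE),
    noise_rel = check_scalar(noise_rel, "noise_rel", lower = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  class(spec) <- "rheology_sim_spec"
  spec
}

#' Generate an oscillation sweep and a flow curve
#'
#' G'(omega) = g0 omega^exponent, G'' = loss_ratio G', with
#' multiplicative log-normal-free noise (1 + eps); the flow curve is the
#' power-law eta = k_flow gammadot^(n_flow - 1) over 0.1-500 1/s.
#'
#' @param spec a [rheology_sim_spec()].
#' @return list with `sweep` (an [oscillation_sweep()]) and `flow` (a
#'   [flow_curve()]).
#' @export
gen_rheology_sweep <- function(spec) {
  stopifnot(inherits(spec, "rheology_sim_spec"))
  with_seed(spec$seed, {
    omega <- exp(seq(log(spec$freq_range[1]), log(spec$freq_range[2]),
      length.out = spec$n_points
    ))
    gp <- spec$g0 * omega^spec$exponent * (1 + rnorm(spec$n_points, sd = spec$noise_rel))
    gl <- spec$loss_ratio * spec$g0 * omega^spec$exponent *
      (1 + rnorm(spec$n_points, sd = spec$noise_rel))
    shear <- exp(seq(log(0.1), log(500), length.out = spec$n_points))
    eta <- spec$k_flow * shear^(spec$n_flow - 1) *
      (1 + rnorm(spec$n_points, sd = spec$noise_rel))
    list(
      sweep = oscillation_sweep(omega, pmax(gp, 0), pmax(gl, 0)),
      flow = flow_curve(shear, pmax(eta, .Machine$double.eps))
    )
  })
}

#' Binding series simulation specification
#'
#' @param kd dissociation constant, mg/mL.
#' @param ligand_conc fixed ligand concentration (same unit scale as the
#'   target; a micromolar dye is ~0 on a mg/mL axis).
#' @param conc_max top target concentration, mg/mL.
#' @param dilution_factor serial dilution factor (> 1).
#' @param n_points number of capillaries (>= 4).
#' @param f_unbound,f_bound response of free and fully bound ligand.
#' @param noise_sd Gaussian noise sd on the response.
#' @param seed integer seed.
#' @return list of class `binding_sim_spec`.
#' @export
binding_sim_spec <- function(kd = 0.5, ligand_conc = 0, conc_max = 5,
                             dilution_factor = 2, n_points = 12L,
                             f_unbound = 800, f_bound = 900, noise_sd = 1,
                             seed = 1L) {
  spec <- list(
    kd = check_scalar(kd, "kd", lower = 0, strict_lower = TRUE),
    ligand_conc = check_scalar(ligand_conc, "ligand_conc", lower = 0),
    conc_max = check_scalar(conc_max, "conc_max", lower = 0, strict_lower = TRUE),
    dilution_factor = check_scalar(dilution_factor, "dilution_factor",
      lower = 1, strict_lower = TRUE
    ),
    n_points = check_count(n_points, "n_points", min = 4L),
    f_unbound = check_scalar(f_unbound, "f_unbound"),
    f_bound = check_scalar(f_bound, "f_bound"),
    noise_sd = check_scalar(noise_sd, "noise_sd", lower = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  class(spec) <- "binding_sim_spec"
  spec
}

#' Generate a binding dilution series
#'
#' Serial twofold-style dilution of the target with responses from the
#' quadratic isotherm plus Gaussian noise.
#'
#' @param spec a [binding_sim_spec()].
#' @return a [binding_series()] with the spec in the `sim_spec`
#'   attribute.
#' @export
gen_binding_series <- function(spec) {
  stopifnot(inherits(spec, "binding_sim_spec"))
  with_seed(spec$seed, {
    conc <- serial_dilution(spec$conc_max, spec$dilution_factor, spec$n_points)
    resp <- binding_isotherm(conc, spec$ligand_conc, spec$kd,
      spec$f_unbound, spec$f_bound
    ) + rnorm(spec$n_points, sd = spec$noise_sd)
    out <- binding_series(conc, resp, ligand_conc = spec$ligand_conc)
    attr(out, "sim_spec") <- spec
    out
  })
}
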