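#' Theoretical hydrogel mesh size from the storage modulus
#'
#' Estimates the mesh size xi of a gel network from its storage modulus
#' under the cubic-lattice (rubber-elasticity) scaling
#' \deqn{\xi = (k_B T / G')^{1/3}}
#' where \eqn{k_B} is the Boltzmann constant. Each network strand is
#' assigned one unit of thermal energy per cell of volume \eqn{\xi^3}.
#'
#' @param g_prime storage modulus G' in pascals (vector allowed). If your
#'   values are in MPa (as moduli of stiff gels are often tabulated), set
#'   `modulus_unit = "MPa"` rather than converting silently: a missed
#'   factor of 1e6 is the dominant failure mode for this formula.
#' @param temperature absolute temperature in kelvin (default 310.15 K,
#'   i.e. 37 degC, the usual mucus measurement temperature).
#' @param modulus_unit `"Pa"` (default) or `"MPa"`.
#' @return object of class `mesh_estimate`: a data.frame with columns
#'   `storage_modulus_pa`, `temperature_k`, `mesh_size_m`, `mesh_size_nm`.
#' @examples
#' mesh_size_from_modulus(75)            # weak gel, ~38.5 nm
#' mesh_size_from_modulus(0.026, modulus_unit = "MPa")
#' @seealso [modulus_from_mesh_size()] for the inverse transform.
#' @export
mesh_size_from_modulus <- function(g_prime, temperature = .default_temperature,
                                   modulus_unit = c("Pa", "MPa")) {
  modulus_unit <- match.arg(modulus_unit)
  if (!is.numeric(g_prime) || length(g_prime) < 1L || any(!is.finite(g_prime))) {
    stop("`g_prime` must be finite and numeric", call. = FALSE)
  }
  if (any(g_prime <= 0)) stop("`g_prime` must be positive", call. = FALSE)
  check_scalar(temperature, "temperature", lower = 0, strict_lower = TRUE)
  g_pa <- if (modulus_unit == "MPa") g_prime * 1e6 else g_prime
  xi <- (.kB * temperature / g_pa)^(1 / 3)
  out <- data.frame(
    storage_modulus_pa = g_pa,
    temperature_k = temperature,
    mesh_size_m = xi,
    mesh_size_nm = xi * 1e9
  )
  class(out) <- c("mesh_estimate", "data.frame")
  out
}

#' Storage modulus implied by a mesh size
#'
#' Inverse of [mesh_size_from_modulus()]: \eqn{G' = k_B T / \xi^3}. Used to
#' cross-validate microscopy-derived pore sizes against the measured
#' modulus.
#'
#' @param mesh_size mesh size in meters (use `mesh_size_nm * 1e-9` for
#'   nanometer inputs); vector allowed.
#' @param temperature absolute temperature in kelvin.
#' @return storage modulus in pascals.
#' @examples
#' modulus_from_mesh_size(47.77e-9)  # ~39.3 Pa
#' @export
modulus_from_mesh_size <- function(mesh_size, temperature = .default_temperature) {
  if (!is.numeric(mesh_size) || any(!is.finite(mesh_size)) || any(mesh_size <= 0)) {
    stop("`mesh_size` must be positive and finite", call. = FALSE)
  }
  check_scalar(temperature, "temperature", lower = 0, strict_lower = TRUE)
  .kB * temperature / mesh_size^3
}

#' @export
print.mesh_estimate <- function(x, ...) {
  cat("Theoretical mesh size (cubic-lattice estimate)\n")
  cat(sprintf("  T = %.2f K\n", x$temperature_k[1]))
  df <- data.frame(
    `G' [Pa]` = signif(x$storage_modulus_pa, 4),
    `xi [nm]` = signif(x$mesh_size_nm, 4),
    check.names = FALSE
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Oscillation sweep container
#'
#' @param angular_frequency angular frequency omega in rad/s, strictly
#'   increasing.
#' @param storage_modulus G' in Pa, non-negative.
#' @param loss_modulus G'' in Pa, non-negative.
#' @return data.frame of class `oscillation_sweep`.
#' @export
oscillation_sweep <- function(angular_frequency, storage_modulus, loss_modulus) {
  n <- length(angular_frequency)
  if (n == 0L) stop("empty sweep", call. = FALSE)
  if (length(storage_modulus) != n || length(loss_modulus) != n) {
    stop("sweep columns must have equal length", call. = FALSE)
  }
  if (any(!is.finite(angular_frequency)) || any(angular_frequency <= 0) ||
      is.unsorted(angular_frequency, strictly = TRUE)) {
    stop("`angular_frequency` must be positive and strictly increasing", call. = FALSE)
  }
  if (any(storage_modulus < 0) || any(loss_modulus < 0)) {
    stop("moduli must be non-negative", call. = FALSE)
  }
  out <- data.frame(
    omega_rad_s = angular_frequency,
    g_prime_pa = storage_modulus,
    g_loss_pa = loss_modulus
  )
  class(out) <- c("oscillation_sweep", "data.frame")
  out
}

#' Flow curve container
#'
#' @param shear_rate shear rate in 1/s, positive, increasing.
#' @param apparent_viscosity apparent viscosity in Pa s, positive.
#' @return data.frame of class `flow_curve`.
#' @export
flow_curve <- function(shear_rate, apparent_viscosity) {
  if (length(shear_rate) != length(apparent_viscosity)) {
    stop("flow-curve columns must have equal length", call. = FALSE)
  }
  if (any(shear_rate <= 0) || any(apparent_viscosity <= 0)) {
    stop("flow-curve values must be positive", call. = FALSE)
  }
  if (is.unsorted(shear_rate, strictly = TRUE)) {
    stop("`shear_rate` must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(shear_rate_1_s = shear_rate, viscosity_pa_s = apparent_viscosity)
  class(out) <- c("flow_curve", "data.frame")
  out
}

#' Gel-state classification of an oscillation sweep
#'
#' A frequency point with G' > G'' responds predominantly elastically
#' (viscoelastic solid); G' < G'' predominantly viscously (viscoelastic
#' liquid). The overall label is the majority vote across the sweep, and
#' crossover frequencies (sign changes of G' - G'') are located by linear
#' interpolation of G' - G'' in log frequency, which is how gel/sol
#' crossovers are conventionally read off a sweep.
#'
#' @param sweep an [oscillation_sweep()].
#' @return list of class `gel_classification` with `per_point` labels,
#'   `overall`, and `crossover_rad_s` (numeric, possibly empty).
#' @export
classify_gel <- function(sweep) {
  stopifnot(inherits(sweep, "oscillation_sweep"))
  if (nrow(sweep) == 0L) stop("empty sweep", call. = FALSE)
  diff_mod <- sweep$g_prime_pa - sweep$g_loss_pa
  labels <- ifelse(diff_mod > 0, "viscoelastic-solid",
    ifelse(diff_mod < 0, "viscoelastic-liquid", "crossover")
  )
  n_solid <- sum(diff_mod > 0)
  n_liquid <- sum(diff_mod < 0)
  overall <- if (n_solid >= n_liquid) "viscoelastic-solid" else "viscoelastic-liquid"
  crossings <- which(diff_mod[-length(diff_mod)] * diff_mod[-1] < 0)
  crossover <- vapply(crossings, function(i) {
    lw <- log(sweep$omega_rad_s[i:(i + 1)])
    d <- diff_mod[i:(i + 1)]
    exp(lw[1] - d[1] * (lw[2] - lw[1]) / (d[2] - d[1]))
  }, numeric(1))
  ## points lying exactly on the crossover also count
  crossover <- sort(unique(c(crossover, sweep$omega_rad_s[diff_mod == 0])))
  structure(
    list(
      per_point = data.frame(omega_rad_s = sweep$omega_rad_s, label = labels),
      overall = overall,
      crossover_rad_s = crossover
    ),
    class = "gel_classification"
  )
}

#' @export
print.gel_classification <- function(x, ...) {
  cat("Gel-state classification:", x$overall, "\n")
  tab <- table(x$per_point$label)
  cat(paste(sprintf("  %s: %d points", names(tab), as.integer(tab)), collapse = "\n"), "\n")
  if (length(x$crossover_rad_s)) {
    cat("  crossover at omega =", paste(signif(x$crossover_rad_s, 4), collapse = ", "), "rad/s\n")
  } else {
    cat("  no crossover\n")
  }
  invisible(x)
}

#' Loss tangent of an oscillation sweep
#'
#' tan(delta) = G''/G' per frequency point; values below 1 indicate a
#' predominantly elastic (gel-like) response.
#'
#' @param sweep an [oscillation_sweep()].
#' @return numeric vector, one value per frequency.
#' @export
tan_delta <- function(sweep) {
  stopifnot(inherits(sweep, "oscillation_sweep"))
  if (any(sweep$g_prime_pa <= 0)) {
    stop("tan(delta) requires G' > 0 at every point", call. = FALSE)
  }
  sweep$g_loss_pa / sweep$g_prime_pa
}

#' Shear-thinning check on a flow curve
#'
#' Fits log10(viscosity) against log10(shear rate) by ordinary least
#' squares. For a power-law fluid eta = k * gammadot^(n - 1) the slope is
#' n - 1, so slope < 0 means shear thinning and `flow_index` = slope + 1
#' recovers n.
#'
#' @param curve a [flow_curve()] with at least 3 points.
#' @return list with `shear_thinning` (logical), `slope`, `flow_index`,
#'   `consistency_index` (k, Pa s^n).
#' @export
shear_thinning_check <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  if (nrow(curve) < 3L) stop("need at least 3 flow-curve points", call. = FALSE)
  fit <- lm(log10(viscosity_pa_s) ~ log10(shear_rate_1_s), data = curve)
  slope <- unname(coef(fit)[2])
  list(
    ## numerical guard: a slope within 1e-8 of zero is a constant viscosity
    shear_thinning = slope < -1e-8,
    slope = slope,
    flow_index = slope + 1,
    consistency_index = 10^unname(coef(fit)[1])
  )
}
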