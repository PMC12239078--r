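#' Serial dilution series
#'
#' Concentrations c_i = conc_max / factor^i for i = 0..n-1, the standard
#' capillary-series layout of thermophoresis binding assays.
#'
#' @param conc_max top concentration (mg/mL).
#' @param factor dilution factor per step (> 1).
#' @param n number of points (>= 2).
#' @return numeric vector, strictly decreasing.
#' @examples
#' serial_dilution(5, 2, 12)  # 5 ... 0.00244 mg/mL
#' @export
serial_dilution <- function(conc_max, factor, n) {
  check_scalar(conc_max, "conc_max", lower = 0, strict_lower = TRUE)
  check_scalar(factor, "factor", lower = 1, strict_lower = TRUE)
  n <- check_count(n, "n", min = 2L)
  conc_max / factor^(seq_len(n) - 1)
}

#' Quadratic (ligand-depletion) binding isotherm
#'
#' Law-of-mass-action bound fraction of a ligand at fixed concentration L
#' titrated with target T:
#' \deqn{FB = \frac{(L + T + K_d) - \sqrt{(L + T + K_d)^2 - 4 L T}}{2L}}
#' evaluated in the numerically stable form 2T / (S + sqrt(S^2 - 4LT)),
#' S = L + T + Kd, which is exact for L -> 0 where it reduces to the
#' simple isotherm T / (T + Kd). The measured response interpolates
#' between the unbound and bound fluorescence levels:
#' response = f_unbound + (f_bound - f_unbound) * FB.
#'
#' Unlike the simple isotherm, this form stays valid when the target
#' concentration is comparable to the ligand concentration (ligand
#' depletion), which is the regime of mass-concentration titrations of
#' mucins against a micromolar dye-labelled ligand.
#'
#' @param target_conc target concentrations (>= 0), any units shared
#'   with `kd`.
#' @param ligand_conc fixed ligand concentration (>= 0, same units).
#' @param kd dissociation constant (> 0, same units).
#' @param f_unbound,f_bound response levels of free and fully bound
#'   ligand.
#' @return responses, same length as `target_conc`.
#' @export
binding_isotherm <- function(target_conc, ligand_conc, kd, f_unbound, f_bound) {
  if (any(target_conc < 0) || ligand_conc < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  check_scalar(kd, "kd", lower = 0, strict_lower = TRUE)
  s <- ligand_conc + target_conc + kd
  disc <- pmax(s^2 - 4 * ligand_conc * target_conc, 0)
  fb <- 2 * target_conc / (s + sqrt(disc))
  f_unbound + (f_bound - f_unbound) * fb
}

#' Binding series container
#'
#' @param target_conc strictly decreasing positive concentrations
#'   (mg/mL), at least 4 points.
#' @param response normalized fluorescence per concentration.
#' @param ligand_conc fixed ligand concentration (same units as
#'   `target_conc` for the depletion term; a micromolar dye ligand is
#'   effectively 0 on a mg/mL scale).
#' @return data.frame of class `binding_series` with attribute
#'   `ligand_conc`.
#' @export
binding_series <- function(target_conc, response, ligand_conc = 0) {
  if (length(target_conc) != length(response)) {
    stop("`target_conc` and `response` must have equal length", call. = FALSE)
  }
  if (length(target_conc) < 4L) stop("need at least 4 points", call. = FALSE)
  if (any(target_conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (is.unsorted(rev(target_conc), strictly = TRUE)) {
    stop("`target_conc` must be strictly decreasing (serial dilution order)", call. = FALSE)
  }
  check_scalar(ligand_conc, "ligand_conc", lower = 0)
  out <- data.frame(target_conc_mg_ml = target_conc, response = response)
  attr(out, "ligand_conc") <- ligand_conc
  class(out) <- c("binding_series", "data.frame")
  out
}

#' Fit a dissociation constant to a dilution series
#'
#' Least-squares fit of the quadratic isotherm to a concentration-
#' response series. Kd is profiled on a log scale: for each candidate Kd
#' the optimal (f_unbound, f_bound) follow from a linear regression of
#' the response on the bound fraction, and the 1-D profile is minimized
#' by golden-section search over log10 Kd spanning three decades beyond
#' the measured concentration range. The baseline direction (response
#' rising or falling with binding) is therefore fitted, not assumed.
#'
#' @param series a [binding_series()] (or data.frame with
#'   `target_conc_mg_ml`, `response`).
#' @param ligand_conc fixed ligand concentration; defaults to the series
#'   attribute.
#' @return object of class `binding_fit` with `kd`, `f_unbound`,
#'   `f_bound`, `residual_norm`, `converged`, `flags`, and the data.
#'   Methods: `print`, `coef`, `predict`, `residuals`.
#' @export
fit_kd <- function(series, ligand_conc = NULL) {
  stopifnot(is.data.frame(series),
    all(c("target_conc_mg_ml", "response") %in% names(series))
  )
  if (is.null(ligand_conc)) ligand_conc <- attr(series, "ligand_conc") %||% 0
  tc <- series$target_conc_mg_ml
  y <- series$response
  if (length(tc) < 4L) stop("need at least 4 points", call. = FALSE)
  flags <- character(0)
  span <- diff(range(y))
  if (span <= .Machine$double.eps * max(abs(y), 1)) {
    return(structure(
      list(
        kd = NA_real_, f_unbound = mean(y), f_bound = mean(y),
        residual_norm = 0, converged = FALSE,
        flags = "non-identifiable: flat response series",
        data = series, ligand_conc = ligand_conc
      ),
      class = "binding_fit"
    ))
  }

  sse_profile <- function(log10_kd) {
    fb <- binding_isotherm(tc, ligand_conc, 10^log10_kd, 0, 1)
    fit <- lm(y ~ fb)
    sum(stats::residuals(fit)^2)
  }
  lo <- log10(min(tc)) - 3
  hi <- log10(max(tc)) + 3
  opt <- optimize(sse_profile, c(lo, hi), tol = 1e-10)
  kd <- 10^opt$minimum
  if (opt$minimum - lo < 1e-3 || hi - opt$minimum < 1e-3) {
    flags <- c(flags, "kd-at-search-bound")
  }
  fb <- binding_isotherm(tc, ligand_conc, kd, 0, 1)
  lin <- lm(y ~ fb)
  f_unbound <- unname(coef(lin)[1])
  f_bound <- f_unbound + unname(coef(lin)[2])
  structure(
    list(
      kd = kd, f_unbound = f_unbound, f_bound = f_bound,
      residual_norm = sqrt(sum(stats::residuals(lin)^2)),
      converged = !length(flags), flags = flags,
      data = series, ligand_conc = ligand_conc
    ),
    class = "binding_fit"
  )
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(kd = object$kd, f_unbound = object$f_unbound, f_bound = object$f_bound)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Quadratic binding-isotherm fit\n")
  if (is.na(x$kd)) {
    cat("  non-identifiable:", paste(x$flags, collapse = "; "), "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "  Kd = %.4g mg/mL (ligand %.4g), f_unbound = %.4g, f_bound = %.4g\n",
    x$kd, x$ligand_conc, x$f_unbound, x$f_bound
  ))
  cat(sprintf("  residual norm %.3g over %d points\n", x$residual_norm, nrow(x$data)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  tc <- if (is.null(newdata)) object$data$target_conc_mg_ml
  else newdata$target_conc_mg_ml %||% newdata
  binding_isotherm(tc, object$ligand_conc, object$kd, object$f_unbound, object$f_bound)
}

#' @export
residuals.binding_fit <- function(object, ...) {
  object$data$response - predict(object)
}
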