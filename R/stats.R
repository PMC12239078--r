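#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H across two or more groups, with the
#' p-value from the chi-square approximation (k - 1 degrees of freedom)
#' or, for small samples (total n <= `exact_max`), from exact enumeration
#' of all assignments of the observed ranks to the group sizes. The
#' statistic is authored here so the test can be validated against the
#' independent base-R implementation; exact small-sample enumeration is
#' not available there.
#'
#' @param values numeric measurements.
#' @param groups group labels, same length as `values`; at least 2
#'   groups, each with at least 3 values for the omnibus test.
#' @param exact_max largest total n for which the exact permutation
#'   p-value is computed (default 10).
#' @return list of class `kruskal_wallis` with `statistic` (H),
#'   `p_value`, `df`, `method` ("chi-square" or "exact"), `flags`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups, exact_max = 10L) {
  if (length(values) != length(groups)) {
    stop("`values` and `groups` must have equal length", call. = FALSE)
  }
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 3L)) {
    warning("group(s) with fewer than 3 values: omnibus test underpowered", call. = FALSE)
  }
  n <- length(values)
  flags <- character(0)
  if (length(unique(values)) == 1L) {
    return(structure(
      list(
        statistic = 0, p_value = 1, df = k - 1L, method = "degenerate",
        flags = "degenerate: all values identical"
      ),
      class = "kruskal_wallis"
    ))
  }
  r <- rank(values)
  h_stat <- function(rr) {
    sums <- tapply(rr, groups, sum)
    (12 / (n * (n + 1))) * sum(sums^2 / as.vector(sizes)) - 3 * (n + 1)
  }
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h_stat(r) / tie_corr
  if (n <= exact_max) {
    perms <- group_assignments(n, as.vector(sizes))
    h_all <- apply(perms, 1L, function(g) {
      sums <- rowsum(r, group = g)
      ((12 / (n * (n + 1))) * sum(sums^2 / as.vector(sizes)) - 3 * (n + 1)) / tie_corr
    })
    p <- mean(h_all >= h - 1e-12)
    method <- "exact"
  } else {
    p <- pchisq(h, df = k - 1, lower.tail = FALSE)
    method <- "chi-square"
  }
  structure(
    list(statistic = unname(h), p_value = p, df = k - 1L, method = method, flags = flags),
    class = "kruskal_wallis"
  )
}

## all distinct assignments of n positions to groups of the given sizes,
## returned as a matrix (one assignment per row, entries = group index)
group_assignments <- function(n, sizes) {
  rec <- function(avail, sizes_left, g) {
    if (length(sizes_left) == 1L) {
      m <- matrix(0L, 1L, n)
      m[1L, avail] <- g
      return(m)
    }
    picks <- combn(avail, sizes_left[1], simplify = FALSE)
    do.call(rbind, lapply(picks, function(p) {
      rest <- rec(setdiff(avail, p), sizes_left[-1], g + 1L)
      rest[, p] <- g
      rest
    }))
  }
  rec(seq_len(n), sizes, 1L)
}

#' @export
print.kruskal_wallis <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (%s)\n",
    x$statistic, x$df, x$p_value, x$method
  ))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Signed-rank statistic V (sum of ranks of the positive differences)
#' for paired data. Zero differences are dropped before ranking
#' (Wilcoxon's original treatment); ties among the absolute differences
#' receive average ranks. The p-value is exact (from the signed-rank
#' null distribution) for n <= `exact_max` non-zero differences without
#' ties, otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y paired measurements (`y` omitted if `x` is already a
#'   vector of differences).
#' @param alternative `"two.sided"`, `"greater"` (x tends above y) or
#'   `"less"`.
#' @param exact_max largest n for the exact p-value (default 25).
#' @return list of class `wilcoxon_signed_rank` with `statistic` (V),
#'   `p_value`, `n` (non-zero pairs), `n_zero_dropped`, `method`,
#'   `flags`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_max = 25L) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(
      list(
        statistic = NA_real_, p_value = NA_real_, n = 0L,
        n_zero_dropped = n_zero, method = "degenerate",
        flags = "degenerate: all differences zero"
      ),
      class = "wilcoxon_signed_rank"
    ))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  has_ties <- anyDuplicated(r) > 0L
  flags <- character(0)
  if (n_zero > 0) flags <- c(flags, sprintf("%d zero difference(s) dropped", n_zero))
  if (n <= exact_max && !has_ties) {
    method <- "exact"
    p <- switch(alternative,
      two.sided = {
        pp <- if (v > n * (n + 1) / 4) {
          stats::psignrank(v - 1, n, lower.tail = FALSE)
        } else {
          stats::psignrank(v, n)
        }
        min(2 * pp, 1)
      },
      greater = stats::psignrank(v - 1, n, lower.tail = FALSE),
      less = stats::psignrank(v, n)
    )
  } else {
    method <- "normal-approximation"
    if (has_ties) flags <- c(flags, "ties: normal approximation used")
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z_num <- v - mu
    correction <- switch(alternative,
      two.sided = sign(z_num) * 0.5, greater = 0.5, less = -0.5
    )
    z <- (z_num - correction) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)),
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z)
    )
    p <- min(p, 1)
  }
  structure(
    list(
      statistic = unname(v), p_value = p, n = n, n_zero_dropped = n_zero,
      method = method, flags = flags
    ),
    class = "wilcoxon_signed_rank"
  )
}

#' @export
print.wilcoxon_signed_rank <- function(x, ...) {
  if (identical(x$method, "degenerate")) {
    cat("Wilcoxon signed-rank: degenerate (all differences zero)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Wilcoxon signed-rank: V = %g, n = %d, p = %.4g (%s)\n",
    x$statistic, x$n, x$p_value, x$method
  ))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Assemble a per-matrix summary table
#'
#' Collects the outputs of the analysis stages for one or more matrices
#' (e.g. a native mucus benchmark and its artificial mimics) into a
#' machine-readable comparison table: MSD and D_eff ranges, transport
#' ratios, pore-size medians from the theoretical and binarization
#' routes, and the gel classification. Stages that were not run for a
#' matrix yield `NA` columns rather than fabricated values.
#'
#' @param ... named per-matrix lists with any of the elements `tracking`
#'   (a `tracking_summary`), `mesh` (a `mesh_estimate`), `pores` (a
#'   `pore_size_stats`), `gel` (a `gel_classification`), `binding` (a
#'   `binding_fit`).
#' @return data.frame of class `mucus_summary`, one row per matrix.
#' @export
build_summary <- function(...) {
  matrices <- list(...)
  if (length(matrices) == 1L && is.null(names(matrices)) && is.list(matrices[[1]]) &&
      !is.null(names(matrices[[1]])) &&
      all(vapply(matrices[[1]], is.list, logical(1)))) {
    matrices <- matrices[[1]]
  }
  if (!length(matrices)) stop("no matrices supplied", call. = FALSE)
  if (is.null(names(matrices)) || any(!nzchar(names(matrices)))) {
    stop("each matrix must be named", call. = FALSE)
  }
  rows <- lapply(names(matrices), function(nm) {
    m <- matrices[[nm]]
    tr <- m$tracking
    pr <- m$pores
    ms <- m$mesh
    gl <- m$gel
    bd <- m$binding
    pct <- if (!is.null(tr)) tr$ratios$percent else NULL
    data.frame(
      matrix = nm,
      msd_min_um2 = if (!is.null(tr)) tr$msd_range[1] else NA_real_,
      msd_max_um2 = if (!is.null(tr)) tr$msd_range[2] else NA_real_,
      deff_min_um2_s = if (!is.null(tr)) tr$deff_range[1] else NA_real_,
      deff_max_um2_s = if (!is.null(tr)) tr$deff_range[2] else NA_real_,
      pct_immobile = if (!is.null(pct)) unname(pct["immobile"]) else NA_real_,
      pct_subdiffusive = if (!is.null(pct)) unname(pct["subdiffusive"]) else NA_real_,
      pct_diffusive = if (!is.null(pct)) unname(pct["diffusive"]) else NA_real_,
      pct_active = if (!is.null(pct) && "active" %in% names(pct)) {
        unname(pct["active"])
      } else {
        NA_real_
      },
      mesh_size_theoretical_nm = if (!is.null(ms)) median(ms$mesh_size_nm) else NA_real_,
      pore_median_feret_min_nm = if (!is.null(pr)) pr$median_feret_min else NA_real_,
      gel_classification = if (!is.null(gl)) gl$overall else NA_character_,
      kd_mg_ml = if (!is.null(bd)) bd$kd else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mucus_summary", "data.frame")
  out
}
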