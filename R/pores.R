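#' Micrograph container
#'
#' An 8-bit grayscale micrograph with a physical pixel scale. Pixel
#' intensities must be integers in [0, 255]; images from 16-bit
#' acquisitions must be rescaled explicitly before analysis so the fixed
#' pore threshold keeps its meaning.
#'
#' @param pixels integer matrix of intensities in [0, 255] (rows = image
#'   rows).
#' @param scale physical size of one pixel in nanometers.
#' @return list of class `micrograph` with `pixels` and `scale_nm_per_px`.
#' @export
micrograph <- function(pixels, scale) {
  stopifnot(is.matrix(pixels))
  if (any(pixels != round(pixels)) || min(pixels) < 0 || max(pixels) > 255) {
    stop("`pixels` must be 8-bit: integers in [0, 255]; rescale explicitly first",
      call. = FALSE
    )
  }
  check_scalar(scale, "scale", lower = 0, strict_lower = TRUE)
  structure(
    list(pixels = matrix(as.integer(pixels), nrow(pixels)), scale_nm_per_px = scale),
    class = "micrograph"
  )
}

#' Fixed-threshold binarization of a micrograph
#'
#' Marks as pore every pixel whose intensity lies in the closed band
#' [threshold_low, threshold_high]. Cryo-SEM pores image dark against the
#' platinum-coated mesh, so the default band 0-75 (inclusive at both
#' ends, applied identically to all images) selects the voids.
#'
#' @param image a [micrograph()].
#' @param threshold_low,threshold_high inclusive intensity bounds of the
#'   pore band.
#' @return logical matrix, `TRUE` for pore pixels.
#' @export
binarize <- function(image, threshold_low = 0, threshold_high = 75) {
  stopifnot(inherits(image, "micrograph"))
  image$pixels >= threshold_low & image$pixels <= threshold_high
}

## 8-connected component labeling by iterative minimum-label propagation.
## Each foreground pixel starts with its own index label; labels flow to
## the neighborhood minimum until a fixed point, then are renumbered
## consecutively in raster order. Iteration count is bounded by the
## longest geodesic path inside a component, fine for micrograph-scale
## images.
label_components_8 <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr + 2L, nc + 2L)
  core_r <- 2:(nr + 1)
  core_c <- 2:(nc + 1)
  lab[core_r, core_c] <- ifelse(mask, seq_len(nr * nc), 0L)
  big <- nr * nc + 1L
  repeat {
    m <- lab[core_r, core_c]
    fg <- m > 0L
    if (!any(fg)) break
    cur <- ifelse(fg, m, big)
    best <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- lab[core_r + dr, core_c + dc]
      nb <- ifelse(nb > 0L, nb, big)
      best <- pmin(best, nb)
    }
    best <- ifelse(fg, pmin(best, cur), 0L)
    if (identical(best, m)) break
    lab[core_r, core_c] <- best
  }
  out <- lab[core_r, core_c]
  ids <- unique(out[out > 0L])
  out[] <- match(out, c(0L, sort(ids))) - 1L
  out
}

#' Feret diameters of a point set
#'
#' Computes the maximum and minimum caliper (Feret) diameters of the
#' convex hull of a 2D point set. The maximum is the hull diameter (the
#' largest vertex-pair distance); the minimum is the smallest width over
#' hull edges, i.e. for each edge the largest distance of any hull point
#' from that edge's line — the classic rotating-calipers result that the
#' minimum width is attained with one caliper flat on an edge.
#'
#' @param points two-column matrix of (x, y) coordinates.
#' @param scale multiplier converting coordinate units to output units
#'   (e.g. nm per pixel).
#' @return named numeric `c(feret_max =, feret_min =)`.
#' @export
feret_diameters <- function(points, scale = 1) {
  stopifnot(is.matrix(points), ncol(points) == 2L, nrow(points) >= 1L)
  if (nrow(points) == 1L) {
    return(c(feret_max = 0, feret_min = 0) * scale)
  }
  h <- chull(points[, 1], points[, 2])
  hull <- points[h, , drop = FALSE]
  nh <- nrow(hull)
  if (nh == 1L) {
    return(c(feret_max = 0, feret_min = 0))
  }
  ## diameter over hull vertex pairs (hulls are small; O(h^2) is fine)
  dx <- outer(hull[, 1], hull[, 1], "-")
  dy <- outer(hull[, 2], hull[, 2], "-")
  fmax <- sqrt(max(dx^2 + dy^2))
  if (nh == 2L) {
    ## degenerate (collinear) hull: zero width
    return(c(feret_max = fmax * scale, feret_min = 0))
  }
  ## minimum width: for each edge, max perpendicular distance of hull pts
  nxt <- c(2:nh, 1L)
  widths <- vapply(seq_len(nh), function(i) {
    e <- hull[nxt[i], ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    ## unit normal to the edge
    nvec <- c(-e[2], e[1]) / len
    d <- (hull[, 1] - hull[i, 1]) * nvec[1] + (hull[, 2] - hull[i, 2]) * nvec[2]
    max(abs(d))
  }, numeric(1))
  c(feret_max = fmax * scale, feret_min = min(widths) * scale)
}

## corner points (pixel outline vertices) of a set of pixels given as
## (row, col) indices; pixel (r, c) occupies the unit square
## [c-1, c] x [r-1, r] in (x, y)
pixel_corner_points <- function(rows, cols) {
  cbind(
    x = c(cols - 1, cols, cols - 1, cols),
    y = c(rows - 1, rows - 1, rows, rows)
  )
}

#' Label pores in a binary mask and measure them
#'
#' Connected components are extracted with 8-connectivity (diagonal
#' contact joins pixels, the convention of particle analyzers). Each
#' component is converted to physical units with the pixel scale and
#' retained when its area is at least `min_size^2` (the noise floor is
#' expressed as an area-equivalent minimum size). Feret diameters are
#' measured on the convex hull of the pixel corner points, so a single
#' pixel has Feret min = scale and Feret max = sqrt(2) * scale.
#' Components touching the image border are flagged and retained by
#' default. The conventional circularity filter [0, 1] admits every
#' shape and is provided as `circularity_range` for fidelity with
#' standard particle-analysis settings.
#'
#' @param mask logical matrix from [binarize()].
#' @param scale nanometers per pixel.
#' @param min_size minimum pore size in nanometers (area threshold
#'   `min_size^2`); default 0.1 nm removes single-pixel noise only at
#'   very coarse scales.
#' @param exclude_border drop border-touching pores instead of flagging?
#' @param circularity_range admitted circularity interval (pass-through
#'   by default).
#' @return data.frame of class `pore_records`: `label`, `area_nm2`,
#'   `feret_max_nm`, `feret_min_nm`, `centroid_row`, `centroid_col`,
#'   `touches_border`.
#' @export
label_pores <- function(mask, scale, min_size = 0.1, exclude_border = FALSE,
                        circularity_range = c(0, 1)) {
  stopifnot(is.logical(mask), is.matrix(mask))
  check_scalar(scale, "scale", lower = 0, strict_lower = TRUE)
  check_scalar(min_size, "min_size", lower = 0)
  lab <- label_components_8(mask)
  n <- max(lab)
  empty <- data.frame(
    label = integer(0), area_nm2 = numeric(0), feret_max_nm = numeric(0),
    feret_min_nm = numeric(0), centroid_row = numeric(0),
    centroid_col = numeric(0), touches_border = logical(0)
  )
  class(empty) <- c("pore_records", "data.frame")
  if (n == 0L) return(empty)
  idx <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[lab > 0L]
  rows <- lapply(seq_len(n), function(id) {
    px <- idx[labs == id, , drop = FALSE]
    area <- nrow(px) * scale^2
    fer <- feret_diameters(pixel_corner_points(px[, 1], px[, 2]), scale = scale)
    circ <- if (fer["feret_max"] > 0) 4 * (nrow(px)) / (pi * (fer["feret_max"] / scale)^2) else 1
    data.frame(
      label = id, area_nm2 = area,
      feret_max_nm = unname(fer["feret_max"]),
      feret_min_nm = unname(fer["feret_min"]),
      centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
      touches_border = any(px[, 1] == 1L | px[, 1] == nrow(mask) |
        px[, 2] == 1L | px[, 2] == ncol(mask)),
      circularity = min(circ, 1)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[out$area_nm2 >= min_size^2, , drop = FALSE]
  out <- out[out$circularity >= circularity_range[1] &
    out$circularity <= circularity_range[2], , drop = FALSE]
  if (exclude_border) out <- out[!out$touches_border, , drop = FALSE]
  out$circularity <- NULL
  rownames(out) <- NULL
  class(out) <- c("pore_records", "data.frame")
  out
}

#' Distribution statistics of pore Feret-min diameters
#'
#' @param records a `pore_records` table from [label_pores()].
#' @return list of class `pore_size_stats` with `n_pores`,
#'   `median_feret_min`, `range_feret_min`, `median_feret_max`,
#'   `feret_min` (full distribution, nm).
#' @export
pore_size_stats <- function(records) {
  stopifnot(is.data.frame(records))
  structure(
    list(
      n_pores = nrow(records),
      median_feret_min = median(records$feret_min_nm),
      range_feret_min = if (nrow(records)) range(records$feret_min_nm) else c(NA_real_, NA_real_),
      median_feret_max = median(records$feret_max_nm),
      feret_min = records$feret_min_nm
    ),
    class = "pore_size_stats"
  )
}

#' @export
print.pore_size_stats <- function(x, ...) {
  cat(sprintf(
    "Pore-size statistics: n = %d, median Feret min = %.4g nm (range %.4g-%.4g nm)\n",
    x$n_pores, x$median_feret_min, x$range_feret_min[1], x$range_feret_min[2]
  ))
  invisible(x)
}

#' Paired comparison of Feret max vs Feret min diameters
#'
#' Wilcoxon signed-rank test on the per-pore (Feret max, Feret min)
#' pairs. For anisotropic pores the max systematically exceeds the min,
#' so a significant difference indicates elongated pore geometry; all-tie
#' input (perfect circles) is degenerate and flagged.
#'
#' @param records a `pore_records` table with at least 6 pores.
#' @param alternative passed to [wilcoxon_signed_rank()].
#' @return a `wilcoxon_signed_rank` result.
#' @export
compare_feret_max_min <- function(records, alternative = "two.sided") {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 6L) stop("need at least 6 pores for the paired test", call. = FALSE)
  wilcoxon_signed_rank(records$feret_max_nm, records$feret_min_nm,
    alternative = alternative
  )
}

#' Cross-validate microscopy pore sizes against the rheological mesh size
#'
#' Kruskal-Wallis comparison of pore/mesh size samples obtained by
#' different methods (theoretical mesh size from the storage modulus,
#' Feret-min diameters from binarized micrographs, optionally manual
#' measurements). Agreement between independent methods supports the
#' measured network length scale.
#'
#' @param ... named numeric samples in nanometers, e.g.
#'   `theoretical = ..., binarization = ..., manual = ...` (at least two).
#' @param significance significance level for the verdict.
#' @return list of class `pore_cross_validation` with the Kruskal-Wallis
#'   result, per-group medians and ranges, `agree` (logical), and
#'   `underpowered` flags for groups with fewer than 3 values.
#' @export
cross_validate_pore_size <- function(..., significance = 0.05) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]]) && !is.data.frame(groups[[1]])) {
    groups <- groups[[1]]
  }
  if (length(groups) < 2L) stop("need at least two method groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  underpowered <- names(groups)[vapply(groups, length, integer(1)) < 3L]
  kw <- kruskal_wallis(
    values = unlist(groups, use.names = FALSE),
    groups = rep(names(groups), vapply(groups, length, integer(1)))
  )
  per_group <- data.frame(
    method = names(groups),
    n = vapply(groups, length, integer(1)),
    median_nm = vapply(groups, median, numeric(1)),
    min_nm = vapply(groups, min, numeric(1)),
    max_nm = vapply(groups, max, numeric(1)),
    row.names = NULL
  )
  structure(
    list(
      test = kw, per_group = per_group,
      agree = kw$p_value >= significance,
      significance = significance,
      underpowered = underpowered
    ),
    class = "pore_cross_validation"
  )
}

#' @export
print.pore_cross_validation <- function(x, ...) {
  cat("Cross-validation of pore/mesh size across methods\n")
  print(x$per_group, row.names = FALSE)
  cat(sprintf(
    "  Kruskal-Wallis H = %.4g, p = %.4g -> methods %s at alpha = %g\n",
    x$test$statistic, x$test$p_value,
    if (x$agree) "agree" else "differ", x$significance
  ))
  if (length(x$underpowered)) {
    cat("  underpowered group(s):", paste(x$underpowered, collapse = ", "), "\n")
  }
  invisible(x)
}
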