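# Independent oracles used across the suite. These deliberately use the
# dumbest possible algorithms (double loops, dense angle grids) so they
# share no code path with the implementation they check.

# all-pairs time-averaged MSD by explicit double loop
brute_force_msd <- function(frames, x, y, frame_interval = 1) {
  o <- order(frames)
  frames <- frames[o]; x <- x[o]; y <- y[o]
  n <- length(frames)
  acc <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (frames[j] > frames[i]) {
        k <- frames[j] - frames[i]
        key <- as.character(k)
        acc[[key]] <- c(acc[[key]], (x[j] - x[i])^2 + (y[j] - y[i])^2)
      }
    }
  }
  ks <- sort(as.integer(names(acc)))
  out <- data.frame(
    lag_s = ks * frame_interval,
    msd_um2 = vapply(as.character(ks), function(k) mean(acc[[k]]), numeric(1)),
    n_pairs = vapply(as.character(ks), function(k) length(acc[[k]]), numeric(1))
  )
  rownames(out) <- NULL
  out
}

# Feret diameters by projection onto a dense rotation grid (0.05 degrees)
brute_force_feret <- function(points, step_deg = 0.05) {
  angles <- seq(0, pi, by = step_deg * pi / 180)
  w <- vapply(angles, function(a) {
    p <- points[, 1] * cos(a) + points[, 2] * sin(a)
    max(p) - min(p)
  }, numeric(1))
  c(feret_max = max(w), feret_min = min(w))
}

# random gapped trajectory for oracle-equivalence tests
random_gapped_trajectory <- function(n_frames = 20, drop = 0.25) {
  frames <- 0:(n_frames - 1)
  keep <- c(TRUE, runif(n_frames - 1) > drop)  # keep at least frame 0
  frames <- frames[keep]
  data.frame(
    frame = frames,
    x_um = cumsum(rnorm(length(frames))),
    y_um = cumsum(rnorm(length(frames)))
  )
}

# convex-ish random blob outline (noisy ellipse), in pixel units
random_blob <- function(n_vertices = 30, a_range = c(10, 40)) {
  th <- sort(runif(n_vertices, 0, 2 * pi))
  a <- runif(1, a_range[1], a_range[2])
  b <- runif(1, a_range[1] / 2, a)
  r <- 1 + 0.05 * rnorm(n_vertices)
  cbind(a * r * cos(th), b * r * sin(th))
}
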