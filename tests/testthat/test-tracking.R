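test_that("frame filter keeps trajectories detected in enough frames", {
  traj <- data.frame(
    particle = rep(c("a", "b", "c"), c(5, 10, 50)),
    frame = c(0:4, 0:9, 0:49),
    x_um = 0, y_um = 0
  )
  expect_identical(apply_frame_filter(traj, 1), traj)
  kept <- apply_frame_filter(traj, 10)
  expect_setequal(unique(kept$particle), c("b", "c"))

  # oracle: retained set equals brute-force per-particle row counting
  set.seed(2)
  gen <- gen_trajectories(trajectory_sim_spec(
    n_particles = 40, n_frames = 30,
    dropout_prob = 0.3, seed = 8
  ))
  for (ff in c(5, 20, 28)) {
    expect_setequal(
      unique(apply_frame_filter(gen, ff)$particle),
      as.integer(names(which(table(gen$particle) >= ff)))
    )
  }
})

test_that("analysis-time truncation keeps frames strictly inside the window", {
  traj <- data.frame(particle = 1, frame = 0:99, x_um = 0, y_um = 0)
  expect_equal(nrow(truncate_to_analysis_time(traj, 100)), 100) # full duration
  short <- truncate_to_analysis_time(traj, 10)
  expect_equal(short$frame, 0:9)

  # AT then FF retains only gap-free-in-window particles
  gappy <- data.frame(
    particle = rep(c(1, 2), each = 50),
    frame = c(0:49, setdiff(0:50, 3)), # particle 2 misses frame 3
    x_um = 0, y_um = 0
  )
  w <- apply_frame_filter(truncate_to_analysis_time(gappy, 10), 10)
  expect_setequal(unique(w$particle), 1)
})

test_that("time-averaged MSD matches hand arithmetic and the brute-force oracle", {
  # 3 collinear points: MSD(1) = 1, MSD(2) = 4
  tri <- data.frame(frame = 0:2, x_um = c(0, 1, 2), y_um = 0)
  m <- compute_msd(tri)
  expect_equal(m$msd_um2, c(1, 4))
  expect_equal(m$n_pairs, c(2, 1))

  # stationary particle: identically zero
  still <- data.frame(frame = 0:9, x_um = 5, y_um = -2)
  expect_true(all(compute_msd(still)$msd_um2 == 0))

  # oracle equivalence on random gapped trajectories
  set.seed(11)
  for (i in 1:20) {
    tr <- random_gapped_trajectory()
    if (nrow(tr) < 2) next
    expect_equal(
      as.data.frame(compute_msd(tr))[, c("lag_s", "msd_um2")],
      brute_force_msd(tr$frame, tr$x_um, tr$y_um)[, c("lag_s", "msd_um2")],
      tolerance = 1e-12
    )
  }

  # single-point trajectory yields an empty, flagged curve
  single <- compute_msd(data.frame(frame = 0, x_um = 0, y_um = 0))
  expect_equal(nrow(single), 0)
  expect_true(attr(single, "degenerate"))
})

test_that("effective diffusivity and Stokes-Einstein reference are correct", {
  expect_equal(deff_from_msd(4, 1), 1) # n = 2
  expect_equal(deff_from_msd(0, 1), 0)
  expect_error(deff_from_msd(1, 0), "positive")

  # 0.2 um diameter bead in water at 37 degC
  expect_equal(stokes_einstein_dw(0.1, 6.9e-4, 310.15), 3.292, tolerance = 1e-3)
  expect_equal(
    stokes_einstein_dw(0.2, 6.9e-4, 310.15),
    stokes_einstein_dw(0.1, 6.9e-4, 310.15) / 2
  )
  # identity D_w * 6 pi eta r / (kB T) = 1 in SI units
  set.seed(1)
  for (i in 1:5) {
    r <- runif(1, 0.01, 1)
    eta <- runif(1, 1e-4, 1e-2)
    tt <- runif(1, 280, 320)
    dw <- stokes_einstein_dw(r, eta, tt) * 1e-12
    expect_equal(dw * 6 * pi * eta * (r * 1e-6) / (1.380649e-23 * tt), 1,
      tolerance = 1e-12
    )
  }
  # hindrance ratio
  expect_equal(dw_deff_ratio(3.29, 0.00140), 2350, tolerance = 1e-3)
  expect_equal(dw_deff_ratio(1, 1), 1)
  expect_equal(dw_deff_ratio(2 * 3.29, 2 * 0.00140), dw_deff_ratio(3.29, 0.00140))
  expect_warning(expect_equal(dw_deff_ratio(1, 0), Inf), "hindrance")
})

test_that("alpha fit is exact on noiseless power-law MSD", {
  lag <- 1:50
  for (a in c(0.5, 1, 1.7)) {
    msd <- structure(
      data.frame(lag_s = lag, msd_um2 = 4 * 0.05 * lag^a, n_pairs = 50),
      class = c("msd_curve", "data.frame")
    )
    for (frac in c(0.1, 0.5, 1)) {
      fit <- fit_alpha(msd, tracking_config(msd_fit_fraction = frac))
      expect_equal(fit$alpha, a, tolerance = 1e-10)
      expect_equal(fit$d0, 0.05, tolerance = 1e-10)
    }
  }
  # degenerate all-zero window
  zero <- structure(
    data.frame(lag_s = lag, msd_um2 = 0, n_pairs = 50),
    class = c("msd_curve", "data.frame")
  )
  zfit <- fit_alpha(zero)
  expect_equal(zfit$alpha, 0)
  expect_equal(zfit$transport_class, "immobile")
  expect_true(any(grepl("degenerate", zfit$flags)))
})

test_that("transport classification uses half-open bins with clamping", {
  expect_equal(classify_transport(0.5)$class, "subdiffusive")
  expect_equal(classify_transport(1.0)$class, "diffusive")
  expect_equal(classify_transport(0.05)$class, "immobile")
  expect_equal(classify_transport(1.5)$class, "active")
  # boundary policy: left-closed bins
  expect_equal(classify_transport(0.2)$class, "subdiffusive")
  expect_equal(classify_transport(0.9)$class, "diffusive")
  expect_equal(classify_transport(1.2)$class, "active")
  neg <- classify_transport(-0.3)
  expect_equal(neg$class, "immobile")
  expect_true(length(neg$flags) > 0)
  expect_equal(classify_transport(NaN)$class, "unclassified")
})

test_that("transport-mode ratios sum to 100 and handle active exclusion", {
  expect_equal(unname(transport_mode_ratios(rep("subdiffusive", 7))$percent["subdiffusive"]), 100)
  mix <- c("immobile", "subdiffusive", "diffusive", "active")
  res <- transport_mode_ratios(mix, exclude_active = TRUE)
  expect_equal(unname(res$percent), rep(100 / 3, 3), tolerance = 1e-9)
  expect_equal(res$n_excluded, 1)
  expect_equal(sum(res$percent), 100, tolerance = 1e-9)
  # designed mixture recovered within a few points
  tr <- gen_trajectories(trajectory_sim_spec(
    n_particles = 300, n_frames = 100, alpha = 0.5, d0 = 0.05,
    immobile_fraction = 0.3, loc_noise_sd = 0.002, seed = 21
  ))
  s <- track_analyze(tr)
  expect_equal(unname(s$ratios$percent["immobile"]), 30, tolerance = 5)
  expect_equal(unname(s$ratios$percent["subdiffusive"]), 70, tolerance = 5)
  expect_equal(sum(s$ratios$percent), 100, tolerance = 1e-9)
})
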