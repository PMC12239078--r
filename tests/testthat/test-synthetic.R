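test_that("generators are deterministic and leave the caller's RNG alone", {
  spec <- trajectory_sim_spec(n_particles = 10, n_frames = 20, alpha = 0.7,
    dropout_prob = 0.2, seed = 5)
  expect_identical(gen_trajectories(spec), gen_trajectories(spec))
  expect_identical(
    gen_frap_trace(frap_sim_spec(seed = 3)),
    gen_frap_trace(frap_sim_spec(seed = 3))
  )
  expect_identical(
    gen_binding_series(binding_sim_spec(seed = 3)),
    gen_binding_series(binding_sim_spec(seed = 3))
  )
  expect_identical(
    gen_rheology_sweep(rheology_sim_spec(seed = 3)),
    gen_rheology_sweep(rheology_sim_spec(seed = 3))
  )
  p1 <- gen_pore_image(pore_image_sim_spec(n_pores = 5, seed = 3))
  p2 <- gen_pore_image(pore_image_sim_spec(n_pores = 5, seed = 3))
  expect_identical(p1$image$pixels, p2$image$pixels)
  expect_identical(p1$truth, p2$truth)

  # caller's RNG stream is restored
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(gen_trajectories(spec))
  expect_identical(rnorm(1), before)
})

test_that("Brownian trajectories have the closed-form lag-1 variance", {
  d0 <- 0.05
  dt <- 1
  spec <- trajectory_sim_spec(
    n_particles = 500, n_frames = 30, d0 = d0, alpha = 1,
    loc_noise_sd = 0, seed = 31
  )
  tr <- gen_trajectories(spec)
  # per-axis lag-1 increment variance = 2 D0 dt, within 3 standard errors
  inc <- do.call(rbind, lapply(split(tr, tr$particle), function(p) {
    data.frame(dx = diff(p$x_um), dy = diff(p$y_um))
  }))
  n <- nrow(inc)
  se <- sqrt(2 / (n - 1)) * 2 * d0 * dt # se of a variance estimate
  expect_lt(abs(var(inc$dx) - 2 * d0 * dt), 3 * se)
  expect_lt(abs(var(inc$dy) - 2 * d0 * dt), 3 * se)

  # ensemble MSD at several lags within 3 SE of 4 D0 tau
  curves <- msd_per_particle(tr)
  for (k in c(1, 3)) {
    vals <- vapply(curves, function(m) m$msd_um2[k], numeric(1))
    expect_lt(
      abs(mean(vals) - 4 * d0 * k),
      3 * sd(vals) / sqrt(length(vals))
    )
  }
})

test_that("fBm increments have the designed autocorrelation sign and exponent", {
  acf1 <- function(alpha) {
    tr <- gen_trajectories(trajectory_sim_spec(
      n_particles = 500, n_frames = 20,
      alpha = alpha, loc_noise_sd = 0, seed = 17
    ))
    inc <- do.call(rbind, lapply(split(tr, tr$particle), function(p) {
      dx <- diff(p$x_um)
      data.frame(a = dx[-length(dx)], b = dx[-1])
    }))
    cor(inc$a, inc$b)
  }
  expect_lt(acf1(0.5), -0.05) # antipersistent
  expect_gt(acf1(1.5), 0.05) # persistent

  # recovery of a designed subdiffusive exponent through the full pipeline
  tr <- gen_trajectories(trajectory_sim_spec(
    n_particles = 500, n_frames = 100,
    alpha = 0.5, d0 = 0.05, seed = 1
  ))
  s <- track_analyze(tr)
  expect_equal(s$median_alpha, 0.5, tolerance = 0.1)
})

test_that("immobile particles are localization noise around a fixed point", {
  sd0 <- 0.02
  tr <- gen_trajectories(trajectory_sim_spec(
    n_particles = 50, n_frames = 50,
    immobile_fraction = 1, loc_noise_sd = sd0, seed = 13
  ))
  by_p <- split(tr, tr$particle)
  expect_true(all(vapply(by_p, function(p) var(p$x_um) <= (3 * sd0)^2, logical(1))))
  expect_true(all(vapply(by_p, function(p) var(p$y_um) <= (3 * sd0)^2, logical(1))))
})

test_that("trajectory spec validation rejects unusable parameters", {
  expect_error(trajectory_sim_spec(alpha = 2), "range")
  expect_error(trajectory_sim_spec(alpha = 0), "range")
  expect_error(trajectory_sim_spec(n_frames = 1), "range")
  expect_error(trajectory_sim_spec(immobile_fraction = 1.2), "range")
  expect_error(trajectory_sim_spec(dropout_prob = 1), "range")
  expect_error(trajectory_sim_spec(d0 = NaN), "finite")
})

test_that("FRAP generator hits the model limits", {
  # fast recovery, long trace: plateau reaches a0 + a1
  fast <- gen_frap_trace(frap_sim_spec(
    a0 = 0.15, a1 = 0.8, d = 5, w = 5, t_bleach = 2,
    duration = 4000, sample_interval = 2, acq_decay_rate = 0, noise_sd = 0, seed = 1
  ))
  expect_equal(tail(fast$data$i_frap, 1), 0.95, tolerance = 1e-2)
  expect_true(all(fast$data$i_frap[fast$data$time_s <= 2] == 1))

  # slow recovery: the first post-bleach sample sits at the floor a0
  slow <- gen_frap_trace(frap_sim_spec(
    a0 = 0.15, a1 = 0.8, d = 1e-5, w = 5, t_bleach = 2,
    duration = 20, sample_interval = 2, acq_decay_rate = 0, noise_sd = 0, seed = 1
  ))
  first_post <- slow$data$i_frap[which(slow$data$time_s > 2)[1]]
  expect_equal(first_post, 0.15, tolerance = 1e-2)

  expect_error(frap_sim_spec(a0 = 0.5, a1 = 0.6), "exceed 1")
})

test_that("pore image generator returns exact analytic ground truth", {
  # a circle is its own Feret pair: 2r in both directions
  spec <- pore_image_sim_spec(
    image_shape = c(256, 256), scale = 10, n_pores = 1,
    pore_axes_range = c(500, 500), seed = 2
  )
  res <- gen_pore_image(spec)
  expect_equal(res$truth$feret_max_nm, 1000)
  expect_equal(res$truth$feret_min_nm, 1000)
  expect_true(all(res$truth$feret_max_nm >= res$truth$feret_min_nm))

  # disjoint intensity bands binarize to exactly n_pores components
  spec2 <- pore_image_sim_spec(
    n_pores = 12, seed = 7,
    pore_intensity_range = c(0, 50), background_intensity_range = c(200, 255)
  )
  res2 <- gen_pore_image(spec2)
  rec <- label_pores(binarize(res2$image), scale = res2$image$scale_nm_per_px)
  expect_equal(nrow(rec), 12)

  # infeasible packing is rejected
  expect_error(
    gen_pore_image(pore_image_sim_spec(
      image_shape = c(64, 64), scale = 10,
      n_pores = 50, pore_axes_range = c(200, 400)
    )),
    "infeasible|failed"
  )
})

test_that("rheology generator produces gels and shear-thinning flow curves", {
  res <- gen_rheology_sweep(rheology_sim_spec(loss_ratio = 0.5, noise_rel = 0, seed = 1))
  cls <- classify_gel(res$sweep)
  expect_equal(cls$overall, "viscoelastic-solid")
  expect_true(all(cls$per_point$label == "viscoelastic-solid"))
  expect_true(all(diff(res$flow$viscosity_pa_s) < 0)) # n_flow = 0.4
  # flat G' (exponent 0) gives a constant mesh size across frequency
  flat <- gen_rheology_sweep(rheology_sim_spec(g0 = 100, exponent = 0, noise_rel = 0, seed = 1))
  mesh <- mesh_size_from_modulus(flat$sweep$g_prime_pa)
  expect_equal(diff(range(mesh$mesh_size_nm)), 0, tolerance = 1e-9)
})

test_that("binding generator follows the isotherm limits", {
  spec <- binding_sim_spec(
    kd = 0.5, conc_max = 500, n_points = 24,
    f_unbound = 800, f_bound = 900, noise_sd = 0, seed = 1
  )
  ser <- gen_binding_series(spec)
  expect_equal(ser$response[1], 900, tolerance = 0.5) # saturation
  expect_equal(tail(ser$response, 1), 800, tolerance = 0.5) # dilution floor
  expect_true(all(diff(ser$target_conc_mg_ml) < 0))
})
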