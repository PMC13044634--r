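# one moderately long trace shared by several statistical checks
shared_trace <- simulate_fcs_trace(
  sim_config(n_particles = 100, duration = 1.5, seed = 101))

test_that("a static emitter at the focus produces iid Poisson counts", {
  cfg <- sim_config(n_particles = 1, dc_true = 0, duration = 0.05,
                    brightness = 40000, background = 0, seed = 3,
                    init_positions = matrix(0, 1, 3))
  tr <- simulate_fcs_trace(cfg)
  lambda <- 40000 * cfg$dt
  n <- length(tr$counts)
  m <- mean(tr$counts)
  expect_lt(abs(m - lambda), 4 * sqrt(lambda / n))
  # index of dispersion ~ 1 for Poisson
  expect_lt(abs(var(tr$counts) / m - 1), 4 * sqrt(2 / n))
})

test_that("background-only simulation is Poisson at the background rate", {
  cfg <- sim_config(n_particles = 1, dc_true = 0, duration = 0.05,
                    brightness = 0, background = 20000, seed = 4)
  tr <- simulate_fcs_trace(cfg)
  lambda <- 20000 * cfg$dt
  expect_lt(abs(mean(tr$counts) - lambda),
            4 * sqrt(lambda / length(tr$counts)))
})

test_that("mean emission rate matches the box-averaged PSF prediction", {
  gt <- shared_trace$attrs$ground_truth
  w <- gt$psf_waist
  mean_psf <- prod(w * sqrt(pi / 2)) / prod(gt$box)
  expected <- gt$brightness * gt$n_particles * mean_psf
  rate <- mean(shared_trace$counts) / shared_trace$bin_dt
  # the trace mean is correlated on the diffusion time (~ms), so the
  # effective sample count is duration / tau_D; 3 SE on that basis
  tau_d <- 0.3^2 / (4 * gt$dc_true[1])
  n_eff <- gt$dt * length(shared_trace$counts) / tau_d
  se <- rate / sqrt(gt$n_particles * n_eff)
  expect_lt(abs(rate - expected), 3 * se + 0.01 * expected)
})

test_that("ensemble MSD grows as 2 (DCx + DCy + DCz) t", {
  cfg <- sim_config(n_particles = 60, box = c(10, 10, 10),
                    dc_true = c(20, 50, 120), duration = 0.02, dt = 1e-5,
                    brightness = 0, seed = 6)
  tr <- simulate_fcs_trace(cfg, traj_stride = 10)
  traj <- tr$attrs$trajectories      # snapshots x 3 x particles
  td <- tr$attrs$traj_dt
  n_snap <- dim(traj)[1]
  for (k in c(2, 5, 10)) {
    d2 <- (traj[seq(1, n_snap - k), , ] - traj[seq(1 + k, n_snap), , ])^2
    msd <- mean(apply(d2, c(1, 3), sum))
    se <- sd(apply(d2, c(1, 3), sum)) / sqrt(cfg$n_particles)
    expect_lt(abs(msd - 2 * sum(cfg$dc_true) * k * td), 3 * se)
  }
})

test_that("traces are reproducible by seed and differ across seeds", {
  cfg <- sim_config(n_particles = 20, duration = 0.01, seed = 42)
  t1 <- simulate_fcs_trace(cfg)
  t2 <- simulate_fcs_trace(cfg)
  expect_identical(t1$counts, t2$counts)
  cfg2 <- sim_config(n_particles = 20, duration = 0.01, seed = 43)
  expect_false(identical(simulate_fcs_trace(cfg2)$counts, t1$counts))
})

test_that("the ACF amplitude matches 1 / (V_eff <C>) for a dilute simulation", {
  gt <- shared_trace$attrs$ground_truth
  c_mean <- gt$n_particles / prod(gt$box)
  amp_expected <- 1 / (v_eff(std_psf()) * c_mean)
  a <- crop_and_downsample(acf_fcs(shared_trace, max_lag = 5e-3),
                           log_bins = 80)
  # extrapolate the amplitude with the known shape: fit just (DC, C)
  fit <- fit_nls(a, model_spec("iso1"), std_psf())
  amp_fitted <- g_fcs(0, diffusion_params("iso1",
                                          dc = fit$theta_hat[["DC"]],
                                          c_nM = fit$theta_hat[["C"]]),
                      std_psf())
  expect_lt(abs(amp_fitted - amp_expected) / amp_expected, 0.10)
})

test_that("raster sampling with zero brightness is pure background noise", {
  geom <- quick_rics_geom(n = 24, t_pix = 5e-6)
  cfg <- sim_config(n_particles = 5, box = c(5, 5, 6), dc_true = 10,
                    brightness = 0, background = 1e5, seed = 9,
                    scan = geom)
  st <- simulate_rics_stack(cfg, n_frames = 12)
  lambda <- 1e5 * geom$t_pix
  x <- as.vector(st$frames)
  expect_lt(abs(mean(x) - lambda), 4 * sqrt(lambda / length(x)))
  expect_lt(abs(var(x) / mean(x) - 1), 4 * sqrt(2 / length(x)))
})

test_that("rotating the scan by 90 degrees re-indexes the image accordingly", {
  # frozen particles on an asymmetric layout; very bright so that shot
  # noise is negligible relative to the structure
  pos <- cbind(c(-0.6, -0.2, 0.5, 0.1), c(-0.5, 0.4, -0.1, 0.6), 0)
  mk <- function(alpha) {
    geom <- quick_rics_geom(n = 21, t_pix = 2e-6, alpha = alpha,
                            s_pix = 0.08)
    cfg <- sim_config(n_particles = 4, box = c(6, 6, 6), dc_true = 0,
                      brightness = 2e9, background = 0, seed = 5,
                      scan = geom, init_positions = pos)
    simulate_rics_stack(cfg, n_frames = 1)[["frames"]][1, , ]
  }
  im0 <- mk(0)
  im90 <- mk(90)
  # im90[j, i] = im0[i, n + 1 - j]: a transpose composed with a flip
  n <- 21
  expected <- t(im0[, n:1])
  cr <- cor(as.vector(im90), as.vector(expected))
  expect_gt(cr, 0.995)
})

test_that("simulated RICS stacks recover the generating diffusion coefficient", {
  geom <- quick_rics_geom(n = 64, t_pix = 4e-6, s_pix = 0.05)
  cfg <- sim_config(n_particles = 150, box = c(5, 5, 6), dc_true = 30,
                    brightness = 1e5, seed = 21, scan = geom)
  st <- simulate_rics_stack(cfg, n_frames = 40)
  a <- crop_and_downsample(acf_rics(st), drop_first = 1, n_lines = 3,
                           points_per_line = 30)
  fit <- fit_nls(a, model_spec("iso1"), std_psf())
  expect_lt(abs(fit$theta_hat[["DC"]] - 30) / 30, 0.35)
  gt <- st$attrs$ground_truth
  expect_lt(abs(fit$theta_hat[["C"]] - gt$c_true_nM) / gt$c_true_nM, 0.35)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_particles = 0), "n_particles")
  expect_error(sim_config(dc_true = -1), "dc_true")
  expect_error(sim_config(duration = 0), "dt")
  expect_error(sim_config(brightness = Inf), "non-finite")
  expect_warning(sim_config(box = c(1, 1, 1)), "5 PSF waists")
  expect_error(
    simulate_rics_stack(sim_config(), n_frames = 1), "scan")
  expect_error(scan_geometry(1e-5, 1e-5, 0.05, 0.05, n_cols = 10,
                             n_rows = 10), "flyback")
})
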