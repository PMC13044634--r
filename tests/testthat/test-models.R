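test_that("pixel displacements rotate correctly into the sample frame", {
  g0 <- quick_rics_geom(alpha = 0, s_pix = 0.02)
  expect_equal(unname(rotate_displacement(3, 2, 0, g0)),
               matrix(c(0.06, 0.04, 0), 1))
  g90 <- quick_rics_geom(alpha = 90, s_pix = 0.02)
  expect_equal(unname(rotate_displacement(1, 0, 0, g90)),
               matrix(c(0, 0.02, 0), 1), tolerance = 1e-12)
  g30 <- quick_rics_geom(alpha = 30, s_pix = 0.02)
  expect_equal(unname(rotate_displacement(2, 1, 0, g30)),
               matrix(c(0.02 * (2 * cos(pi / 6) - sin(pi / 6)),
                        0.02 * (2 * sin(pi / 6) + cos(pi / 6)), 0), 1),
               tolerance = 1e-12)
})

test_that("lag mapping is xi * t_pix + psi * t_line", {
  g <- scan_geometry(2e-6, 2e-3, 0.05, 0.05, n_cols = 100, n_rows = 100)
  expect_equal(lag_time(0, 0, g), 0)
  expect_equal(lag_time(2, 1, g), 2.004e-3)
  g2 <- scan_geometry(3.5e-6, 3.5e-3, 0.05, 0.05, n_cols = 1000,
                      n_rows = 1000)
  expect_equal(lag_time(100, 2, g2), 7.35e-3)
})

test_that("triplet factor follows the dark-state kinetics", {
  tau <- c(1e-6, 1e-4, 1e-2)
  expect_equal(triplet_factor(tau, 0, 1e-4), rep(1, 3))
  expect_equal(triplet_factor(10, 0.3, 1e-4), 1, tolerance = 1e-12)
  # amplitude 0.11, relaxation 116 us, evaluated at one relaxation time
  expect_equal(triplet_factor(116e-6, 0.11, 116e-6), 1.045468245538,
               tolerance = 1e-10)
  expect_error(triplet_factor(1e-4, 1, 1e-4), "tsa")
})

test_that("Gaussian model has the fluctuation amplitude and closed-form decay", {
  psf <- std_psf()
  p <- diffusion_params("iso1", dc = 100, c_nM = 1)
  # zero lag: exactly 1 / (V_eff <C>)
  expect_equal(g_fcs(0, p, psf), 1 / (v_eff(psf) * 1 * 0.6022140857),
               tolerance = 1e-9)
  # independently computed high-precision value at tau = 1 ms
  expect_equal(g_fcs(1e-3, p, psf), 0.47963985557191766, tolerance = 1e-10)
})

test_that("model degeneracies and symmetries hold", {
  psf <- std_psf()
  tau <- 10^seq(-6, -1, length.out = 30)
  # f = 1 two-component collapses to the single component
  p2 <- diffusion_params("iso2", dc = 50, dc2 = 500, f = 1, c_nM = 5)
  p1 <- diffusion_params("iso1", dc = 50, c_nM = 5)
  expect_equal(g_fcs(tau, p2, psf), g_fcs(tau, p1, psf))
  # equal components equal the single component at any f
  p2b <- diffusion_params("iso2", dc = 50, dc2 = 50, f = 0.37, c_nM = 5)
  expect_equal(g_fcs(tau, p2b, psf), g_fcs(tau, p1, psf))
  # swapping x/y coefficients and displacements with wx = wy is neutral
  pa <- diffusion_params("aniso1", dc = c(20, 80, 40), c_nM = 5)
  pb <- diffusion_params("aniso1", dc = c(80, 20, 40), c_nM = 5)
  d <- cbind(0.1, 0.25, 0)
  ds <- cbind(0.25, 0.1, 0)
  expect_equal(g_gaussian(d, tau, pa, psf), g_gaussian(ds, tau, pb, psf))
})

test_that("correlation decays monotonically and vanishes at large lags", {
  psf <- std_psf()
  p <- diffusion_params("iso1", dc = 100, c_nM = 2)
  tau <- 10^seq(-6, 1, length.out = 60)
  g <- g_fcs(tau, p, psf)
  expect_true(all(diff(g) < 0))
  expect_lt(g[length(g)], 1e-3 * g[1])
  expect_lt(g_gaussian(c(5, 0, 0), 1e-4, p, psf), 1e-6 * g[1])
})

test_that("point FCS equals the spatiotemporal model at zero spatial lag", {
  psf <- std_psf()
  set.seed(3)
  for (i in 1:20) {
    p <- diffusion_params("iso1", dc = runif(1, 1, 500),
                          c_nM = runif(1, 0.5, 50),
                          tsa = runif(1, 0, 0.5), tau_t = 1e-5)
    tau <- sort(10^runif(5, -6, -2))
    expect_identical(g_fcs(tau, p, psf),
                     g_gaussian(matrix(0, 5, 3), tau, p, psf))
  }
})

test_that("lateral half-decay lag matches root finding", {
  # quasi-isolated lateral factor: make the axial waist effectively flat
  psf <- gaussian_psf(0.3, 0.3, 1e4)
  p <- diffusion_params("iso1", dc = 100, c_nM = 1)
  g0 <- g_fcs(0, p, psf)
  root <- uniroot(function(t) g_fcs(t, p, psf) / g0 - 0.5,
                  c(1e-7, 1), tol = 1e-12)$root
  expect_equal(root, 0.3^2 / (4 * 100), tolerance = 1e-4)
})

test_that("measured-PSF model matches the Gaussian closed form on a sampled grid", {
  psf <- std_psf()
  # the grid must cover the blurred support at the largest lag tested
  grid <- sample_gaussian_psf(psf, voxel = c(0.035, 0.035, 0.12),
                              half_extent = 4 * c(0.3, 0.3, 1.1))
  p <- diffusion_params("iso1", dc = 100, c_nM = 2, tsa = 0.15,
                        tau_t = 5e-5)
  # definitional zero-lag identity against the grid quadrature
  expect_equal(g_measured(c(0, 0, 0), 0, p, grid),
               triplet_factor(0, 0.15, 5e-5) /
                 (v_eff(grid) * 2 * 0.6022140857),
               tolerance = 1e-9)
  # (tau, Delta) lattice within 2% of the closed form
  for (tau in c(1e-4, 5e-4, 2e-3)) {
    for (dx in c(0, 0.1, 0.25)) {
      a <- g_measured(c(dx, 0.05, 0), tau, p, grid)
      b <- g_gaussian(c(dx, 0.05, 0), tau, p, psf)
      expect_equal(a, b, tolerance = 0.02)
    }
  }
})

test_that("measured-PSF model converges with grid refinement", {
  psf <- std_psf()
  p <- diffusion_params("iso1", dc = 100, c_nM = 2)
  tau <- 5e-4
  err <- vapply(c(0.08, 0.04, 0.02), function(v) {
    grid <- sample_gaussian_psf(psf, voxel = c(v, v, 3 * v))
    abs(g_measured(c(0.1, 0, 0), tau, p, grid) -
          g_gaussian(c(0.1, 0, 0), tau, p, psf))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("coarsening the measured PSF drifts the zero-lag value monotonically", {
  psf <- std_psf()
  grid <- sample_gaussian_psf(psf, voxel = c(0.02, 0.02, 0.06))
  p <- diffusion_params("iso1", dc = 100, c_nM = 2)
  g0 <- vapply(list(grid, downsample_psf(grid, 2), downsample_psf(grid, 3)),
               function(g) g_measured(c(0, 0, 0), 0, p, g), numeric(1))
  expect_true(all(diff(g0) > 0) || all(diff(g0) < 0))
})
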