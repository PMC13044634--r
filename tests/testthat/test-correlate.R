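test_that("temporal ACF equals the direct double-sum estimator", {
  # toy alternating trace, checked against the explicit oracle
  x <- c(2, 0, 2, 0, 2, 0, 2, 0)
  tr <- photon_trace(x, bin_dt = 1)
  a <- acf_fcs(tr, max_lag = 4)
  expect_equal(a$g, acf_direct(x, 4), tolerance = 1e-12)
  expect_equal(a$g[1], -7 / 8)  # hand value of the lag-1 estimator

  # FFT path identical to O(N^2) evaluation on random traces
  set.seed(5)
  for (n in c(257, 1024, 4096)) {
    x <- rpois(n, 3)
    tr <- photon_trace(x, bin_dt = 1e-5)
    a <- acf_fcs(tr, max_lag = 50e-5)
    expect_equal(a$g, acf_direct(x, 50), tolerance = 1e-10)
  }
})

test_that("constant traces have zero correlation and windows select data", {
  tr <- photon_trace(rep(4L, 1000), bin_dt = 1e-3)
  a <- acf_fcs(tr, max_lag = 0.05)
  expect_true(all(abs(a$g) < 1e-14))

  # the window restricts estimation to the selected segment
  x <- c(rep(0L, 500), rpois(500, 5))
  tr2 <- photon_trace(x, bin_dt = 1e-3)
  aw <- acf_fcs(tr2, window = c(0.5, 1.0), max_lag = 0.02)
  ref <- acf_direct(x[501:1000], 20)
  expect_equal(aw$g, ref, tolerance = 1e-10)
  expect_error(acf_fcs(tr2, window = c(0.2, 0.2), max_lag = 0.01), "empty")
  expect_error(acf_fcs(photon_trace(c(0L, 0L, 0L), 1), max_lag = 1), "zero mean")
})

test_that("spatial ACF equals the brute-force double sum", {
  img <- matrix(0, 4, 4)
  img[2, 3] <- 5
  st <- image_stack(array(img, c(1, 4, 4)), quick_rics_geom(4))
  a <- acf_rics(st, xi_max = 2, psi_max = 2)
  expect_equal(a$g, acf2d_direct(img, 2, 2), tolerance = 1e-10)

  set.seed(8)
  img2 <- matrix(rpois(12 * 12, 4), 12, 12)
  st2 <- image_stack(array(img2, c(1, 12, 12)), quick_rics_geom(12))
  a2 <- acf_rics(st2, xi_max = 3, psi_max = 3)
  expect_equal(a2$g, acf2d_direct(img2, 3, 3), tolerance = 1e-10)
})

test_that("constant frames yield zero spatial correlation", {
  st <- image_stack(array(3L, c(2, 8, 8)), quick_rics_geom(8))
  a <- acf_rics(st)
  expect_true(all(abs(a$g) < 1e-14))
})

test_that("the psi = 0 line matches the temporal estimator on per-row streams", {
  # spatial lags along the fast axis are temporal lags of xi * t_pix, so
  # the psi = 0 spatial ACF must agree with the per-row temporal sums
  set.seed(9)
  img <- matrix(rpois(16 * 16, 6), 16, 16)
  st <- image_stack(array(img, c(1, 16, 16)), quick_rics_geom(16))
  a <- acf_rics(st, xi_max = 5, psi_max = 0)
  mu <- mean(img)
  d <- img - mu
  direct <- vapply(0:5, function(xi) {
    s <- 0; cnt <- 0
    for (r in 1:16) {
      v <- d[r, ]
      if (xi == 0) { s <- s + sum(v * v); cnt <- cnt + 16 }
      else {
        s <- s + sum(v[1:(16 - xi)] * v[(xi + 1):16])
        cnt <- cnt + 16 - xi
      }
    }
    s / cnt / mu^2
  }, numeric(1))
  expect_equal(a$g[1, a$xi >= 0], direct, tolerance = 1e-10)
})

test_that("iid noise frames decorrelate at nonzero lags", {
  set.seed(10)
  n <- 40
  st <- image_stack(array(rpois(20 * n * n, 5), c(20, n, n)),
                    quick_rics_geom(n))
  a <- acf_rics(st, xi_max = 4, psi_max = 2)
  nz <- a$g
  nz[a$psi == 0, a$xi == 0] <- NA
  expect_true(all(abs(nz) < 4 / sqrt(20 * n * n), na.rm = TRUE))
})

test_that("background subtraction removes a stationary structure", {
  set.seed(12)
  n <- 24
  structure_img <- outer(sin(seq(0, pi, length.out = n)),
                         cos(seq(0, 2 * pi, length.out = n))) * 3 + 5
  frames <- array(0, c(30, n, n))
  for (f in 1:30) frames[f, , ] <- rpois(n * n, structure_img)
  st <- image_stack(frames, quick_rics_geom(n))
  bg <- apply(frames, c(2, 3), mean)
  a_bg <- acf_rics(st, background = bg, mode = "background_subtract",
                   xi_max = 4, psi_max = 2)
  a_raw <- acf_rics(st, xi_max = 4, psi_max = 2)
  # without subtraction the structure dominates distant lags; with it the
  # far-lag correlation collapses toward zero
  far_raw <- mean(abs(a_raw$g[, abs(a_raw$xi) >= 3]))
  far_bg <- mean(abs(a_bg$g[, abs(a_bg$xi) >= 3]))
  expect_lt(far_bg, far_raw / 5)
  expect_error(acf_rics(st, mode = "background_subtract"), "background")
})

test_that("sector splitting distributes regions evenly inside the image", {
  # whole image when a single self-correlated sector is requested
  g1 <- sector_grid("sector_self", 1, 1, sector_size = 10)
  s1 <- split_sectors(c(1000, 1000), g1, c(0.01, 0.01))
  expect_identical(s1$region[[1]], c(1L, 1000L, 1L, 1000L))

  # containment with even spacing: centres at 200/500/800 for 400-px areas
  g3 <- sector_grid("larger_self", 3, 3, sector_size = 1, corr_size = 4)
  s3 <- split_sectors(c(1000, 1000), g3, c(0.01, 0.01))
  expect_identical(sort(unique(s3$center_col)), c(200L, 500L, 800L))
  expect_identical(sort(unique(s3$center_row)), c(200L, 500L, 800L))
  for (r in s3$region)
    expect_true(r[1] >= 1 && r[3] >= 1 && r[2] <= 1000 && r[4] <= 1000)

  # the 25 x 25 grid of 0.8 um sectors with 3 um correlation areas
  g25 <- sector_grid("larger_self", 25, 25, sector_size = 0.8, corr_size = 3)
  s25 <- split_sectors(c(1000, 1000), g25, c(0.02, 0.02))
  expect_identical(nrow(s25), 625L)

  # sector_self tiles disjointly
  gt <- sector_grid("sector_self", 4, 4, sector_size = 2)
  stiles <- split_sectors(c(400, 400), gt, c(0.02, 0.02))
  regions <- do.call(rbind, stiles$region)
  for (i in 1:15) for (j in (i + 1):16) {
    ri <- regions[i, ]; rj <- regions[j, ]
    overlap <- max(0, min(ri[2], rj[2]) - max(ri[1], rj[1]) + 1) *
      max(0, min(ri[4], rj[4]) - max(ri[3], rj[3]) + 1)
    expect_identical(overlap, 0)
  }

  # pair configuration nests the reference inside the correlation area
  gp <- sector_grid("pair", 2, 2, sector_size = 0.4, corr_size = 2)
  sp <- split_sectors(c(500, 500), gp, c(0.01, 0.01))
  for (k in seq_len(nrow(sp))) {
    ref <- sp$reference[[k]]; reg <- sp$region[[k]]
    expect_true(ref[1] >= reg[1] && ref[2] <= reg[2] &&
                  ref[3] >= reg[3] && ref[4] <= reg[4])
  }
  expect_error(split_sectors(c(100, 100), g3, c(0.001, 0.001)), "larger")
})

test_that("cropping and downsampling behave as documented", {
  lags <- (1:5000) * 1e-6
  g <- 1 / (1 + lags / 1e-3)
  cu <- acf_curve(lags, g)
  expect_equal(crop_and_downsample(cu, drop_first = 0), cu)

  # log binning matches per-bin averaging done directly
  ds <- crop_and_downsample(cu, log_bins = 100)
  expect_lte(nrow(ds), 100)
  bins <- corrspec:::log_bin_index(lags, 100)
  expect_equal(ds$g, as.vector(tapply(g, bins, mean)), tolerance = 1e-12)
  expect_equal(ds$lag, as.vector(tapply(lags, bins, mean)), tolerance = 1e-12)

  expect_error(crop_and_downsample(cu, drop_first = 5000), "nothing left")

  # RICS quadrant: 3 lines with at most 100 points each, ~300 points
  set.seed(13)
  st <- image_stack(array(rpois(2 * 256 * 256, 4), c(2, 256, 256)),
                    quick_rics_geom(256))
  a <- acf_rics(st)
  cr <- crop_and_downsample(a, drop_first = 1, n_lines = 3,
                            points_per_line = 100)
  expect_identical(dim(cr$g), c(3L, 100L))
  expect_identical(length(cr$psi), 3L)
  expect_true(all(cr$xi >= 1))
})

test_that("averaging replicate curves attaches the across-trace SEM", {
  set.seed(14)
  curves <- lapply(1:20, function(i) model_curve(noise = 0.05, seed = i))
  m <- acf_mean(curves)
  expect_identical(attr(m, "n_traces"), 20L)
  G <- vapply(curves, function(cu) cu$g, numeric(nrow(m)))
  expect_equal(m$sigma, apply(G, 1, sd) / sqrt(20))
  expect_error(acf_mean(list(curves[[1]], model_curve(n = 40))),
               "mismatched")
})
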