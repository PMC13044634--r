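test_that("the empirical covariance follows the replicate-ACF definition", {
  c1 <- acf_curve(c(1, 2), c(1, 2))
  c2 <- acf_curve(c(1, 2), c(3, 0))
  em <- suppressWarnings(estimate_covariance(list(c1, c2)))
  expect_equal(em$cov, matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)
  # the mean-ACF target rescales the same matrix by 1/N
  emm <- suppressWarnings(estimate_covariance(list(c1, c2), target = "mean"))
  expect_equal(emm$cov, matrix(c(2, -2, -2, 2), 2) / 2, ignore_attr = TRUE)
  expect_equal(emm$cov_single, em$cov)

  # identical curves give a zero matrix (validated with jitter)
  expect_error(estimate_covariance(list(c1)), "at least 2")
  em0 <- suppressWarnings(suppressMessages(
    estimate_covariance(list(c1, c1, c1))))
  expect_true(all(em0$cov == 0))

  # on a simulated cohort the estimate is symmetric positive definite
  set.seed(20)
  curves <- lapply(1:150, function(i) model_curve(n = 30, noise = 0.03,
                                                  seed = i))
  emc <- estimate_covariance(curves)
  expect_equal(emc$cov, t(emc$cov))
  expect_true(all(diag(emc$cov) > 0))
  expect_true(all(eigen(emc$cov, only.values = TRUE)$values > 0))
  expect_error(estimate_covariance(list(c1, acf_curve(c(1, 3), c(1, 1)))),
               "mismatched")
})

test_that("chi-squared respects the weight structure of each error model", {
  y <- c(1, 2); f0 <- y
  expect_equal(chi_squared(y, f0, em_ols()), 0)
  expect_equal(chi_squared(y, f0, em_wls(c(1, 2))), 0)
  # WLS: (1/1)^2 + (2/2)^2 = 2
  expect_equal(chi_squared(c(2, 4), c(1, 2), em_wls(c(1, 2))), 2)
  # GLS hand inverse: r = (1,1), Sigma = [[2,1],[1,2]] -> 2/3
  em <- em_gls(matrix(c(2, 1, 1, 2), 2))
  expect_equal(chi_squared(c(1, 1), c(0, 0), em), 2 / 3)
  expect_error(chi_squared(1:3, 1:2, em_ols()), "length")
})

test_that("objective identities: GLS(diag) = WLS and WLS(equal) = scaled OLS", {
  set.seed(21)
  y <- rnorm(40); f <- rnorm(40)
  s <- runif(40, 0.5, 2)
  expect_equal(chi_squared(y, f, em_gls(diag(s^2))),
               chi_squared(y, f, em_wls(s)), tolerance = 1e-12)
  expect_equal(chi_squared(y, f, em_wls(rep(2, 40))),
               chi_squared(y, f, em_ols()) / 4, tolerance = 1e-12)
})

test_that("noiseless curves are recovered to optimizer tolerance", {
  cu <- model_curve(dc = 180, c_nM = 12, n = 60, noise = 0)
  fit <- fit_nls(cu, model_spec("iso1"), std_psf())
  expect_equal(unname(fit$theta_hat["DC"]), 180, tolerance = 1e-6)
  expect_equal(unname(fit$theta_hat["C"]), 12, tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-12)
  g <- goodness_of_fit(fit)
  expect_equal(g$ssr, 0, tolerance = 1e-15)
  expect_true(fit$converged)

  # with triplet kinetics included
  cu2 <- model_curve(dc = 80, c_nM = 6, n = 80, tsa = 0.2, tau_t = 3e-5)
  fit2 <- fit_nls(cu2, model_spec("iso1", triplet = TRUE), std_psf())
  expect_equal(unname(fit2$theta_hat[c("DC", "C", "TSA", "tauT")]),
               c(80, 6, 0.2, 3e-5), tolerance = 1e-4)
})

test_that("weighted fits report calibrated reduced chi-squared", {
  set.seed(22)
  noise <- 0.02
  cu <- model_curve(dc = 100, c_nM = 4, n = 200, noise = noise)
  fit <- fit_nls(cu, model_spec("iso1"), std_psf(), em_wls())
  expect_lt(abs(fit$chi2_red - 1), 4 * sqrt(2 / (fit$n - fit$p)))
  # GLS chi2 equals the squared norm of decorrelated residuals
  emg <- em_gls(diag(noise^2, 200))
  fitg <- fit_nls(cu, model_spec("iso1"), std_psf(), emg)
  expect_equal(fitg$chi2, sum(fitg$residuals$decorrelated^2))
})

test_that("GLS fitting of 2D correlation data is refused with an explanation", {
  set.seed(23)
  st <- image_stack(array(rpois(2 * 32 * 32, 5), c(2, 32, 32)),
                    quick_rics_geom(32))
  a <- crop_and_downsample(acf_rics(st), drop_first = 1)
  em <- em_gls(diag(1, nrow(corrspec:::build_fit_points(a))))
  expect_error(fit_nls(a, model_spec("iso1"), std_psf(), em),
               "not supported for RICS")
  expect_error(fit_bayes(a, model_spec("iso1"), std_psf(), em),
               "not supported for RICS")
})

test_that("the F-test follows the nested-model formula", {
  mk <- function(chi2, n, p) structure(
    list(chi2 = chi2, n = n, p = p, em_mode = "OLS"), class = "ccs_fit")
  # equal objectives: F = 0, p = 1
  r0 <- f_test_nested(mk(100, 100, 3), mk(100, 100, 5))
  expect_equal(r0$F, 0)
  expect_equal(r0$p_value, 1)
  # hand arithmetic: ((120-100)/2) / (100/95) = 9.5
  r <- f_test_nested(mk(120, 100, 3), mk(100, 100, 5))
  expect_equal(r$F, 9.5)
  expect_equal(r$p_value, pf(9.5, 2, 95, lower.tail = FALSE))
  expect_error(f_test_nested(mk(90, 100, 3), mk(100, 100, 5)), "worse")
  expect_error(f_test_nested(mk(120, 100, 5), mk(100, 100, 3)),
               "more parameters")
})

test_that("the F-test is calibrated under the simple model", {
  # data simulated from the simple model: p-values should not concentrate
  # at small values (reduced-replication type-I check)
  set.seed(24)
  pvals <- replicate(20, {
    cu <- model_curve(dc = 100, c_nM = 4, n = 60, noise = 0.03)
    fs <- fit_nls(cu, model_spec("iso1"), std_psf())
    fc <- fit_nls(cu, model_spec("iso2"), std_psf())
    if (fc$chi2 > fs$chi2) fc$chi2 <- fs$chi2  # optimizer tie
    f_test_nested(fs, structure(fc, class = "ccs_fit"))$p_value
  })
  expect_gt(mean(pvals > 0.05), 0.6)
})

test_that("nested sampling reproduces the analytic evidence of a conjugate toy", {
  set.seed(42)
  y <- rnorm(30, mean = 2.3, sd = 0.5)
  s <- 0.5; a <- 0; b <- 5
  loglik <- function(mu) sum(dnorm(y, mu, s, log = TRUE))
  f <- Vectorize(function(mu) exp(loglik(mu) + 40))
  logZ_true <- log(integrate(f, a, b)$value / (b - a)) - 40
  run <- corrspec:::ns_run(function(u) loglik(a + u * (b - a)), 1,
                           n_live = 200)
  expect_lt(abs(run$log_z - logZ_true), 3 * run$log_z_err)
  # posterior mean matches the conjugate posterior mean
  mu_hat <- sum(exp(run$logwt) * (a + run$u[, 1] * (b - a)))
  expect_equal(mu_hat, mean(y), tolerance = 3 * s / sqrt(30) / 5)
})

test_that("a flat likelihood returns the prior and unit evidence", {
  set.seed(25)
  run <- corrspec:::ns_run(function(u) 0, 2, n_live = 100)
  expect_lt(abs(run$log_z), 0.2)
  w <- exp(run$logwt)
  expect_equal(sum(w * run$u[, 1]), 0.5, tolerance = 0.1)
  expect_equal(sum(w * run$u[, 2]), 0.5, tolerance = 0.1)
})

test_that("Bayesian OLS infers the noise scale and matches NLS estimates", {
  set.seed(26)
  cu <- model_curve(dc = 100, c_nM = 4, n = 80, noise = 0.03)
  post <- fit_bayes(cu, model_spec("iso1"), std_psf(), em_ols(),
                    n_live = 120, seed = 8)
  s <- post$summary
  expect_equal(s$mean[s$name == "sigma_err"], 0.03, tolerance = 0.35)
  fit <- fit_nls(cu, model_spec("iso1"), std_psf())
  expect_equal(s$mean[s$name == "DC"], unname(fit$theta_hat["DC"]),
               tolerance = 0.05)
  # quantile ranges are nested
  expect_true(all(s$q_lo95 <= s$q_lo68 & s$q_hi68 <= s$q_hi95))
  # goodness of fit evaluated at the posterior median
  expect_true(all(c("ssr", "chi2", "chi2_red") %in%
                    names(goodness_of_fit(post))))
})

test_that("evidence comparison ranks, bands, and refuses mixed error models", {
  mk <- function(lz, err, mode, kind = "iso1", trip = FALSE) structure(
    list(log_z = lz, log_z_err = err, em_mode = mode, n = 100,
         spec = model_spec(kind, triplet = trip)),
    class = "ccs_posterior")
  r <- compare_evidence(list(mk(19.0, 0.3, "GLS"),
                             mk(8.2, 0.3, "GLS", "iso2"),
                             mk(16.8, 0.4, "GLS", "iso1", TRUE),
                             mk(6.3, 0.5, "GLS", "iso2", TRUE)))
  expect_identical(r$model[1], "iso1")
  expect_identical(r$band[1], "best")
  expect_identical(r$band[r$model == "iso1+triplet"], "positive")
  expect_identical(r$band[r$model == "iso2+triplet"], "very strong")
  d <- mk(19.2, 0.3, "GLS")
  rr <- compare_evidence(list(mk(19.0, 0.3, "GLS"), d))
  expect_identical(rr$band[2], "indistinguishable")
  expect_error(compare_evidence(list(mk(1, 0.1, "OLS"), mk(2, 0.1, "GLS"))),
               "mixed error models")
})

test_that("two-component parameters respect the identifiability constraint", {
  expect_error(diffusion_params("iso2", dc = 100, dc2 = 50, f = 0.5,
                                c_nM = 1), "DC1 < DC2")
  # the (DC1, dDC) parameterization keeps DC2 above DC1 by construction
  pt <- corrspec:::param_table(model_spec("iso2"))
  expect_true(all(c("DC1", "dDC", "f", "C") %in% pt$name))
  th <- c(DC1 = 30, dDC = 200, f = 0.4, C = 5)
  p <- corrspec:::theta_to_params(model_spec("iso2"), th)
  expect_equal(p$dc2[1], 230)
})

test_that("prior bounds default to the documented ranges and can be overridden", {
  pr <- prior_spec()
  expect_equal(pr$DC, c(0, 5000))
  expect_equal(pr$C, c(0, 1000))
  expect_equal(pr$TSA, c(0, 1))
  expect_equal(pr$tauT, c(1e-8, 1e-2))
  expect_equal(pr$scale, c(0, 2))
  pr2 <- prior_spec(DC = c(10, 500))
  expect_equal(unname(corrspec:::param_table(model_spec("aniso1"),
                                             pr2)$lower[1:3]),
               rep(10, 3))
  expect_error(prior_spec(DC = c(5, 1)), "lower < upper")
})
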