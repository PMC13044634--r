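# Static nested sampling with MCMC-constrained replacement.
#
# Works in the unit hypercube; the caller supplies a log-likelihood over
# unit-cube coordinates (prior mass is uniform there by construction, so
# the prior transform carries the actual box priors).  Live-point
# replacement uses a Gaussian random-walk whose proposal covariance is the
# sample covariance of the current live set, with step-size adaptation
# toward a target acceptance rate.  Evidence error is the usual
# information-based estimate sqrt(H / n_live).

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

ns_run <- function(loglik_u, n_dim, n_live = 200, dlogz = 0.05,
                   n_mcmc = 25, max_iter = 200000) {
  U <- matrix(runif(n_live * n_dim), n_live, n_dim)
  logL <- apply(U, 1, loglik_u)
  n_call <- n_live

  dead_u <- matrix(NA_real_, 0, n_dim)
  dead_logL <- numeric(0)
  dead_logw <- numeric(0)
  logz <- -Inf
  log_x_prev <- 0
  step <- 0.5
  it <- 0

  propose_chol <- function() {
    S <- cov(U)
    S <- S + diag(1e-10, n_dim)
    t(chol(S)) * (2.38 / sqrt(n_dim))
  }
  Lp <- propose_chol()

  while (it < max_iter) {
    it <- it + 1
    worst <- which.min(logL)
    L_min <- logL[worst]
    log_x <- -it / n_live
    logw <- log_x_prev + log(1 - exp(log_x - log_x_prev))
    dead_u <- rbind(dead_u, U[worst, ])
    dead_logL <- c(dead_logL, L_min)
    dead_logw <- c(dead_logw, logw)
    logz <- logsumexp(c(logz, L_min + logw))
    log_x_prev <- log_x

    # replacement: constrained random walk from a random live point
    if (it %% 20 == 0) Lp <- propose_chol()
    found <- FALSE
    for (attempt in 1:5) {
      src <- sample.int(n_live, 1)
      u <- U[src, ]
      l <- logL[src]
      n_acc <- 0
      for (s in seq_len(n_mcmc)) {
        u_new <- u + step * as.vector(Lp %*% rnorm(n_dim))
        if (any(u_new <= 0 | u_new >= 1)) next
        l_new <- loglik_u(u_new)
        n_call <- n_call + 1
        if (l_new > L_min) {
          u <- u_new
          l <- l_new
          n_acc <- n_acc + 1
        }
      }
      acc <- n_acc / n_mcmc
      if (acc > 0.5) step <- min(step * 1.3, 10)
      else if (acc < 0.15) step <- max(step / 1.3, 1e-4)
      if (n_acc > 0 && src != worst) { found <- TRUE; break }
      if (n_acc > 0 && src == worst) { found <- TRUE; break }
    }
    if (!found) {
      # could not move: replicate a random other live point (degenerate
      # but keeps the run alive; surfaced via the diagnostics field)
      src <- sample.int(n_live, 1)
      u <- U[src, ]
      l <- logL[src]
    }
    U[worst, ] <- u
    logL[worst] <- l

    # termination: remaining evidence below tolerance
    logz_remain <- max(logL) + log_x
    if (it > 2 * n_live &&
        logsumexp(c(logz, logz_remain)) - logz < dlogz) break
  }

  # drain the live points at the final prior volume
  log_x_final <- -it / n_live - log(n_live)
  ord <- order(logL)
  dead_u <- rbind(dead_u, U[ord, , drop = FALSE])
  dead_logL <- c(dead_logL, logL[ord])
  dead_logw <- c(dead_logw, rep(log_x_final, n_live))
  logz <- logsumexp(dead_logL + dead_logw)

  logwt <- dead_logL + dead_logw - logz
  H <- sum(exp(logwt) * (dead_logL - logz))
  list(u = dead_u, logL = dead_logL, logwt = logwt,
       log_z = logz, log_z_err = sqrt(max(H, 0) / n_live),
       n_call = n_call, n_iter = it, information = H)
}

# weighted quantile for normalized weights
wquantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Fit a correlation model by Bayesian nested sampling
#'
#' Samples the posterior of the model parameters under independent uniform
#' priors on the bound intervals and the Gaussian likelihood matching the
#' error model: a single inferred noise scale for OLS (log-uniform prior
#' spanning 1e-6 to 1e2 times the data scale), per-point standard
#' deviations for WLS, and the full empirical covariance (quadratic form
#' and normalization through its Cholesky factor) for GLS.  Nested
#' sampling yields weighted posterior samples and the log-evidence
#' `log Z` with its information-based uncertainty, used for model
#' comparison.
#'
#' @inheritParams fit_nls
#' @param n_live number of live points.
#' @param n_mcmc random-walk steps per live-point replacement (more steps
#'   reduce run-to-run log-evidence scatter for hard posteriors, e.g.
#'   model comparison involving weakly constrained kinetic parameters).
#' @param dlogz evidence termination tolerance.
#' @param seed optional integer; when given, sampling is reproducible (the
#'   global RNG state is restored afterwards).
#' @param n_predictive number of equal-weight posterior draws used for the
#'   posterior-predictive quantile bands.
#' @return An object of class `ccs_posterior`: `summary` (tibble of
#'   weighted posterior statistics per parameter), `samples` (equal-weight
#'   draws), `log_z`, `log_z_err`, `predictive` (per-point median and
#'   68.3/95.5% quantile-range bands), `gof` (goodness of fit at the
#'   posterior median), and sampler diagnostics.
#' @export
fit_bayes <- function(data, spec, psf, em = em_ols(),
                      priors = prior_spec(), n_live = 200, n_mcmc = 25,
                      dlogz = 0.05, seed = NULL, n_predictive = 300) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  points <- build_fit_points(data)
  pt <- param_table(spec, priors, n_cond = max(points$condition))
  n <- nrow(points)
  check_gls_applicable(em, points)
  y <- points$g

  infer_sigma <- em$mode == "OLS"
  if (infer_sigma) {
    data_scale <- sd(y)
    lsig_lo <- log(1e-6 * data_scale)
    lsig_hi <- log(1e2 * data_scale)
    pt <- dplyr::bind_rows(pt, tibble::tibble(name = "sigma_err",
                                              lower = NA, upper = NA))
  }
  p <- nrow(pt)
  if (n <= p) stop("need more data points than parameters")
  sig_w <- if (em$mode == "WLS") resolve_wls_sigma(em, points)
  if (em$mode == "WLS") em$sigma <- sig_w
  const_wls <- if (em$mode == "WLS") -sum(log(2 * pi * sig_w^2)) / 2
  const_gls <- if (em$mode == "GLS")
    -n / 2 * log(2 * pi) - sum(log(diag(em$chol)))

  transform <- function(u) {
    th <- numeric(p)
    for (i in seq_len(p)) {
      if (infer_sigma && pt$name[i] == "sigma_err")
        th[i] <- exp(lsig_lo + u[i] * (lsig_hi - lsig_lo))
      else th[i] <- pt$lower[i] + u[i] * (pt$upper[i] - pt$lower[i])
    }
    names(th) <- pt$name
    th
  }

  loglik_theta <- function(th) {
    f <- tryCatch(model_values(spec, th, points, psf),
                  error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f))) return(-1e300)
    r <- y - f
    switch(em$mode,
      OLS = {
        s <- th[["sigma_err"]]
        -n / 2 * log(2 * pi * s^2) - sum(r^2) / (2 * s^2)
      },
      WLS = const_wls - sum((r / sig_w)^2) / 2,
      GLS = const_gls - sum(decorrelate(r, em)^2) / 2)
  }
  loglik_u <- function(u) loglik_theta(transform(u))

  run <- ns_run(loglik_u, n_dim = p, n_live = n_live, n_mcmc = n_mcmc,
                dlogz = dlogz)
  theta <- t(apply(run$u, 1, transform))
  colnames(theta) <- pt$name
  w <- exp(run$logwt)
  w <- w / sum(w)

  qs <- c(0.02275, 0.15865, 0.5, 0.84135, 0.97725)
  summ <- purrr::map_dfr(seq_len(p), function(i) {
    x <- theta[, i]
    qq <- wquantile(x, w, qs)
    tibble::tibble(name = pt$name[i],
                   mean = sum(w * x),
                   sd = sqrt(max(sum(w * x^2) - sum(w * x)^2, 0)),
                   median = qq[3], q_lo68 = qq[2], q_hi68 = qq[4],
                   q_lo95 = qq[1], q_hi95 = qq[5])
  })

  # equal-weight resample for predictive bands and downstream use
  n_eq <- max(n_predictive, 1000)
  idx <- sample.int(nrow(theta), n_eq, replace = TRUE, prob = w)
  samples <- theta[idx, , drop = FALSE]

  pred_idx <- idx[seq_len(min(n_predictive, n_eq))]
  fmat <- vapply(pred_idx, function(i)
    model_values(spec, theta[i, ], points, psf), numeric(n))
  pq <- t(apply(fmat, 1, quantile, probs = qs, names = FALSE))
  predictive <- tibble::tibble(
    condition = points$condition, tau = points$tau, g = y,
    f_median = pq[, 3], f_lo68 = pq[, 2], f_hi68 = pq[, 4],
    f_lo95 = pq[, 1], f_hi95 = pq[, 5])

  med <- setNames(summ$median, summ$name)
  f_med <- model_values(spec, med, points, psf)
  gof_em <- if (em$mode == "OLS") {
    structure(list(mode = "WLS", sigma = rep(med[["sigma_err"]], n)),
              class = "error_model")
  } else em
  chi2 <- chi_squared(y, f_med, gof_em)
  ssr <- sum((y - f_med)^2)
  n_fit_par <- sum(pt$name != "sigma_err")
  gof <- list(ssr = ssr, chi2 = chi2, chi2_red = chi2 / (n - n_fit_par))

  structure(list(summary = summ, samples = samples, weights = w,
                 theta_all = theta, logwt = run$logwt,
                 log_z = run$log_z, log_z_err = run$log_z_err,
                 information = run$information, n_call = run$n_call,
                 n_iter = run$n_iter, n = n, p = n_fit_par,
                 predictive = predictive, gof = gof, points = points,
                 spec = spec, psf = psf, em_mode = em$mode,
                 fitted_median = f_med),
            class = "ccs_posterior")
}

#' @export
print.ccs_posterior <- function(x, ...) {
  cat(sprintf("<ccs_posterior> %s%s, %s errors: log Z = %.2f +/- %.2f (%d likelihood calls)\n",
              x$spec$kind, if (x$spec$triplet) "+triplet" else "",
              x$em_mode, x$log_z, x$log_z_err, x$n_call))
  s <- x$summary
  cat(sprintf("  %s = %.4g +/- %.3g  [68.3%% QR %.4g..%.4g]",
              s$name, s$mean, s$sd, s$q_lo68, s$q_hi68), sep = "\n")
  invisible(x)
}

#' @export
goodness_of_fit.ccs_posterior <- function(fit) fit$gof

#' Rank models by Bayesian evidence
#'
#' Orders posterior results by log-evidence and reports pairwise
#' differences against the best model with combined uncertainties and the
#' conventional interpretation bands: |dlogZ| < 1 indistinguishable, 1-3
#' positive, 3-5 strong, > 5 very strong evidence.  All results must come
#' from the same data and error model (mixing error models invalidates the
#' comparison and is refused).
#'
#' @param results list of `ccs_posterior` objects.
#' @param labels optional model labels.
#' @return A tibble ranked by `log_z`.
#' @export
compare_evidence <- function(results, labels = NULL) {
  if (length(results) < 2) stop("need at least two results")
  modes <- vapply(results, function(r) r$em_mode, character(1))
  if (length(unique(modes)) != 1)
    stop("mixed error models: evidence comparison invalid")
  ns <- vapply(results, function(r) r$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("results fit different data (point counts differ)")
  if (is.null(labels))
    labels <- vapply(results, function(r)
      paste0(r$spec$kind, if (r$spec$triplet) "+triplet" else ""),
      character(1))
  lz <- vapply(results, function(r) r$log_z, numeric(1))
  le <- vapply(results, function(r) r$log_z_err, numeric(1))
  best <- which.max(lz)
  d <- lz[best] - lz
  derr <- sqrt(le^2 + le[best]^2)
  band <- dplyr::case_when(
    abs(d) < 1 ~ "indistinguishable",
    abs(d) <= 3 ~ "positive",
    abs(d) <= 5 ~ "strong",
    TRUE ~ "very strong")
  band[best] <- "best"
  out <- tibble::tibble(model = labels, log_z = lz, log_z_err = le,
                        delta_log_z = d, delta_err = derr, band = band)
  dplyr::arrange(out, dplyr::desc(.data$log_z))
}
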