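#' Error models for correlation-curve fitting
#'
#' Define the weight structure of the chi-squared objective
#' `chi^2(theta) = r^T W r` and of the Gaussian likelihood: `em_ols()`
#' uses uniform errors (`W = I`), `em_wls()` per-point standard deviations
#' (`W = diag(1/sigma^2)`), and `em_gls()` a full covariance matrix
#' (`W = Sigma^-1`, applied through its Cholesky factorization, never an
#' explicit inverse).
#'
#' @param sigma per-point standard deviations (WLS); if omitted, taken
#'   from the data's `sigma` column at fit time.
#' @param cov covariance matrix Sigma (GLS).
#' @return An object of class `error_model`.
#' @export
em_ols <- function() structure(list(mode = "OLS"), class = "error_model")

#' @rdname em_ols
#' @export
em_wls <- function(sigma = NULL) {
  if (!is.null(sigma) && any(sigma <= 0)) stop("WLS sigma must be > 0")
  structure(list(mode = "WLS", sigma = sigma), class = "error_model")
}

#' @rdname em_ols
#' @export
em_gls <- function(cov) {
  v <- validate_covariance(cov)
  structure(list(mode = "GLS", cov = v$cov, chol = v$chol,
                 jitter = v$jitter),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model> %s%s\n", x$mode,
              if (x$mode == "GLS") sprintf(" (%d x %d covariance)",
                                           nrow(x$cov), ncol(x$cov)) else ""))
  invisible(x)
}

# symmetrize, then factorize with escalating diagonal jitter; hard error
# rather than silent pseudo-inversion
validate_covariance <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("cov must be square")
  S <- (S + t(S)) / 2
  mean_diag <- mean(diag(S))
  jit_base <- if (mean_diag > 0) mean_diag else 1
  for (jit in c(0, 1e-12, 1e-10, 1e-8) * jit_base) {
    R <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
    if (!is.null(R)) {
      if (jit > 0)
        message(sprintf("covariance regularized with diagonal jitter %.3g", jit))
      return(list(cov = S, chol = R, jitter = jit))
    }
  }
  stop("covariance matrix is not positive definite (after jitter escalation)")
}

#' Empirical lag covariance from replicate ACFs
#'
#' Sample covariance of the per-trace ACF values across N replicate
#' curves on an identical lag grid, with the usual `1/(N-1)`
#' normalization.  The result is symmetrized and validated positive
#' definite (minimal diagonal jitter if needed).  Reliable estimation
#' requires N substantially larger than the number of lags; a warning is
#' issued when `N < 3 * n_lags`.
#'
#' @param acfs list of [acf_curve()] objects on the same lag grid (N >= 2).
#' @param target `"single"` (default) returns the per-trace covariance of
#'   the replicate-ACF definition, which is the matrix conventionally
#'   plugged into the GLS weight and likelihood when fitting the cohort
#'   mean -- it keeps the effective information content at the
#'   single-trace level and yields the characteristically broad GLS
#'   posteriors; `"mean"` rescales by `1/N` so the matrix describes the
#'   sampling covariance of the mean ACF itself (the statistically
#'   calibrated choice for pooled point estimation; see the methods
#'   vignette).
#' @return An `error_model` of mode GLS carrying the covariance (the
#'   per-trace matrix is always kept in `$cov_single`).
#' @export
estimate_covariance <- function(acfs, target = c("single", "mean")) {
  target <- match.arg(target)
  if (length(acfs) < 2) stop("at least 2 curves required")
  lags <- acfs[[1]]$lag
  for (a in acfs)
    if (!isTRUE(all.equal(a$lag, lags))) stop("mismatched lag grids")
  G <- t(vapply(acfs, function(a) a$g, numeric(length(lags))))
  if (nrow(G) < 3 * ncol(G))
    warning(sprintf(
      "only %d traces for %d lags; covariance estimation wants N >> n_lags",
      nrow(G), ncol(G)))
  S <- cov(G)
  em <- em_gls(if (target == "mean") S / nrow(G) else S)
  em$cov_single <- S
  em$n_traces <- nrow(G)
  em$lags <- lags
  em
}

#' Chi-squared statistic under an error model
#'
#' `chi^2 = [y - f]^T W [y - f]` with `W` determined by the error model:
#' identity (OLS), `diag(1/sigma^2)` (WLS), or `Sigma^-1` via Cholesky
#' factorization (GLS).
#'
#' @param y observed values.
#' @param f model values (same length).
#' @param em an `error_model`.
#' @return The chi-squared value.
#' @export
chi_squared <- function(y, f, em) {
  if (length(y) != length(f)) stop("length mismatch")
  r <- y - f
  switch(em$mode,
         OLS = sum(r^2),
         WLS = {
           if (is.null(em$sigma)) stop("WLS error model has no sigma")
           sum((r / em$sigma)^2)
         },
         GLS = {
           if (length(r) != nrow(em$cov)) stop("covariance dimension mismatch")
           sum(decorrelate(r, em)^2)
         })
}

# whiten a residual vector: L^-1 r for Sigma = L L^T (R = chol upper, L = t(R))
decorrelate <- function(r, em) {
  backsolve(em$chol, r, transpose = TRUE)
}

# ---------------------------------------------------------------------------
# model specification and parameterization

#' Specify a correlation model to fit
#'
#' Names the diffusion kind (`iso1`/`aniso1`/`iso2`/`aniso2`), whether
#' triplet kinetics are included, how the axial coefficient is treated for
#' anisotropic kinds (`free`: DCz independent; `uniaxial`: DCz = DCy;
#' `quasi2d`: DCz = 0), and whether the PSF scale factor is fitted.
#' Two-component kinds are parameterized as `(DC1, dDC = DC2 - DC1 > 0)`
#' so that the identifiability constraint DC1 < DC2 holds by construction
#' (no label switching).
#'
#' @param kind diffusion kind.
#' @param triplet include the triplet factor (adds TSA, tauT).
#' @param axial axial-coefficient convention for anisotropic kinds.
#' @param fit_scale fit the PSF scale factor (Gaussian PSF only).
#' @param offset include an additive constant nuisance term.  Finite
#'   images bias the mean-subtracted spatial ACF by a small constant
#'   (roughly the correlation area over the image area times the
#'   amplitude); at production image sizes this is negligible, but for
#'   small scans the offset absorbs it.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("iso1", "aniso1", "iso2", "aniso2"),
                       triplet = FALSE,
                       axial = c("free", "uniaxial", "quasi2d"),
                       fit_scale = FALSE, offset = FALSE) {
  structure(list(kind = match.arg(kind), triplet = triplet,
                 axial = match.arg(axial), fit_scale = fit_scale,
                 offset = offset),
            class = "model_spec")
}

#' Default prior bounds
#'
#' Finite box priors applied to all fitted parameters in both frameworks:
#' diffusion coefficients 0-5000 um^2/s, concentration 0-1000 nM, triplet
#' amplitude 0-1, triplet relaxation time 0.01-1e4 us, PSF scale 0-2.
#'
#' @param ... named overrides, each `c(lower, upper)`; the names `DC` and
#'   `dDC` apply to every diffusion-coefficient-like parameter.
#' @return Named list of `c(lower, upper)` bounds.
#' @export
prior_spec <- function(...) {
  out <- list(DC = c(0, 5000), dDC = c(0, 5000), f = c(0, 1),
              C = c(0, 1000), TSA = c(0, 1), tauT = c(1e-8, 1e-2),
              scale = c(0, 2), offset = c(-1, 1))
  over <- list(...)
  for (nm in names(over)) {
    b <- over[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop("bounds must be finite c(lower, upper) with lower < upper")
    out[[nm]] <- b
  }
  out
}

# parameter table for a model spec: name, lower, upper; n_cond > 1 gives
# each condition its own baseline offset (finite-image bias and occupancy
# noise are per-stack quantities)
param_table <- function(spec, priors = prior_spec(), n_cond = 1L) {
  dc_names <- switch(spec$axial,
                     free = c("DCx", "DCy", "DCz"),
                     uniaxial = c("DCx", "DCy"),
                     quasi2d = c("DCx", "DCy"))
  nm <- switch(spec$kind,
               iso1 = "DC",
               aniso1 = dc_names,
               iso2 = c("DC1", "dDC"),
               aniso2 = c(paste0("DC1", substring(dc_names, 3)),
                          paste0("dDC", substring(dc_names, 3))))
  if (spec$kind %in% c("iso2", "aniso2")) nm <- c(nm, "f")
  nm <- c(nm, "C")
  if (spec$triplet) nm <- c(nm, "TSA", "tauT")
  if (spec$fit_scale) nm <- c(nm, "scale")
  if (isTRUE(spec$offset))
    nm <- c(nm, if (n_cond > 1) paste0("offset", seq_len(n_cond)) else "offset")
  look <- function(p) {
    if (!is.null(priors[[p]])) return(priors[[p]])
    if (grepl("^DC", p)) return(priors$DC)
    if (grepl("^dDC", p)) return(priors$dDC)
    if (grepl("^offset", p)) return(priors$offset)
    stop("no prior bound for parameter ", p)
  }
  b <- t(vapply(nm, look, numeric(2)))
  tibble::tibble(name = nm, lower = b[, 1], upper = b[, 2])
}

# expand named axial parameters to a length-3 dc vector
axial_expand <- function(v, axial) {
  switch(axial,
         free = v,
         uniaxial = c(v[1], v[2], v[2]),
         quasi2d = c(v[1], v[2], 0))
}

theta_to_params <- function(spec, theta) {
  g <- function(n) unname(theta[n])
  tsa <- if (spec$triplet) g("TSA") else 0
  tau_t <- if (spec$triplet) g("tauT") else NULL
  switch(spec$kind,
    iso1 = diffusion_params("iso1", dc = g("DC"), c_nM = g("C"),
                            tsa = tsa, tau_t = tau_t),
    aniso1 = {
      v <- switch(spec$axial,
                  free = c(g("DCx"), g("DCy"), g("DCz")),
                  c(g("DCx"), g("DCy")))
      diffusion_params("aniso1", dc = axial_expand(v, spec$axial),
                       c_nM = g("C"), tsa = tsa, tau_t = tau_t)
    },
    iso2 = diffusion_params("iso2", dc = g("DC1"),
                            dc2 = g("DC1") + g("dDC"), f = g("f"),
                            c_nM = g("C"), tsa = tsa, tau_t = tau_t),
    aniso2 = {
      v1 <- switch(spec$axial,
                   free = c(g("DC1x"), g("DC1y"), g("DC1z")),
                   c(g("DC1x"), g("DC1y")))
      dv <- switch(spec$axial,
                   free = c(g("dDCx"), g("dDCy"), g("dDCz")),
                   c(g("dDCx"), g("dDCy")))
      d1 <- axial_expand(v1, spec$axial)
      diffusion_params("aniso2", dc = d1,
                       dc2 = d1 + axial_expand(dv, spec$axial), f = g("f"),
                       c_nM = g("C"), tsa = tsa, tau_t = tau_t)
    })
}

# ---------------------------------------------------------------------------
# fit points: flatten curves/images (or lists of them) into (tau, delta, g)

build_fit_points <- function(data) {
  one <- function(d, cond) {
    if (inherits(d, "acf_curve")) {
      tibble::tibble(condition = cond, tau = d$lag, dx = 0, dy = 0, dz = 0,
                     g = d$g,
                     sigma = if ("sigma" %in% names(d)) d$sigma else NA_real_,
                     is_2d = FALSE)
    } else if (inherits(d, "acf_image")) {
      grid <- tidyr::expand_grid(psi = d$psi, xi = d$xi)
      dd <- rotate_displacement(grid$xi, grid$psi, 0, d$geometry)
      tibble::tibble(condition = cond,
                     tau = lag_time(grid$xi, grid$psi, d$geometry),
                     dx = dd[, 1], dy = dd[, 2], dz = dd[, 3],
                     g = as.vector(t(d$g)),
                     sigma = if (!is.null(d$sigma)) as.vector(t(d$sigma))
                             else NA_real_,
                     is_2d = TRUE)
    } else stop("data must be acf_curve or acf_image objects")
  }
  if (inherits(data, c("acf_curve", "acf_image"))) data <- list(data)
  dplyr::bind_rows(purrr::imap(data, function(d, i) one(d, i)))
}

model_values <- function(spec, theta, points, psf) {
  # keep boundary values (C = 0, TSA = 1, tauT = 0, scale = 0) out of the
  # singular set so bound-constrained optimizers can touch the bounds
  eps <- 1e-12
  if ("C" %in% names(theta)) theta["C"] <- max(theta["C"], eps)
  if ("TSA" %in% names(theta)) theta["TSA"] <- min(theta["TSA"], 1 - 1e-9)
  if ("tauT" %in% names(theta)) theta["tauT"] <- max(theta["tauT"], eps)
  if ("scale" %in% names(theta)) theta["scale"] <- max(theta["scale"], 1e-3)
  if (spec$fit_scale) {
    if (!inherits(psf, "gaussian_psf"))
      stop("fit_scale requires a Gaussian PSF")
    psf$scale <- unname(theta["scale"])
  }
  params <- theta_to_params(spec, theta)
  delta <- cbind(points$dx, points$dy, points$dz)
  g <- if (inherits(psf, "gaussian_psf")) {
    g_gaussian(delta, points$tau, params, psf)
  } else {
    suppressWarnings(g_measured(delta, points$tau, params, psf))
  }
  if (isTRUE(spec$offset)) {
    g <- g + if ("offset" %in% names(theta)) unname(theta["offset"])
             else unname(theta[paste0("offset", points$condition)])
  }
  g
}

# deterministic moment-based start appended to the grid of box starts:
# concentration from the short-lag amplitude, diffusion coefficient from
# the half-decay lag of the curve (all clamped into the prior box)
moment_start <- function(pt, points, psf) {
  st <- pt$lower + (pt$upper - pt$lower) / 2
  names(st) <- pt$name
  o <- order(points$tau)
  g <- points$g[o]; tau <- points$tau[o]
  g0 <- max(g[1], 1e-12)
  ve <- if (inherits(psf, "gaussian_psf")) v_eff(psf) else v_eff(psf)
  c_est <- 1 / (g0 * ve * .NM_TO_UM3)
  w2 <- if (inherits(psf, "gaussian_psf")) (psf$scale * psf$w_x)^2 else {
    # effective lateral width from the grid voxel extent
    (dim(psf$values)[1] * psf$voxel[1] / 5)^2
  }
  ih <- which(g <= g0 / 2)
  dc_est <- if (length(ih)) w2 / (4 * max(tau[ih[1]], 1e-9)) else st[1]
  clamp <- function(v, i) min(max(v, pt$lower[i] + 1e-3 * (pt$upper[i] -
    pt$lower[i])), pt$upper[i] - 1e-3 * (pt$upper[i] - pt$lower[i]))
  for (i in seq_len(nrow(pt))) {
    nm <- pt$name[i]
    if (grepl("^DC", nm)) st[i] <- clamp(dc_est, i)
    if (nm == "C") st[i] <- clamp(c_est, i)
    if (nm == "dDC") st[i] <- clamp(dc_est, i)
    if (nm == "TSA") st[i] <- clamp(0.1, i)
    if (nm == "tauT") st[i] <- clamp(1e-5, i)
    if (nm == "f") st[i] <- 0.5
    if (nm == "scale") st[i] <- 1
    if (grepl("^offset", nm)) st[i] <- 0
  }
  unname(st)
}

resolve_wls_sigma <- function(em, points) {
  s <- em$sigma %||% points$sigma
  if (is.null(s) || any(!is.finite(s)))
    stop("WLS requires per-point sigma (from the error model or the data)")
  if (any(s <= 0)) stop("WLS sigma must be > 0")
  s
}

check_gls_applicable <- function(em, points) {
  if (em$mode == "GLS" && any(points$is_2d))
    stop(paste("GLS fitting is not supported for RICS 2D correlation data:",
               "estimating a stable lag covariance would require thousands of",
               "independent frames per condition. Use OLS or WLS."))
  if (em$mode == "GLS" && nrow(points) != nrow(em$cov))
    stop("covariance dimension does not match the number of fit points")
}

# ---------------------------------------------------------------------------
# nonlinear least squares

#' Fit a correlation model by nonlinear least squares
#'
#' Bound-constrained Levenberg-Marquardt minimization of the chi-squared
#' objective under the chosen error model, from a deterministic multi-start
#' (prior-box centre plus a +/- quarter-box offset per parameter, 2p+1
#' starts; the best chi-squared wins).  For lists of curves/images the
#' diffusion, concentration and triplet parameters are shared across
#' conditions (joint fit); geometry enters through each condition's lag
#' mapping.
#'
#' @param data an [acf_curve()], [acf_image()], or list thereof.
#' @param spec a [model_spec()].
#' @param psf a [gaussian_psf()] or [psf_grid()].
#' @param em an error model ([em_ols()], [em_wls()], [em_gls()]).
#' @param priors bounds from [prior_spec()].
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return An object of class `ccs_fit` with elements `theta_hat`,
#'   `stderr`, `ssr`, `chi2`, `chi2_red`, `n`, `p`, `residuals` (raw and,
#'   per error model, standardized/decorrelated), `fitted`, `points`,
#'   `converged`, `active_bounds`.
#' @export
fit_nls <- function(data, spec, psf, em = em_ols(), priors = prior_spec(),
                    maxiter = 200) {
  points <- build_fit_points(data)
  pt <- param_table(spec, priors, n_cond = max(points$condition))
  n <- nrow(points); p <- nrow(pt)
  if (n <= p) stop("need more data points than parameters")
  check_gls_applicable(em, points)
  sig <- if (em$mode == "WLS") resolve_wls_sigma(em, points)
  if (em$mode == "WLS") em$sigma <- sig
  wres <- switch(em$mode,
                 OLS = function(r) r,
                 WLS = function(r) r / sig,
                 GLS = function(r) decorrelate(r, em))
  resid_fn <- function(th) {
    names(th) <- pt$name
    wres(points$g - model_values(spec, th, points, psf))
  }

  range <- pt$upper - pt$lower
  center <- pt$lower + range / 2
  starts <- list(center)
  for (i in seq_len(p)) {
    for (s in c(-1, 1)) {
      st <- center
      st[i] <- center[i] + s * range[i] / 4
      starts[[length(starts) + 1]] <- st
    }
  }
  starts[[length(starts) + 1]] <- moment_start(pt, points, psf)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = pt$lower,
                         upper = pt$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("optimization failed from every start")
  converged <- best$info %in% 1:4
  if (!converged)
    warning("NLS did not report convergence: ", best$message)

  theta <- setNames(best$par, pt$name)
  f <- model_values(spec, theta, points, psf)
  r <- points$g - f
  chi2 <- chi_squared(points$g, f, em)
  ssr <- sum(r^2)
  chi2_red <- chi2 / (n - p)
  # covariance of estimates from the weighted Jacobian; OLS rescales by
  # the post-hoc error variance sigma^2 = SSR / (n - p)
  scale2 <- if (em$mode == "OLS") ssr / (n - p) else 1
  cov_theta <- tryCatch(solve(best$hessian) * scale2, error = function(e)
    matrix(NA_real_, p, p))
  stderr <- setNames(sqrt(pmax(diag(cov_theta), 0)), pt$name)
  active <- pt$name[(theta - pt$lower < 1e-8 * range) |
                      (pt$upper - theta < 1e-8 * range)]
  res <- list(raw = r)
  if (em$mode == "WLS") res$standardized <- r / sig
  if (em$mode == "GLS") res$decorrelated <- decorrelate(r, em)

  structure(list(theta_hat = theta, stderr = stderr, ssr = ssr,
                 chi2 = chi2, chi2_red = chi2_red, n = n, p = p,
                 sigma2_hat = if (em$mode == "OLS") scale2 else NULL,
                 residuals = res, fitted = f, points = points,
                 spec = spec, psf = psf, em_mode = em$mode,
                 converged = converged, active_bounds = active),
            class = "ccs_fit")
}

#' @export
print.ccs_fit <- function(x, ...) {
  cat(sprintf("<ccs_fit> %s%s, %s errors: chi2 = %.4g, chi2_red = %.4g (n = %d, p = %d)\n",
              x$spec$kind, if (x$spec$triplet) "+triplet" else "",
              x$em_mode, x$chi2, x$chi2_red, x$n, x$p))
  est <- sprintf("  %s = %.4g +/- %.3g", names(x$theta_hat), x$theta_hat,
                 x$stderr)
  cat(est, sep = "\n")
  if (length(x$active_bounds))
    cat("  active bounds:", paste(x$active_bounds, collapse = ", "), "\n")
  invisible(x)
}

#' Goodness of fit
#'
#' Reports the sum of squared raw residuals, the chi-squared statistic
#' under the fit's error model, and the reduced chi-squared
#' `chi2 / (n - p)`.  For posterior results the metrics are computed at
#' the median posterior parameters.
#'
#' @param fit a `ccs_fit` or `ccs_posterior`.
#' @return A list with `ssr`, `chi2`, `chi2_red`.
#' @export
goodness_of_fit <- function(fit) UseMethod("goodness_of_fit")

#' @export
goodness_of_fit.ccs_fit <- function(fit) {
  if (fit$n <= fit$p) stop("n must exceed p")
  list(ssr = fit$ssr, chi2 = fit$chi2, chi2_red = fit$chi2_red)
}

#' F-test for nested diffusion models
#'
#' Tests whether the chi-squared reduction achieved by a more complex
#' nested model is statistically significant:
#' `F = [(chi2_s - chi2_c) / (p_c - p_s)] / [chi2_c / (n - p_c)]`,
#' with the p-value from the F distribution with `(p_c - p_s, n - p_c)`
#' degrees of freedom.  Both fits must use the same data and error model.
#'
#' @param simple,complex `ccs_fit` objects, `simple` nested in `complex`.
#' @return A list with `F`, `p_value`, and the degrees of freedom.
#' @export
f_test_nested <- function(simple, complex) {
  if (simple$n != complex$n) stop("fits use different data")
  if (simple$em_mode != complex$em_mode) stop("fits use different error models")
  if (complex$p <= simple$p) stop("complex model must have more parameters")
  if (complex$chi2 > simple$chi2 + 1e-12)
    stop("complex fit worse than simple fit: optimizer failure")
  d1 <- complex$p - simple$p
  d2 <- complex$n - complex$p
  Fs <- ((simple$chi2 - complex$chi2) / d1) / (complex$chi2 / d2)
  list(F = Fs, p_value = pf(Fs, d1, d2, lower.tail = FALSE),
       df1 = d1, df2 = d2)
}
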