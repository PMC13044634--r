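# broom-style accessors for fitted objects

#' Tidy a nonlinear least-squares correlation fit
#'
#' @param x a `ccs_fit`.
#' @param ... unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.ccs_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta_hat),
                 estimate = unname(x$theta_hat),
                 std.error = unname(x$stderr))
}

#' @rdname tidy.ccs_fit
#' @export
glance.ccs_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n, p = x$p, ssr = x$ssr, chi2 = x$chi2,
                 chi2_red = x$chi2_red, em_mode = x$em_mode,
                 converged = x$converged)
}

#' Tidy a Bayesian posterior result
#'
#' @param x a `ccs_posterior`.
#' @param ... unused.
#' @return A tibble with one row per parameter: posterior mean, sd,
#'   median, and the 68.3% / 95.5% quantile ranges.
#' @export
tidy.ccs_posterior <- function(x, ...) {
  dplyr::rename(x$summary, term = "name")
}

#' @rdname tidy.ccs_posterior
#' @export
glance.ccs_posterior <- function(x, ...) {
  tibble::tibble(nobs = x$n, p = x$p, log_z = x$log_z,
                 log_z_err = x$log_z_err, chi2 = x$gof$chi2,
                 chi2_red = x$gof$chi2_red, em_mode = x$em_mode,
                 n_call = x$n_call)
}
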