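# ggplot2 figure builders.  Every plot is regenerated deterministically
# from stored artifacts; nothing depends on in-memory state beyond the
# objects passed in.

#' Plot a photon trace as a binned count rate
#'
#' @param trace a [photon_trace()].
#' @param bin display bin width, s.
#' @param window optional `c(t0, t1)` analysis window drawn as dashed
#'   lines.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, bin = 0.01, window = NULL) {
  k <- max(1L, round(bin / trace$bin_dt))
  n <- length(trace$counts) %/% k
  rate <- colSums(matrix(trace$counts[seq_len(n * k)], k, n)) / (k * trace$bin_dt)
  df <- tibble::tibble(t = (seq_len(n) - 0.5) * k * trace$bin_dt,
                       rate = rate / 1000)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$rate)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "rate (kcounts/s)") +
    ggplot2::theme_minimal()
  if (!is.null(window))
    p <- p + ggplot2::geom_vline(xintercept = window, linetype = "dashed",
                                 colour = "red")
  p
}

#' Plot an autocorrelation curve
#'
#' @param object an [acf_curve()].
#' @param log_x logarithmic lag axis.
#' @param fit optional `ccs_fit` or `ccs_posterior` whose (median) model
#'   curve is overlaid.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.acf_curve <- function(object, log_x = TRUE, fit = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$lag, .data$g)) +
    ggplot2::geom_point(size = 0.8, colour = "steelblue") +
    ggplot2::labs(x = "lag time (s)", y = "G") +
    ggplot2::theme_minimal()
  if ("sigma" %in% names(df))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$g - .data$sigma,
                   ymax = .data$g + .data$sigma),
      linewidth = 0.3, colour = "steelblue")
  if (!is.null(fit)) {
    fd <- if (inherits(fit, "ccs_posterior")) {
      tibble::tibble(lag = fit$points$tau, f = fit$fitted_median)
    } else {
      tibble::tibble(lag = fit$points$tau, f = fit$fitted)
    }
    p <- p + ggplot2::geom_line(data = fd,
                                ggplot2::aes(.data$lag, .data$f),
                                colour = "black")
  }
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a 2D spatial ACF as a heat map
#'
#' @param object an [acf_image()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.acf_image <- function(object, ...) {
  df <- tidyr::expand_grid(psi = object$psi, xi = object$xi)
  df$g <- as.vector(t(object$g))
  ggplot2::ggplot(df, ggplot2::aes(.data$xi, .data$psi, fill = .data$g)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(xi ~ "(pixels)"),
                  y = expression(psi ~ "(lines)"), fill = "G") +
    ggplot2::theme_minimal()
}

#' Plot fit residuals
#'
#' For Bayesian posteriors the median residual is drawn with shaded 68.3%
#' and 95.5% quantile-range bands; an NLS fit may be overlaid as a dashed
#' line.  Residuals are shown in the transform matching the error model
#' (raw, standardized, or decorrelated).
#'
#' @param fit a `ccs_posterior` or `ccs_fit`.
#' @param nls_overlay optional `ccs_fit` drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_residuals <- function(fit, nls_overlay = NULL) {
  if (inherits(fit, "ccs_posterior")) {
    pr <- fit$predictive
    df <- tibble::tibble(
      tau = pr$tau,
      med = pr$g - pr$f_median,
      lo68 = pr$g - pr$f_hi68, hi68 = pr$g - pr$f_lo68,
      lo95 = pr$g - pr$f_hi95, hi95 = pr$g - pr$f_lo95)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$tau, .data$med)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                           fill = "grey80") +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo68, ymax = .data$hi68),
                           fill = "grey55") +
      ggplot2::geom_line(colour = "black")
  } else {
    res <- fit$residuals$decorrelated %||% fit$residuals$standardized %||%
      fit$residuals$raw
    df <- tibble::tibble(tau = fit$points$tau, med = res)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$tau, .data$med)) +
      ggplot2::geom_line(colour = "black")
  }
  if (!is.null(nls_overlay)) {
    res <- nls_overlay$residuals$decorrelated %||%
      nls_overlay$residuals$standardized %||% nls_overlay$residuals$raw
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(tau = nls_overlay$points$tau, med = res),
      colour = "red", linetype = "dashed")
  }
  p + ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag time (s)", y = "residual") +
    ggplot2::theme_minimal()
}

#' Overlay posterior densities of one parameter across fits
#'
#' Reproduces the usual error-model comparison figure: kernel densities of
#' a parameter's posterior draws for several fits, medians as dashed
#' lines.
#'
#' @param posteriors named list of `ccs_posterior` objects.
#' @param param parameter name (default `"DC"`).
#' @return A ggplot object.
#' @export
plot_posterior <- function(posteriors, param = "DC") {
  df <- purrr::imap_dfr(posteriors, function(p, nm)
    tibble::tibble(method = nm, value = p$samples[, param]))
  med <- dplyr::summarise(dplyr::group_by(df, .data$method),
                          m = median(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$value, colour = .data$method,
                                   fill = .data$method)) +
    ggplot2::geom_density(alpha = 0.2) +
    ggplot2::geom_vline(data = med,
                        ggplot2::aes(xintercept = .data$m,
                                     colour = .data$method),
                        linetype = "dashed") +
    ggplot2::labs(x = param, y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Heat map of a lag covariance matrix
#'
#' @param em a GLS `error_model` (or a covariance matrix).
#' @return A ggplot object.
#' @export
plot_covariance <- function(em) {
  S <- if (inherits(em, "error_model")) em$cov else em
  df <- tidyr::expand_grid(i = seq_len(nrow(S)), j = seq_len(ncol(S)))
  df$value <- as.vector(S)
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "lag index", y = "lag index", fill = expression(Sigma)) +
    ggplot2::theme_minimal()
}

#' Plot a spatial parameter map
#'
#' @param object a `param_map` from [map_parameters()].
#' @param ... unused.
#' @return A ggplot object (row 1 at the top of the image; axes in um).
#' @export
autoplot.param_map <- function(object, ...) {
  df <- tidyr::expand_grid(y = object$centers_y, x = object$centers_x)
  df$value <- as.vector(t(object$grid))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey50") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  fill = sprintf("%s (%s)", object$param, object$units)) +
    ggplot2::theme_minimal()
}

#' Plot diffusion estimates against scan angle
#'
#' @param summary result of [angular_summary()].
#' @return A ggplot object.
#' @export
plot_angular <- function(summary) {
  df <- summary$table
  if (is.null(df)) stop("angular summary has no per-angle table")
  ggplot2::ggplot(df, ggplot2::aes(.data$angle, .data$estimate,
                                   colour = .data$name)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$sd,
                                        ymax = .data$estimate + .data$sd),
                           width = 3) +
    ggplot2::labs(x = "scan angle (deg)", y = "DC (um^2/s)") +
    ggplot2::theme_minimal()
}
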