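#' Spatial parameter maps from sector-wise RICS fits
#'
#' Splits a RICS stack into sectors, computes the spatial ACF of each
#' sector region (self-, larger-area-, or pair-correlation), crops it to
#' the fitting quadrant, fits the chosen model per sector, and assembles
#' one spatial map per fitted parameter.  Sectors whose fit fails are
#' masked with the failure reason; maps never interpolate over failures.
#'
#' @param stack an [image_stack()].
#' @param grid a [sector_grid()].
#' @param spec a [model_spec()].
#' @param psf PSF for the fits.
#' @param em error model; OLS (the default, matching typical map use) or
#'   WLS when at least two frames supply per-point SEMs.
#' @param priors bounds from [prior_spec()].
#' @param drop_first,n_lines,points_per_line ACF cropping controls per
#'   sector (see [crop_and_downsample()]).
#' @param params parameters to map (default DC-like and C).
#' @return A list with `maps` (named list of `param_map` objects),
#'   `table` (tibble of per-sector results), and `masked_fraction`.
#' @export
map_parameters <- function(stack, grid, spec, psf, em = em_ols(),
                           priors = prior_spec(), drop_first = 1,
                           n_lines = 3, points_per_line = 100,
                           params = NULL) {
  if (!em$mode %in% c("OLS", "WLS"))
    stop("per-sector mapping supports OLS or WLS error models")
  g <- stack$geometry
  sectors <- split_sectors(c(g$n_rows, g$n_cols), grid,
                           c(g$s_xi, g$s_psi))
  fit_one <- function(region, reference) {
    acf2 <- acf_rics(stack, region = region, reference = reference)
    acf2 <- crop_and_downsample(acf2, drop_first = drop_first,
                                n_lines = n_lines,
                                points_per_line = points_per_line)
    fit_nls(acf2, spec, psf, em, priors = priors)
  }
  fits <- purrr::map2(sectors$region, sectors$reference, function(r, ref)
    tryCatch(fit_one(r, ref), error = function(e) e))
  failed <- purrr::map_lgl(fits, inherits, "error")
  if (all(failed))
    stop("all sectors failed: ", conditionMessage(fits[[1]]))

  pnames <- params %||% {
    nm <- names(fits[[which(!failed)[1]]]$theta_hat)
    nm[grepl("^DC", nm) | nm == "C"]
  }
  tab <- sectors
  tab$failed <- failed
  tab$reason <- ifelse(failed, purrr::map_chr(fits, function(f)
    if (inherits(f, "error")) conditionMessage(f) else NA_character_),
    NA_character_)
  for (pn in pnames)
    tab[[pn]] <- purrr::map_dbl(fits, function(f)
      if (inherits(f, "error")) NA_real_ else unname(f$theta_hat[pn]))

  maps <- lapply(pnames, function(pn) {
    m <- matrix(tab[[pn]], grid$n_y, grid$n_x, byrow = TRUE)
    structure(list(
      grid = m,
      centers_x = sort(unique(tab$center_col)) * g$s_xi,
      centers_y = sort(unique(tab$center_row)) * g$s_psi,
      mask = matrix(failed, grid$n_y, grid$n_x, byrow = TRUE),
      units = if (grepl("^DC", pn)) "um^2/s" else if (pn == "C") "nM" else "",
      param = pn), class = "param_map")
  })
  names(maps) <- pnames
  list(maps = maps, table = tab, fits = fits,
       masked_fraction = mean(failed))
}

#' @export
print.param_map <- function(x, ...) {
  cat(sprintf("<param_map> %s [%s], %d x %d sectors (%d masked)\n",
              x$param, x$units, nrow(x$grid), ncol(x$grid), sum(x$mask)))
  invisible(x)
}

#' Angular dependence of fitted diffusion coefficients
#'
#' Summarizes fits of RICS data recorded at multiple scan angles.  For
#' per-angle fits it tabulates the diffusion estimates against angle; for
#' joint anisotropic fits it reports DCx and DCy with uncertainties and
#' flags anisotropy when |DCx - DCy| exceeds twice the combined
#' uncertainty.
#'
#' @param fits named list of `ccs_fit` or `ccs_posterior` objects; names
#'   (or the `angle` argument) give the scan angle of each condition.  A
#'   single joint anisotropic fit may be passed directly.
#' @param angles optional numeric angles overriding the names.
#' @return A list with `table` (per-angle tibble), `joint` (DCx/DCy
#'   summary when available), and `anisotropic` (logical flag).
#' @export
angular_summary <- function(fits, angles = NULL) {
  est_of <- function(f) {
    if (inherits(f, "ccs_fit"))
      tibble::tibble(name = names(f$theta_hat),
                     estimate = unname(f$theta_hat),
                     sd = unname(f$stderr))
    else if (inherits(f, "ccs_posterior"))
      tibble::tibble(name = f$summary$name, estimate = f$summary$mean,
                     sd = f$summary$sd)
    else stop("fits must be ccs_fit or ccs_posterior objects")
  }
  joint_flag <- function(e) {
    if (!all(c("DCx", "DCy") %in% e$name)) return(NULL)
    dx <- e[e$name == "DCx", ]; dy <- e[e$name == "DCy", ]
    comb <- sqrt(dx$sd^2 + dy$sd^2)
    list(DCx = dx$estimate, DCx_sd = dx$sd, DCy = dy$estimate,
         DCy_sd = dy$sd,
         anisotropic = is.finite(comb) &&
           abs(dx$estimate - dy$estimate) > 2 * comb)
  }
  if (inherits(fits, c("ccs_fit", "ccs_posterior"))) {
    j <- joint_flag(est_of(fits))
    if (is.null(j)) stop("joint fit does not expose DCx/DCy")
    return(list(table = NULL, joint = j, anisotropic = j$anisotropic))
  }
  if (length(fits) < 2) stop("at least two angles required")
  if (is.null(angles)) angles <- as.numeric(names(fits))
  if (any(is.na(angles))) stop("angles must be supplied or encoded in names")
  tab <- purrr::map2_dfr(fits, angles, function(f, a) {
    e <- est_of(f)
    e <- e[grepl("^DC", e$name), ]
    dplyr::mutate(e, angle = a, .before = 1)
  })
  joints <- purrr::compact(purrr::map(fits, function(f) joint_flag(est_of(f))))
  j <- if (length(joints)) joints[[1]] else NULL
  list(table = tab, joint = j,
       anisotropic = isTRUE(j$anisotropic))
}
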