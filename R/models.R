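#' Diffusion model parameters
#'
#' Parameter container for the forward correlation models: single- or
#' two-component, isotropic or anisotropic diffusion, optional triplet
#' kinetics.  Concentrations are supplied in nM and converted internally
#' to molecules/um^3 (1 nM = 0.6022 molecules/um^3).
#'
#' Two-component kinds require `dc2 > dc` componentwise on every fitted
#' axis (identifiability: component 1 is the slower one).
#'
#' @param kind one of `"iso1"`, `"aniso1"`, `"iso2"`, `"aniso2"`.
#' @param dc diffusion coefficient(s) of component 1, um^2/s.  A scalar for
#'   isotropic kinds, `c(DCx, DCy, DCz)` for anisotropic kinds.
#' @param dc2 component-2 diffusion coefficient(s) (two-component kinds).
#' @param f fraction of component 1 in \[0, 1\].
#' @param c_nM mean concentration, nM (> 0).
#' @param tsa triplet-state amplitude in \[0, 1).
#' @param tau_t triplet relaxation time, s (required when `tsa > 0`).
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(kind = c("iso1", "aniso1", "iso2", "aniso2"),
                             dc, dc2 = NULL, f = 1, c_nM,
                             tsa = 0, tau_t = NULL) {
  kind <- match.arg(kind)
  expand <- function(d) if (length(d) == 1) rep(d, 3) else as.numeric(d)
  two <- kind %in% c("iso2", "aniso2")
  iso <- kind %in% c("iso1", "iso2")
  if (iso && length(dc) != 1 && length(unique(dc)) != 1)
    stop("isotropic kinds take a single diffusion coefficient")
  dc <- expand(dc)
  if (any(!is.finite(dc)) || any(dc < 0)) stop("dc must be finite and >= 0")
  if (two) {
    if (is.null(dc2)) stop("two-component kinds require dc2")
    dc2 <- expand(dc2)
    if (any(dc2 < dc)) stop("identifiability requires DC1 < DC2 componentwise")
    if (f < 0 || f > 1) stop("f must be in [0, 1]")
  } else {
    dc2 <- NULL
    f <- 1
  }
  if (!is.finite(c_nM) || c_nM <= 0) stop("c_nM must be > 0")
  if (tsa < 0 || tsa >= 1) stop("tsa must be in [0, 1)")
  if (tsa > 0 && (is.null(tau_t) || tau_t <= 0))
    stop("tau_t must be > 0 when tsa > 0")
  structure(list(kind = kind, dc = dc, dc2 = dc2, f = f, c_nM = c_nM,
                 c_mean = c_nM * .NM_TO_UM3, tsa = tsa, tau_t = tau_t),
            class = "diffusion_params")
}

#' Map pixel displacements to sample-frame displacements
#'
#' Scales pixel lags by the pixel sizes and rotates the resulting
#' scan-frame displacement about the optical axis by the scan angle alpha,
#' yielding physical displacements in the sample frame.
#'
#' @param xi,psi,zeta pixel/line/plane lags (vectors recycle).
#' @param geom a [scan_geometry()].
#' @return A matrix with columns `dx`, `dy`, `dz` in um.
#' @export
rotate_displacement <- function(xi, psi, zeta = 0, geom) {
  n <- max(length(xi), length(psi), length(zeta))
  xs <- rep_len(xi, n) * geom$s_xi
  ys <- rep_len(psi, n) * geom$s_psi
  zs <- rep_len(zeta, n) * geom$s_zeta
  a <- geom$alpha * pi / 180
  cbind(dx = cos(a) * xs - sin(a) * ys,
        dy = sin(a) * xs + cos(a) * ys,
        dz = zs)
}

#' Lag time of a RICS pixel displacement
#'
#' The raster scan encodes time in space: a displacement of `xi` pixels
#' along the fast axis corresponds to `xi * t_pix`, and `psi` lines along
#' the slow axis to `psi * t_line`.
#'
#' @param xi,psi pixel and line lags.
#' @param geom a [scan_geometry()].
#' @return Lag time(s) in seconds.
#' @export
lag_time <- function(xi, psi, geom) {
  xi * geom$t_pix + psi * geom$t_line
}

#' Triplet-state correlation factor
#'
#' Multiplicative contribution of reversible dark-state (triplet) kinetics,
#' `1 + TSA/(1 - TSA) exp(-tau/tau_T)`.
#'
#' @param tau lag times, s.
#' @param tsa triplet-state amplitude in \[0, 1).
#' @param tau_t triplet relaxation time, s.
#' @return Dimensionless factor(s) >= 1.
#' @export
triplet_factor <- function(tau, tsa, tau_t) {
  if (tsa == 0) return(rep(1, length(tau)))
  if (tsa >= 1) stop("tsa must be < 1")
  if (tau_t <= 0) stop("tau_t must be > 0")
  1 + tsa / (1 - tsa) * exp(-tau / tau_t)
}

# one diffusion component: prod_i  w_i/sqrt(4 D_i tau + w_i^2) *
#                                  exp(-Delta_i^2 / (4 D_i tau + w_i^2))
# normalized so the component equals 1 at tau = 0, Delta = 0
g_component <- function(delta, tau, dc, w) {
  out <- rep(1, length(tau))
  for (i in 1:3) {
    s2 <- 4 * dc[i] * tau + w[i]^2
    out <- out * w[i] / sqrt(s2) * exp(-delta[, i]^2 / s2)
  }
  out
}

#' Spatiotemporal correlation model, Gaussian PSF
#'
#' Closed-form correlation amplitude for anisotropic free diffusion through
#' a 3D Gaussian focal volume, for a sample-frame displacement `delta` and
#' lag time `tau`.  The amplitude convention is the standard fluctuation
#' result: `G(0, 0) = 1 / (V_eff <C>)`, with two-component kinds mixed
#' linearly by the fraction `f` and triplet kinetics applied as a
#' multiplicative factor.  PSF waists are pre-scaled by the PSF scale
#' factor.
#'
#' @param delta displacement(s): a length-3 vector or an `n x 3` matrix of
#'   `(dx, dy, dz)` in um.
#' @param tau lag time(s), s (recycled against rows of `delta`).
#' @param params a [diffusion_params()].
#' @param psf a [gaussian_psf()].
#' @return Correlation value(s), dimensionless.
#' @export
g_gaussian <- function(delta, tau, params, psf) {
  if (is.null(dim(delta))) delta <- matrix(delta, ncol = 3, byrow = FALSE)
  if (nrow(delta) == 1 && length(tau) > 1)
    delta <- delta[rep(1, length(tau)), , drop = FALSE]
  tau <- rep_len(tau, nrow(delta))
  if (any(tau < 0)) stop("tau must be >= 0")
  w <- psf$scale * c(psf$w_x, psf$w_y, psf$w_z)
  if (any(w <= 0)) stop("nonpositive waists")
  amp <- 1 / (v_eff(psf) * params$c_mean)
  g <- params$f * g_component(delta, tau, params$dc, w)
  if (!is.null(params$dc2))
    g <- g + (1 - params$f) * g_component(delta, tau, params$dc2, w)
  amp * g * triplet_factor(tau, params$tsa, params$tau_t %||% 1)
}

#' Temporal correlation model for point FCS
#'
#' The zero-spatial-lag special case of [g_gaussian()]: evaluating the
#' spatiotemporal model at `delta = 0` removes the spatial exponentials and
#' yields the purely temporal ACF used in point FCS.
#'
#' @param tau lag times, s.
#' @param params a [diffusion_params()].
#' @param psf a [gaussian_psf()].
#' @return Correlation values, dimensionless.
#' @export
g_fcs <- function(tau, params, psf) {
  g_gaussian(matrix(0, length(tau), 3), tau, params, psf)
}

#' Spatiotemporal correlation model, measured PSF
#'
#' Numerical evaluation of
#' `G(Delta, tau) = int int PSF(r) K(r' - r, tau) PSF(r' - Delta) dr dr' /
#'  (<C> [int PSF]^2)`
#' with `K` the free-diffusion Green's function (separable Gaussian with
#' per-axis variance `2 DC_i tau`).  Implemented as a per-axis Gaussian
#' blur of the PSF grid followed by the inner product with the PSF shifted
#' by `Delta` (trilinear interpolation for off-grid displacements).  Two
#' component kinds are mixed by `f`; triplet kinetics multiply the result.
#' When a requested blur sigma is below half a voxel (but nonzero) the
#' blur for that axis falls back to the unblurred grid with a warning.
#'
#' @param delta displacement(s): length-3 vector or `n x 3` matrix, um.
#' @param tau lag time(s), s.
#' @param params a [diffusion_params()].
#' @param psf a [psf_grid()].
#' @return Correlation value(s), dimensionless.
#' @export
g_measured <- function(delta, tau, params, psf) {
  if (is.null(dim(delta))) delta <- matrix(delta, ncol = 3, byrow = FALSE)
  if (nrow(delta) == 1 && length(tau) > 1)
    delta <- delta[rep(1, length(tau)), , drop = FALSE]
  tau <- rep_len(tau, nrow(delta))
  if (any(tau < 0)) stop("tau must be >= 0")
  v <- psf$values
  vox <- psf$voxel
  ext <- (dim(v) - 1) * vox
  if (any(abs(delta) > rep(ext, each = nrow(delta))))
    stop("displacement outside PSF grid support")
  denom_int <- (sum(v) * prod(vox))^2 * params$c_mean
  fellback <- FALSE

  # cache the shifted PSF per unique displacement (shared across
  # components and lag times)
  dkey <- paste(delta[, 1], delta[, 2], delta[, 3])
  shifted_cache <- lapply(
    setNames(which(!duplicated(dkey)), unique(dkey)),
    function(r) shift_grid(v, delta[r, ] / vox)
  )

  eval_comp <- function(dc) {
    out <- numeric(length(tau))
    for (ut in unique(tau)) {
      sig <- sqrt(2 * dc * ut)
      blurred <- v
      for (ax in 1:3) {
        if (sig[ax] <= 0) next
        if (sig[ax] < 0.5 * vox[ax]) { fellback <<- TRUE; next }
        blurred <- blur_axis(blurred, sig[ax], vox[ax], ax)
      }
      rows <- which(tau == ut)
      # the unit-sum blur kernel already carries one voxel-volume factor
      # of the double integral; the outer sum carries the other
      for (r in rows)
        out[r] <- sum(blurred * shifted_cache[[dkey[r]]]) * prod(vox)
    }
    out
  }

  g <- params$f * eval_comp(params$dc)
  if (!is.null(params$dc2)) g <- g + (1 - params$f) * eval_comp(params$dc2)
  if (fellback)
    warning("blur sigma below half a voxel for some lags; used unblurred PSF")
  g / denom_int * triplet_factor(tau, params$tsa, params$tau_t %||% 1)
}

# 1D Gaussian blur along one axis of a 3D array (zero-padded edges);
# kernel normalized to unit sum so the grid integral is conserved
blur_axis <- function(arr, sigma, dx, axis) {
  n <- dim(arr)[axis]
  hw <- min(n - 1, max(1L, ceiling(4 * sigma / dx)))
  off <- (-hw):hw
  k <- dnorm(off * dx, sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (j in seq_along(off)) {
    i <- seq_len(n)
    ii <- i + off[j]
    ok <- ii >= 1 & ii <= n
    K[cbind(i[ok], ii[ok])] <- K[cbind(i[ok], ii[ok])] + k[j]
  }
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  out <- K %*% m
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
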