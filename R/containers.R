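#' Photon count trace
#'
#' Container for a binned photon-count time trace, the raw input for point
#' FCS.  Counts are nonnegative integers per time bin of fixed width.
#'
#' @param counts integer vector of photon counts per bin (length >= 2).
#' @param bin_dt bin width in seconds (> 0).
#' @param t_start acquisition start time in seconds.
#' @param attrs named list of free-form metadata (e.g. angle, speed keys).
#' @return An object of class `photon_trace`.
#' @export
photon_trace <- function(counts, bin_dt, t_start = 0, attrs = list()) {
  if (length(counts) < 2) stop("counts must have length >= 2")
  if (!is.numeric(bin_dt) || bin_dt <= 0) stop("bin_dt must be > 0")
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(
    list(counts = as.integer(counts), bin_dt = bin_dt, t_start = t_start,
         attrs = attrs),
    class = "photon_trace"
  )
}

#' @export
print.photon_trace <- function(x, ...) {
  dur <- length(x$counts) * x$bin_dt
  cat(sprintf("<photon_trace> %d bins of %.3g s (%.3g s, mean rate %.4g counts/s)\n",
              length(x$counts), x$bin_dt, dur,
              mean(x$counts) / x$bin_dt))
  invisible(x)
}

#' @export
length.photon_trace <- function(x) length(x$counts)

#' Raster scan geometry
#'
#' Timing and pixel-size metadata of a raster scan.  `t_line` includes the
#' flyback dead time, so `t_line >= n_cols * t_pix`.  The scan angle
#' `alpha` (degrees) rotates scan-frame displacements into the sample
#' frame; pixel sizes `s_xi`, `s_psi`, `s_zeta` are in micrometres per
#' pixel along the fast, slow, and axial scan axes.
#'
#' @param t_pix pixel dwell time, s.
#' @param t_line line time including flyback, s.
#' @param s_xi,s_psi,s_zeta pixel sizes, um/pixel.
#' @param alpha scan angle, degrees.
#' @param n_cols,n_rows image dimensions in pixels.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(t_pix, t_line, s_xi, s_psi, s_zeta = s_xi,
                          alpha = 0, n_cols, n_rows) {
  if (t_pix <= 0 || t_line <= 0) stop("scan times must be > 0")
  if (t_line < n_cols * t_pix - 1e-12)
    stop("t_line must be >= n_cols * t_pix (flyback would be negative)")
  if (any(c(s_xi, s_psi, s_zeta) <= 0)) stop("pixel sizes must be > 0")
  structure(
    list(t_pix = t_pix, t_line = t_line, s_xi = s_xi, s_psi = s_psi,
         s_zeta = s_zeta, alpha = alpha, n_cols = as.integer(n_cols),
         n_rows = as.integer(n_rows)),
    class = "scan_geometry"
  )
}

#' RICS image stack
#'
#' @param frames numeric array `n_frames x n_rows x n_cols` of nonnegative
#'   photon counts.
#' @param geometry a [scan_geometry()].
#' @param attrs named list of metadata (angle, speed, slot id, ...).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, geometry, attrs = list()) {
  if (length(dim(frames)) != 3) stop("frames must be a 3D array")
  if (any(frames < 0)) stop("counts must be nonnegative")
  if (!inherits(geometry, "scan_geometry")) stop("geometry must be a scan_geometry")
  if (dim(frames)[3] != geometry$n_cols || dim(frames)[2] != geometry$n_rows)
    stop("frame shape inconsistent with scan geometry")
  structure(list(frames = frames, geometry = geometry, attrs = attrs),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frames of %d x %d px (t_pix %.3g us, t_line %.3g ms, alpha %g deg)\n",
              d[1], d[2], d[3], x$geometry$t_pix * 1e6,
              x$geometry$t_line * 1e3, x$geometry$alpha))
  invisible(x)
}

#' Temporal autocorrelation curve
#'
#' A tibble with columns `lag` (s, strictly increasing, >= one bin),
#' `g` (correlation value) and optionally `sigma` (standard error of the
#' mean across traces), carrying `n_traces` and free metadata attributes.
#'
#' @param lag lag times, s.
#' @param g correlation values.
#' @param sigma optional per-lag standard error of the mean.
#' @param n_traces number of contributing traces.
#' @param attrs named list of metadata.
#' @return A tibble of class `acf_curve`.
#' @export
acf_curve <- function(lag, g, sigma = NULL, n_traces = 1L, attrs = list()) {
  if (any(diff(lag) <= 0)) stop("lags must be strictly increasing")
  if (!is.null(sigma)) {
    if (length(sigma) != length(g)) stop("sigma length mismatch")
    if (any(sigma < 0, na.rm = TRUE)) stop("sigma must be >= 0")
  }
  out <- tibble::tibble(lag = as.numeric(lag), g = as.numeric(g))
  if (!is.null(sigma)) out$sigma <- as.numeric(sigma)
  structure(out, class = c("acf_curve", class(out)),
            n_traces = as.integer(n_traces), cs_attrs = attrs)
}

#' Spatial (2D) autocorrelation of a RICS stack
#'
#' @param g matrix of correlation values, rows indexed by line lag `psi`,
#'   columns by pixel lag `xi`.
#' @param xi integer pixel lags along the fast-scan axis (may be negative).
#' @param psi integer line lags along the slow-scan axis (>= 0).
#' @param geometry the [scan_geometry()] of the source stack.
#' @param sigma optional matrix of per-point standard errors across frames.
#' @param attrs named list of metadata.
#' @return An object of class `acf_image`.
#' @export
acf_image <- function(g, xi, psi, geometry, sigma = NULL, attrs = list()) {
  if (!all(is.finite(g))) stop("g must be finite")
  if (nrow(g) != length(psi) || ncol(g) != length(xi))
    stop("g shape inconsistent with lag vectors")
  structure(
    list(g = g, xi = as.integer(xi), psi = as.integer(psi),
         geometry = geometry, sigma = sigma, attrs = attrs),
    class = "acf_image"
  )
}

#' @export
print.acf_image <- function(x, ...) {
  cat(sprintf("<acf_image> %d psi-lines x %d xi-lags (xi %d..%d, psi %d..%d)\n",
              length(x$psi), length(x$xi), min(x$xi), max(x$xi),
              min(x$psi), max(x$psi)))
  invisible(x)
}

#' Zero-lag value of a 2D ACF
#' @param acf an [acf_image()].
#' @return The (0, 0) correlation value.
#' @export
acf_zero_lag <- function(acf) {
  acf$g[match(0L, acf$psi), match(0L, acf$xi)]
}
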