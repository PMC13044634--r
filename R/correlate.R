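#' Temporal autocorrelation of a photon trace
#'
#' Estimates `G(tau) = <dI(t) dI(t + tau)> / <I>^2` over a time window,
#' with `dI = I - <I>` and `<I>` the window mean.  The numerator uses the
#' conventional biased (1/M) fluctuation estimator, computed by
#' zero-padded FFT (exactly equal to the direct double-sum estimator up to
#' floating point).  Lags are dense and linear from one bin up to
#' `max_lag`; the zero lag (shot-noise dominated) is not returned.
#'
#' @param trace a [photon_trace()].
#' @param window analysis window `c(t0, t1)` in seconds relative to
#'   `t_start`, or `NULL` for the full trace.
#' @param max_lag maximum lag, s (must be shorter than the window).
#' @return An [acf_curve()].
#' @export
acf_fcs <- function(trace, window = NULL, max_lag) {
  x <- trace$counts
  dt <- trace$bin_dt
  if (!is.null(window)) {
    i0 <- max(1L, floor(window[1] / dt) + 1L)
    i1 <- min(length(x), ceiling(window[2] / dt))
    if (i1 <= i0) stop("empty analysis window")
    x <- x[i0:i1]
  }
  n <- length(x)
  k_max <- floor(max_lag / dt)
  if (k_max >= n) stop("max_lag must be shorter than the analysis window")
  if (k_max < 1) stop("max_lag shorter than one bin")
  m <- mean(x)
  if (m == 0) stop("zero mean intensity: normalization undefined")
  num <- fft_autocov(x - m, k_max) / n
  acf_curve(lag = (1:k_max) * dt, g = num[-1] / m^2, n_traces = 1L,
            attrs = trace$attrs)
}

# raw autocovariance sums  sum_t x_t x_{t+k}  for k = 0..k_max,
# zero-padded FFT (linear, not circular)
fft_autocov <- function(x, k_max) {
  n <- length(x)
  np <- nextn(n + k_max + 1L)
  xp <- c(x, numeric(np - n))
  f <- fft(xp)
  s <- Re(fft(f * Conj(f), inverse = TRUE)) / np
  s[1:(k_max + 1L)]
}

#' Average autocorrelation curves
#'
#' Pointwise mean of ACF curves computed on an identical lag grid, with
#' the per-lag standard error of the mean attached when two or more curves
#' contribute.
#'
#' @param curves list of [acf_curve()] objects on the same lag grid.
#' @return An [acf_curve()] with `sigma` = SEM across curves.
#' @export
acf_mean <- function(curves) {
  lags <- curves[[1]]$lag
  for (cu in curves)
    if (!isTRUE(all.equal(cu$lag, lags))) stop("mismatched lag grids")
  G <- vapply(curves, function(cu) cu$g, numeric(length(lags)))
  n <- length(curves)
  sigma <- if (n >= 2) apply(G, 1, sd) / sqrt(n) else NULL
  acf_curve(lags, rowMeans(G), sigma = sigma, n_traces = n,
            attrs = attr(curves[[1]], "cs_attrs") %||% list())
}

#' Spatial autocorrelation of a RICS image stack
#'
#' Computes the 2D spatial correlation of intensity fluctuations per frame
#' and averages over frames.  With `mode = "mean_normalize"` each frame is
#' normalized by subtracting its mean and dividing by the squared mean
#' intensity (solution-type data).  With `mode = "background_subtract"` the
#' supplied group-average image is subtracted from each frame first and the
#' result is normalized by the variance of the background-subtracted
#' signal raised to `variance_power` (structured samples); the default
#' power 1 makes the zero-lag value approximately 1.
#'
#' At each lag the numerator averages over all pixel pairs that fall
#' inside the frame (no periodic wraparound).  The per-point `sigma` is
#' the standard error across frames when at least two frames contribute.
#'
#' @param stack an [image_stack()].
#' @param background group-average background image (matrix
#'   `n_rows x n_cols`), required iff `mode = "background_subtract"`.
#' @param mode normalization variant.
#' @param xi_max,psi_max largest pixel/line lags returned (defaults:
#'   `n_cols %/% 2` and `n_rows %/% 2`).
#' @param region optional correlation region `c(row0, row1, col0, col1)`
#'   (1-based, inclusive) restricting the analysis to a sub-image.
#' @param reference optional reference region for pair-correlation: the
#'   reference sub-image is cross-correlated against the (larger) `region`.
#' @param variance_power exponent applied to the variance in the
#'   background-subtracted normalization (1 or 2; the printed rule is
#'   ambiguous, see the methods vignette).
#' @return An [acf_image()].
#' @export
acf_rics <- function(stack, background = NULL,
                     mode = c("mean_normalize", "background_subtract"),
                     xi_max = NULL, psi_max = NULL,
                     region = NULL, reference = NULL, variance_power = 1) {
  mode <- match.arg(mode)
  fr <- stack$frames
  nf <- dim(fr)[1]
  if (nf < 1) stop("empty stack")
  if (mode == "background_subtract" && is.null(background))
    stop("background image required for background_subtract mode")
  if (!is.null(background) &&
      !all(dim(background) == dim(fr)[2:3]))
    stop("frame/background shape mismatch")
  if (is.null(region)) region <- c(1L, dim(fr)[2], 1L, dim(fr)[3])
  nr <- region[2] - region[1] + 1L
  nc <- region[4] - region[3] + 1L
  if (is.null(xi_max)) xi_max <- nc %/% 2L
  if (is.null(psi_max)) psi_max <- nr %/% 2L
  xi <- (-xi_max):xi_max
  psi <- 0:psi_max

  gsum <- matrix(0, length(psi), length(xi))
  gsq <- matrix(0, length(psi), length(xi))
  for (f in seq_len(nf)) {
    img <- fr[f, region[1]:region[2], region[3]:region[4]]
    if (mode == "background_subtract") {
      d <- img - background[region[1]:region[2], region[3]:region[4]]
      denom <- var(as.vector(d))^variance_power
    } else {
      mu <- mean(img)
      d <- img - mu
      denom <- mu^2
    }
    if (denom == 0) stop("zero normalization denominator")
    if (is.null(reference)) {
      gf <- xcorr2_valid(d, d, xi_max, psi_max) / denom
    } else {
      ref <- fr[f, reference[1]:reference[2], reference[3]:reference[4]]
      if (mode == "background_subtract") {
        dref <- ref - background[reference[1]:reference[2],
                                 reference[3]:reference[4]]
      } else {
        dref <- ref - mean(ref)
        denom <- mean(ref) * mean(img)
        if (denom == 0) stop("zero normalization denominator")
      }
      # embed the reference in the frame of the target region
      demb <- matrix(0, nr, nc)
      memb <- matrix(0, nr, nc)
      r_off <- reference[1] - region[1]
      c_off <- reference[3] - region[3]
      rr <- (1 + r_off):(r_off + nrow(dref))
      cc <- (1 + c_off):(c_off + ncol(dref))
      demb[rr, cc] <- dref
      memb[rr, cc] <- 1
      gf <- xcorr2_valid(demb, d, xi_max, psi_max, mask_a = memb) / denom
    }
    gsum <- gsum + gf
    gsq <- gsq + gf^2
  }
  g <- gsum / nf
  sigma <- if (nf >= 2) {
    sqrt(pmax(gsq / nf - g^2, 0) / (nf - 1))
  } else NULL
  acf_image(g, xi, psi, stack$geometry, sigma = sigma, attrs = stack$attrs)
}

# mean over valid pairs of  a(x, y) * b(x + xi, y + psi)  via zero-padded
# FFT; rows of a/b indexed by the slow axis (psi), columns by the fast
# axis (xi).  mask_a marks which entries of `a` participate (for
# pair-correlation where the reference occupies part of the frame).
xcorr2_valid <- function(a, b, xi_max, psi_max, mask_a = NULL) {
  nr <- nrow(a); nc <- ncol(a)
  pr <- nextn(nr + psi_max); pc <- nextn(nc + xi_max)
  pad <- function(m) {
    out <- matrix(0, pr, pc)
    out[1:nr, 1:nc] <- m
    out
  }
  fa <- fft(pad(a)); fb <- fft(pad(b))
  cc <- Re(fft(Conj(fa) * fb, inverse = TRUE)) / (pr * pc)
  ma <- if (is.null(mask_a)) matrix(1, nr, nc) else mask_a
  fma <- fft(pad(ma)); fmb <- fft(pad(matrix(1, nr, nc)))
  nn <- Re(fft(Conj(fma) * fmb, inverse = TRUE)) / (pr * pc)
  idx <- function(k, n) ifelse(k >= 0, k + 1L, n + k + 1L)
  xi <- (-xi_max):xi_max
  psi <- 0:psi_max
  num <- cc[idx(psi, pr), idx(xi, pc), drop = FALSE]
  cnt <- round(nn[idx(psi, pr), idx(xi, pc), drop = FALSE])
  cnt[cnt < 1] <- NA
  out <- num / cnt
  out[is.na(out)] <- 0
  out
}

#' Sector grid for spatially resolved RICS analysis
#'
#' Defines how an image is split for spatially resolved autocorrelation:
#' `sector_self` correlates each sector with itself; `larger_self`
#' correlates a larger region centred on each sector; `pair`
#' cross-correlates each sector (reference) with a concentric larger area.
#'
#' @param config one of `"sector_self"`, `"larger_self"`, `"pair"`.
#' @param n_x,n_y number of sectors along the fast/slow axes (>= 1).
#' @param sector_size sector edge length, um.
#' @param corr_size edge length of the larger correlation area, um
#'   (required for `larger_self` and `pair`).
#' @return An object of class `sector_grid`.
#' @export
sector_grid <- function(config = c("sector_self", "larger_self", "pair"),
                        n_x, n_y, sector_size, corr_size = NULL) {
  config <- match.arg(config)
  if (n_x < 1 || n_y < 1) stop("n_x and n_y must be >= 1")
  if (sector_size <= 0) stop("sector_size must be > 0")
  if (config != "sector_self") {
    if (is.null(corr_size) || corr_size < sector_size)
      stop("corr_size >= sector_size required for this configuration")
  }
  structure(list(config = config, n_x = as.integer(n_x),
                 n_y = as.integer(n_y), sector_size = sector_size,
                 corr_size = corr_size),
            class = "sector_grid")
}

# evenly spaced 1-based region start pixels such that regions of `size_px`
# pixels touch but never cross the borders of an n-pixel axis; ties in the
# rounding go toward the image centre
sector_starts <- function(n_px, n_sec, size_px) {
  if (size_px > n_px) stop("correlation area larger than image")
  if (n_sec == 1) raw <- (n_px - size_px) / 2 + 1
  else raw <- seq(1, n_px - size_px + 1, length.out = n_sec)
  mid <- (n_px - size_px) / 2 + 1
  ifelse(raw <= mid, ceiling(raw - 0.5), floor(raw + 0.5))
}

#' Split an image into sector regions
#'
#' Computes sector centres evenly distributed across the image with all
#' correlation areas fully contained in it, and returns per-sector pixel
#' regions: the correlation region and, for the pair configuration, the
#' reference region.
#'
#' @param stack_shape image shape `c(n_rows, n_cols)` in pixels.
#' @param grid a [sector_grid()].
#' @param pixel_size pixel sizes `c(s_xi, s_psi)` um/pixel used to convert
#'   the grid's physical sizes to pixels.
#' @return A tibble with one row per sector: centre pixel coordinates and
#'   the correlation (and reference) regions as `c(row0, row1, col0,
#'   col1)` list-columns.
#' @export
split_sectors <- function(stack_shape, grid, pixel_size) {
  nr <- stack_shape[1]; nc <- stack_shape[2]
  sec_px_x <- max(1L, round(grid$sector_size / pixel_size[1]))
  sec_px_y <- max(1L, round(grid$sector_size / pixel_size[2]))
  if (grid$config == "sector_self") {
    corr_px_x <- sec_px_x; corr_px_y <- sec_px_y
  } else {
    corr_px_x <- max(1L, round(grid$corr_size / pixel_size[1]))
    corr_px_y <- max(1L, round(grid$corr_size / pixel_size[2]))
  }
  sx <- as.integer(sector_starts(nc, grid$n_x, corr_px_x))
  sy <- as.integer(sector_starts(nr, grid$n_y, corr_px_y))
  corr_px_x <- as.integer(corr_px_x); corr_px_y <- as.integer(corr_px_y)
  sec_px_x <- as.integer(sec_px_x); sec_px_y <- as.integer(sec_px_y)
  if (grid$config == "sector_self") {
    if ((grid$n_x > 1 && min(diff(sx)) < sec_px_x - 1e-9) ||
        (grid$n_y > 1 && min(diff(sy)) < sec_px_y - 1e-9))
      stop("sector_self sectors would overlap: image too small for the grid")
  }
  out <- tidyr::expand_grid(iy = seq_len(grid$n_y), ix = seq_len(grid$n_x))
  out$center_row <- sy[out$iy] + corr_px_y %/% 2L - 1L
  out$center_col <- sx[out$ix] + corr_px_x %/% 2L - 1L
  out$region <- purrr::map2(out$iy, out$ix, function(iy, ix)
    c(sy[iy], sy[iy] + corr_px_y - 1L, sx[ix], sx[ix] + corr_px_x - 1L))
  out$reference <- if (grid$config == "pair") {
    purrr::map2(out$center_row, out$center_col, function(cr, cc) {
      r0 <- cr - sec_px_y %/% 2L + 1L
      c0 <- cc - sec_px_x %/% 2L + 1L
      c(r0, r0 + sec_px_y - 1L, c0, c0 + sec_px_x - 1L)
    })
  } else {
    rep(list(NULL), nrow(out))
  }
  bad <- purrr::map_lgl(out$region, function(r)
    r[1] < 1 || r[3] < 1 || r[2] > nr || r[4] > nc)
  if (any(bad)) stop("requested regions do not fit inside the image")
  out
}

#' Crop and downsample a correlation function
#'
#' Removes leading lags (detector shot noise / afterpulsing region),
#' restricts a 2D ACF to the first `n_lines` psi-lines of the positive-xi
#' quadrant with at most `points_per_line` points per line, and optionally
#' averages points within logarithmically spaced lag bins (propagating
#' `sigma` as the SEM-combined value).
#'
#' @param acf an [acf_curve()] or [acf_image()].
#' @param drop_first number of leading lags removed from each line.
#' @param n_lines number of psi-lines kept (2D only; default 3).
#' @param points_per_line maximum number of points kept per line.
#' @param log_bins number of logarithmic bins, or `NULL` for none.
#' @return The cropped object, same class as the input.
#' @export
crop_and_downsample <- function(acf, drop_first = 0, n_lines = 3,
                                points_per_line = Inf, log_bins = NULL) {
  if (inherits(acf, "acf_curve")) {
    n <- nrow(acf)
    if (drop_first >= n) stop("nothing left after cropping")
    keep <- seq.int(drop_first + 1L, min(n, drop_first + points_per_line))
    lag <- acf$lag[keep]; g <- acf$g[keep]
    sig <- if ("sigma" %in% names(acf)) acf$sigma[keep] else NULL
    if (!is.null(log_bins)) {
      b <- log_bin(lag, g, sig, log_bins)
      lag <- b$lag; g <- b$g; sig <- b$sigma
    }
    return(acf_curve(lag, g, sigma = sig,
                     n_traces = attr(acf, "n_traces") %||% 1L,
                     attrs = attr(acf, "cs_attrs") %||% list()))
  }
  stopifnot(inherits(acf, "acf_image"))
  pos <- which(acf$xi >= 0)
  keep_xi <- pos[acf$xi[pos] >= drop_first]
  keep_xi <- head(keep_xi, points_per_line)
  keep_psi <- which(acf$psi %in% 0:(n_lines - 1))
  if (length(keep_xi) == 0 || length(keep_psi) == 0)
    stop("nothing left after cropping")
  g <- acf$g[keep_psi, keep_xi, drop = FALSE]
  sig <- if (!is.null(acf$sigma)) acf$sigma[keep_psi, keep_xi, drop = FALSE]
  xi <- acf$xi[keep_xi]
  if (!is.null(log_bins)) {
    # shared logarithmic binning of the xi axis across lines
    bins <- log_bin_index(xi - min(xi) + 1, log_bins)
    xi <- as.vector(tapply(xi, bins, mean))
    gb <- t(apply(g, 1, function(r) tapply(r, bins, mean)))
    sig <- if (!is.null(sig)) {
      t(apply(sig, 1, function(r)
        sqrt(tapply(r^2, bins, sum)) / tabulate(bins)))
    }
    g <- gb
  }
  acf_image(g, xi, acf$psi[keep_psi], acf$geometry, sigma = sig,
            attrs = acf$attrs)
}

log_bin_index <- function(x, n_bins) {
  lo <- log(min(x)); hi <- log(max(x))
  edges <- seq(lo, hi + 1e-9, length.out = n_bins + 1)
  findInterval(log(x), edges, rightmost.closed = TRUE)
}

log_bin <- function(lag, g, sigma, n_bins) {
  bins <- log_bin_index(lag, n_bins)
  n_in <- tabulate(bins)
  keep <- n_in > 0
  list(lag = as.vector(tapply(lag, bins, mean)),
       g = as.vector(tapply(g, bins, mean)),
       sigma = if (!is.null(sigma))
         as.vector(tapply(sigma^2, bins, sum))^0.5 / n_in[keep])
}
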