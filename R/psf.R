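#' Gaussian ellipsoid point spread function
#'
#' 3D Gaussian PSF `exp(-2x^2/wx^2 - 2y^2/wy^2 - 2z^2/wz^2)` with waists
#' given as 1/e^2 radii in micrometres (not FWHM).  A dimensionless scale
#' factor in \[0, 2\] multiplies all waists, accommodating calibration
#' uncertainty during fitting.
#'
#' @param w_x,w_y,w_z waist (1/e^2) radii, um.
#' @param scale dimensionless scale factor in \[0, 2\].
#' @return An object of class `gaussian_psf`.
#' @export
gaussian_psf <- function(w_x, w_y, w_z, scale = 1) {
  if (any(c(w_x, w_y, w_z) <= 0)) stop("waists must be > 0")
  if (scale < 0 || scale > 2) stop("scale must be in [0, 2]")
  structure(list(w_x = w_x, w_y = w_y, w_z = w_z, scale = scale),
            class = "gaussian_psf")
}

#' @export
print.gaussian_psf <- function(x, ...) {
  cat(sprintf("<gaussian_psf> waists (%.3g, %.3g, %.3g) um, scale %.3g, V_eff %.4g um^3\n",
              x$w_x, x$w_y, x$w_z, x$scale, v_eff(x)))
  invisible(x)
}

#' Gridded (measured) point spread function
#'
#' A 3D intensity grid sampled on voxels of physical size `voxel` um.
#' Values are stored peak-normalized; the normalization cancels in the
#' effective-volume integral and in all correlation models.
#'
#' @param values nonnegative 3D array of intensities (x, y, z order).
#' @param voxel voxel sizes `c(vx, vy, vz)`, um.
#' @param origin voxel index (1-based, possibly fractional) of the PSF
#'   centre; defaults to the intensity centroid.
#' @return An object of class `psf_grid`.
#' @export
psf_grid <- function(values, voxel, origin = NULL) {
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  if (any(values < 0)) stop("values must be >= 0")
  mx <- max(values)
  if (mx <= 0) stop("values must not be all zero")
  if (any(voxel <= 0)) stop("voxel sizes must be > 0")
  values <- values / mx
  if (is.null(origin)) origin <- grid_centroid(values)
  structure(list(values = values, voxel = as.numeric(voxel),
                 origin = as.numeric(origin)),
            class = "psf_grid")
}

#' @export
print.psf_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<psf_grid> %d x %d x %d voxels of (%.3g, %.3g, %.3g) um, V_eff %.4g um^3\n",
              d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3],
              v_eff(x)))
  invisible(x)
}

# intensity centroid in (possibly fractional) 1-based voxel indices
grid_centroid <- function(v) {
  d <- dim(v)
  tot <- sum(v)
  ix <- rowSums(v)          # sums over y, z for each x
  iy <- apply(v, 2, sum)
  iz <- apply(v, 3, sum)
  c(sum(seq_len(d[1]) * ix), sum(seq_len(d[2]) * iy),
    sum(seq_len(d[3]) * iz)) / tot
}

#' Effective focal volume
#'
#' Computes `V_eff = [integral PSF]^2 / integral PSF^2` (um^3), which sets
#' the zero-lag correlation amplitude `1 / (V_eff <C>)`.  For the Gaussian
#' ellipsoid this is the closed form `pi^(3/2) (s wx)(s wy)(s wz)` with `s`
#' the PSF scale factor; for a gridded PSF it is evaluated by Riemann sum
#' over voxels.
#'
#' @param psf a [gaussian_psf()] or [psf_grid()].
#' @param ... unused.
#' @return Effective volume in um^3.
#' @export
v_eff <- function(psf, ...) UseMethod("v_eff")

#' @rdname v_eff
#' @export
v_eff.gaussian_psf <- function(psf, ...) {
  s <- psf$scale
  pi^1.5 * (s * psf$w_x) * (s * psf$w_y) * (s * psf$w_z)
}

#' @rdname v_eff
#' @export
v_eff.psf_grid <- function(psf, ...) {
  v <- psf$values
  edge_max <- max(v[1, , ], v[dim(v)[1], , ], v[, 1, ], v[, dim(v)[2], ],
                  v[, , 1], v[, , dim(v)[3]])
  if (edge_max >= 0.01)
    warning("PSF grid edge values exceed 1% of peak; V_eff quadrature may be truncated")
  vv <- prod(psf$voxel)
  (sum(v) * vv)^2 / (sum(v^2) * vv)
}

#' Downsample a gridded PSF by block-mean pooling
#'
#' Coarsens a PSF grid by integer factors per axis, averaging values within
#' blocks and multiplying voxel sizes accordingly.  Trailing planes that do
#' not fill a complete block are dropped (floor division), so e.g. a 35 x
#' 35 x 43 grid becomes 17 x 17 x 21 at factor 2 and 11 x 11 x 14 at
#' factor 3.
#'
#' @param psf a [psf_grid()].
#' @param factors integer downsampling factors `c(fx, fy, fz)`, all >= 1.
#' @return A coarser [psf_grid()].
#' @export
downsample_psf <- function(psf, factors) {
  factors <- as.integer(factors)
  if (length(factors) == 1) factors <- rep(factors, 3)
  d <- dim(psf$values)
  if (any(factors < 1)) stop("factors must be >= 1")
  if (any(factors > d)) stop("factor exceeds grid size")
  nd <- d %/% factors
  v <- psf$values[seq_len(nd[1] * factors[1]),
                  seq_len(nd[2] * factors[2]),
                  seq_len(nd[3] * factors[3]), drop = FALSE]
  # block mean via successive axis folding
  dim(v) <- c(factors[1], nd[1], factors[2] * nd[2] * factors[3] * nd[3])
  v <- colMeans(v)
  dim(v) <- c(nd[1], factors[2], nd[2] * factors[3] * nd[3])
  v <- apply(v, c(1, 3), mean)
  dim(v) <- c(nd[1], nd[2], factors[3], nd[3])
  v <- apply(v, c(1, 2, 4), mean)
  psf_grid(v, psf$voxel * factors)
}

#' Sample a Gaussian PSF onto a voxel grid
#'
#' Convenience constructor used for validation and synthetic bead stacks.
#'
#' @param psf a [gaussian_psf()].
#' @param voxel voxel sizes, um.
#' @param half_extent half-width of the grid per axis, um; default 2.5
#'   waists.
#' @param center offset of the PSF peak from the grid centre, um.
#' @return A [psf_grid()].
#' @export
sample_gaussian_psf <- function(psf, voxel,
                                half_extent = 2.5 * psf$scale *
                                  c(psf$w_x, psf$w_y, psf$w_z),
                                center = c(0, 0, 0)) {
  n <- pmax(3L, 2L * floor(half_extent / voxel) + 1L)
  ax <- lapply(1:3, function(i) (seq_len(n[i]) - (n[i] + 1) / 2) * voxel[i])
  w <- psf$scale * c(psf$w_x, psf$w_y, psf$w_z)
  gx <- exp(-2 * (ax[[1]] - center[1])^2 / w[1]^2)
  gy <- exp(-2 * (ax[[2]] - center[2])^2 / w[2]^2)
  gz <- exp(-2 * (ax[[3]] - center[3])^2 / w[3]^2)
  psf_grid(outer(outer(gx, gy), gz), voxel)
}

# least-squares fit of the Gaussian ellipsoid to a 3D grid;
# returns centroid (um, relative to grid centre) and waists (um)
fit_gaussian_ellipsoid <- function(values, voxel) {
  d <- dim(values)
  ax <- lapply(1:3, function(i) (seq_len(d[i]) - (d[i] + 1) / 2) * voxel[i])
  cen <- grid_centroid(values)
  c_um <- (cen - (d + 1) / 2) * voxel
  # second-moment start for waists: w^2 = 4 * var for exp(-2 x^2 / w^2)
  mom <- function(i, axis) {
    m <- apply(values, i, sum)
    m <- m / sum(m)
    sqrt(4 * sum(m * (axis - sum(m * axis))^2))
  }
  w0 <- pmax(c(mom(1, ax[[1]]), mom(2, ax[[2]]), mom(3, ax[[3]])),
             0.25 * voxel)
  grid <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  yv <- as.vector(values)
  resid_fn <- function(p) {
    mu <- p[1:3]; w <- p[4:6]; A <- p[7]
    yv - A * exp(-2 * ((grid$x - mu[1])^2 / w[1]^2 +
                       (grid$y - mu[2])^2 / w[2]^2 +
                       (grid$z - mu[3])^2 / w[3]^2))
  }
  p0 <- c(c_um, w0, max(yv))
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fn,
    lower = c(rep(-Inf, 3), rep(1e-4, 3), 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  list(center = fit$par[1:3], waist = abs(fit$par[4:6]),
       amplitude = fit$par[7])
}

#' Build a PSF model from bead stacks
#'
#' Localizes sub-diffraction beads in one or more 3D stacks, extracts a
#' subvolume around each, aligns the subvolumes on their Gaussian-fit
#' centroids (least-squares fit of the Gaussian ellipsoid), averages them
#' into a single gridded PSF, and fits the Gaussian ellipsoid to the
#' average to report equivalent waists.
#'
#' @param stacks a [psf_grid()] or list of them (bead image stacks, all on
#'   the same voxel grid).
#' @param threshold bead detection threshold as a fraction of the global
#'   maximum.
#' @param halfwidth_factor subvolume half-width in units of the fitted
#'   waist per axis.
#' @param subtract_background subtract the per-stack median before
#'   processing (detector offset removal).
#' @param exclusion_um per-axis half-extent (um) masked around each
#'   detected peak during localization; beads closer than twice this are
#'   rejected as overlapping.  Should generously cover one bead image.
#' @return A list with elements `psf` (the averaged [psf_grid()]),
#'   `gaussian` (the fitted [gaussian_psf()]), and `beads` (a tibble of
#'   per-bead centroids and waists).
#' @export
build_psf_from_beads <- function(stacks, threshold = 0.3,
                                 halfwidth_factor = 5,
                                 subtract_background = TRUE,
                                 exclusion_um = c(0.8, 0.8, 3)) {
  if (inherits(stacks, "psf_grid")) stacks <- list(stacks)
  if (length(stacks) < 1) stop("at least one bead stack required")
  voxel <- stacks[[1]]$voxel
  if (any(voxel[1:2] > 0.040 + 1e-12) || voxel[3] > 0.100 + 1e-12)
    warning("coarse voxel sampling (recommended: lateral <= 40 nm, axial <= 100 nm)")

  beads <- list()
  for (st in stacks) {
    v <- st$values
    if (subtract_background) v <- pmax(v - median(v), 0)
    mx0 <- max(v)
    if (mx0 <= 0) next
    work <- v
    centers <- list()
    hw <- pmax(3L, ceiling(exclusion_um / voxel))
    repeat {
      mx <- max(work)
      if (mx < threshold * mx0) break
      idx <- arrayInd(which.max(work), dim(work))[1, ]
      centers[[length(centers) + 1]] <- idx
      rr <- lapply(1:3, function(i)
        max(1, idx[i] - hw[i]):min(dim(work)[i], idx[i] + hw[i]))
      work[rr[[1]], rr[[2]], rr[[3]]] <- 0
    }
    if (length(centers) >= 2) {
      cm <- do.call(rbind, centers)
      for (i in 1:(nrow(cm) - 1)) for (j in (i + 1):nrow(cm)) {
        sep <- abs(cm[i, ] - cm[j, ]) * voxel
        if (all(sep < 2 * exclusion_um))
          stop("overlapping beads: minimum-separation violation")
      }
    }
    for (idx in centers) beads[[length(beads) + 1]] <- list(stack = v, peak = idx)
  }
  if (length(beads) == 0) stop("no bead above threshold")

  # first pass: fit each bead in a generous subvolume to get waists
  fits <- lapply(beads, function(b) {
    sub <- extract_subvolume(b$stack, b$peak, pmax(5L, ceiling(0.8 / voxel)))
    f <- fit_gaussian_ellipsoid(sub$values, voxel)
    list(sub = sub, fit = f)
  })
  w_est <- rowMeans(sapply(fits, function(f) f$fit$waist))
  hw_vox <- pmax(2L, ceiling(halfwidth_factor * w_est / voxel))

  # second pass: re-extract at 5x waist, align on fitted centroid, average
  aligned <- lapply(seq_along(beads), function(i) {
    b <- beads[[i]]
    sub <- extract_subvolume(b$stack, b$peak, hw_vox)
    f <- fit_gaussian_ellipsoid(sub$values, voxel)
    shift_grid(sub$values, -f$center / voxel)
  })
  avg <- Reduce(`+`, aligned) / length(aligned)
  avg_fit <- fit_gaussian_ellipsoid(avg, voxel)
  bead_tbl <- tibble::tibble(
    bead = seq_along(fits),
    wx = sapply(fits, function(f) f$fit$waist[1]),
    wy = sapply(fits, function(f) f$fit$waist[2]),
    wz = sapply(fits, function(f) f$fit$waist[3])
  )
  list(psf = psf_grid(pmax(avg, 0), voxel),
       gaussian = gaussian_psf(avg_fit$waist[1], avg_fit$waist[2],
                               avg_fit$waist[3]),
       beads = bead_tbl)
}

extract_subvolume <- function(v, center, hw) {
  d <- dim(v)
  rr <- lapply(1:3, function(i) {
    lo <- max(1L, center[i] - hw[i]); hi <- min(d[i], center[i] + hw[i])
    lo:hi
  })
  list(values = v[rr[[1]], rr[[2]], rr[[3]], drop = FALSE],
       offset = sapply(rr, function(r) r[1]))
}

# shift a 3D grid by fractional voxel offsets (out[i] = v[i - shift]) via
# trilinear interpolation, zero outside
shift_grid <- function(v, shift_vox) {
  interp1 <- function(arr, s, axis) {
    # out[i] = arr[i - s] along one axis
    n <- dim(arr)[axis]
    pos <- seq_len(n) - s
    lo <- floor(pos); fr <- pos - lo
    get_plane <- function(i) {
      i[i < 1 | i > n] <- NA
      switch(axis,
             arr[i, , , drop = FALSE],
             arr[, i, , drop = FALSE],
             arr[, , i, drop = FALSE])
    }
    a <- get_plane(lo); b <- get_plane(lo + 1)
    a[is.na(a)] <- 0; b[is.na(b)] <- 0
    fr_shape <- c(1, 1, 1); fr_shape[axis] <- n
    frA <- array(rep(fr, each = prod(dim(arr)[seq_len(axis - 1)])),
                 dim = dim(arr))
    a * (1 - frA) + b * frA
  }
  out <- interp1(v, shift_vox[1], 1)
  out <- interp1(out, shift_vox[2], 2)
  out <- interp1(out, shift_vox[3], 3)
  out
}
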