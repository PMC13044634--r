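# shared fixtures, all generated in code

std_psf <- function() gaussian_psf(0.3, 0.3, 1.1)

# a synthetic ACF curve drawn around the model (cheap stand-in for a full
# simulation when only curve-level behaviour is under test)
model_curve <- function(dc = 100, c_nM = 4, n = 80, noise = 0,
                        tsa = 0, tau_t = NULL, seed = NULL,
                        max_lag = 2e-2) {
  if (!is.null(seed)) set.seed(seed)
  lags <- exp(seq(log(1e-6), log(max_lag), length.out = n))
  lags <- sort(unique(lags))
  p <- diffusion_params(if (tsa > 0) "iso1" else "iso1", dc = dc,
                        c_nM = c_nM, tsa = tsa, tau_t = tau_t)
  g <- g_fcs(lags, p, std_psf())
  if (noise > 0) g <- g + rnorm(length(g), 0, noise)
  acf_curve(lags, g, sigma = if (noise > 0) rep(noise, length(g)),
            n_traces = 1L)
}

# direct O(N^2) evaluation of the temporal ACF estimator (oracle)
acf_direct <- function(x, k_max) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  vapply(seq_len(k_max), function(k)
    sum(d[1:(n - k)] * d[(k + 1):n]) / n / m^2, numeric(1))
}

# direct double-sum evaluation of the spatial ACF estimator (oracle);
# rows = slow axis (psi), cols = fast axis (xi); frame-mean normalization
acf2d_direct <- function(img, xi_max, psi_max) {
  mu <- mean(img)
  d <- img - mu
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, psi_max + 1, 2 * xi_max + 1)
  for (psi in 0:psi_max) {
    for (xi in (-xi_max):xi_max) {
      s <- 0; cnt <- 0
      for (y in 1:nr) {
        for (x in 1:nc) {
          yy <- y + psi; xx <- x + xi
          if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc) {
            s <- s + d[y, x] * d[yy, xx]
            cnt <- cnt + 1
          }
        }
      }
      out[psi + 1, xi + xi_max + 1] <- s / cnt / mu^2
    }
  }
  out
}

quick_rics_geom <- function(n = 32, t_pix = 4e-6, alpha = 0,
                            s_pix = 0.1, flyback = 1.25) {
  scan_geometry(t_pix = t_pix, t_line = flyback * n * t_pix,
                s_xi = s_pix, s_psi = s_pix, alpha = alpha,
                n_cols = n, n_rows = n)
}
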