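#' Simulation configuration for the Brownian-dynamics emitter
#'
#' Defines a free-diffusion photon-emission simulation: `n_particles`
#' molecules diffuse in a periodic box centred on the laser focus, and the
#' photon count in each time bin is Poisson with mean
#' `dt * (background + brightness * sum_k PSF(r_k))`, the PSF being
#' peak-normalized.  Defaults are the single-trace study conditions used
#' throughout validation: 100 particles in a 2.5 x 2.5 x 7 um box with
#' DC = 100 um^2/s, simulated at a 1 us time step with a Gaussian PSF of
#' waists (0.3, 0.3, 1.1) um.
#'
#' @param n_particles number of molecules (>= 1).
#' @param box box edge lengths `c(Lx, Ly, Lz)`, um.
#' @param dc_true diffusion coefficient(s) um^2/s; scalar or `c(DCx, DCy,
#'   DCz)`.
#' @param duration simulated time, s.
#' @param dt time step = photon bin width, s.
#' @param brightness molecular brightness at the PSF peak, counts/s.
#' @param background background count rate, counts/s.
#' @param psf a [gaussian_psf()].
#' @param seed integer seed; the simulator uses its own deterministic RNG
#'   stream, so equal seeds give bit-identical output.
#' @param scan a [scan_geometry()] for raster scanning, or `NULL` for
#'   point FCS at the box centre.
#' @param init_positions optional `n_particles x 3` matrix of initial
#'   positions (um, box-centred coordinates); default uniform in the box.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_particles = 100, box = c(2.5, 2.5, 7),
                       dc_true = 100, duration = 80, dt = 1e-6,
                       brightness = 30000, background = 0,
                       psf = gaussian_psf(0.3, 0.3, 1.1), seed = 1,
                       scan = NULL, init_positions = NULL) {
  if (n_particles < 1) stop("n_particles must be >= 1")
  if (any(box <= 0)) stop("box lengths must be > 0")
  if (dt <= 0 || duration < dt) stop("need dt > 0 and duration >= dt")
  dc_true <- if (length(dc_true) == 1) rep(dc_true, 3) else as.numeric(dc_true)
  if (any(!is.finite(dc_true)) || any(dc_true < 0))
    stop("dc_true must be finite and >= 0")
  if (!all(is.finite(c(box, duration, dt, brightness, background))))
    stop("non-finite simulation parameters")
  if (!inherits(psf, "gaussian_psf"))
    stop("the simulator requires a gaussian_psf")
  w <- psf$scale * c(psf$w_x, psf$w_y, psf$w_z)
  if (any(box < 5 * w))
    warning("box smaller than 5 PSF waists on some axis; periodic images may correlate")
  structure(list(n_particles = as.integer(n_particles), box = box,
                 dc_true = dc_true, duration = duration, dt = dt,
                 brightness = brightness, background = background,
                 psf = psf, seed = as.integer(seed), scan = scan,
                 init_positions = init_positions),
            class = "sim_config")
}

ground_truth_attrs <- function(cfg) {
  list(dc_true = cfg$dc_true, c_true_nM = cfg$n_particles /
         prod(cfg$box) / .NM_TO_UM3,
       n_particles = cfg$n_particles, box = cfg$box,
       brightness = cfg$brightness, background = cfg$background,
       psf_waist = c(cfg$psf$w_x, cfg$psf$w_y, cfg$psf$w_z),
       psf_scale = cfg$psf$scale, seed = cfg$seed, dt = cfg$dt)
}

#' Simulate a point-FCS photon trace
#'
#' Runs the Brownian-dynamics emitter with the focus fixed at the box
#' centre.  Per step each particle takes an independent Gaussian
#' displacement with per-axis standard deviation `sqrt(2 DC_i dt)` and is
#' wrapped periodically; the photon count of the bin is Poisson with the
#' intensity evaluated at the bin start.
#'
#' @param cfg a [sim_config()] with `scan = NULL`.
#' @param traj_stride if > 0, store unwrapped particle positions every
#'   `traj_stride` steps (for diffusion diagnostics such as MSD checks).
#' @return A [photon_trace()]; ground truth is stored in `$attrs
#'   $ground_truth`, and trajectories (snapshots x 3 x particles) in
#'   `$attrs$trajectories` when requested.
#' @export
simulate_fcs_trace <- function(cfg, traj_stride = 0L) {
  if (!is.null(cfg$scan)) stop("cfg$scan must be absent for point FCS")
  n_steps <- round(cfg$duration / cfg$dt)
  if (n_steps > 2e9) stop("duration/dt overflows addressable trace length")
  res <- bd_simulate_fcs(
    cfg$n_particles, cfg$box, cfg$dc_true, cfg$duration, cfg$dt,
    cfg$brightness, cfg$background,
    c(cfg$psf$w_x, cfg$psf$w_y, cfg$psf$w_z), cfg$psf$scale,
    as.double(cfg$seed), cfg$init_positions, as.integer(traj_stride)
  )
  attrs <- list(ground_truth = ground_truth_attrs(cfg))
  if (traj_stride > 0) {
    attrs$trajectories <- res$trajectories
    attrs$traj_dt <- cfg$dt * traj_stride
  }
  photon_trace(res$counts, cfg$dt, attrs = attrs)
}

#' Simulate a RICS image stack
#'
#' Raster-samples the same emission model: the focus visits pixels in scan
#' order, dwelling `t_pix` per pixel, with particles diffusing
#' continuously through the dwell and flyback periods (no photons recorded
#' during flyback).  The scan axes are rotated by the scan angle in the
#' sample frame.
#'
#' @param cfg a [sim_config()] with `scan` set to a [scan_geometry()].
#' @param n_frames number of frames.
#' @return An [image_stack()] with ground truth in `$attrs$ground_truth`.
#' @export
simulate_rics_stack <- function(cfg, n_frames) {
  g <- cfg$scan
  if (is.null(g)) stop("cfg$scan must be set for raster scanning")
  if (g$t_line < g$n_cols * g$t_pix - 1e-12)
    stop("t_line shorter than n_cols * t_pix (negative flyback)")
  fr <- bd_simulate_rics(
    cfg$n_particles, cfg$box, cfg$dc_true, as.integer(n_frames),
    g$n_rows, g$n_cols, g$t_pix, g$t_line, g$s_xi, g$s_psi, g$alpha,
    cfg$brightness, cfg$background,
    c(cfg$psf$w_x, cfg$psf$w_y, cfg$psf$w_z), cfg$psf$scale,
    as.double(cfg$seed), cfg$init_positions
  )
  image_stack(fr, g, attrs = list(ground_truth = ground_truth_attrs(cfg)))
}
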