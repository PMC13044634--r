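# HDF5 persistence.  Layout (version 1.0):
#   /traces/<name>/counts            + group attrs bin_dt, t_start, ...
#   /images/<name>/frames            + scan-geometry attrs
#   /acf/<name>/{lag,g,sigma}        (curves)  or {g,xi,psi,sigma} (2D)
#   /fits/<name>/{theta,stderr,...}  + metric attrs
#   /psf/<name>/values               + voxel/origin attrs, or Gaussian attrs
# Ground truth of simulated objects lives in a `ground_truth` subgroup.
# Every object group carries `corrspec_version`; arrays are stored at full
# precision.

.CS_LAYOUT_VERSION <- "1.0"

h5_exists <- function(file, path) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid))
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  cur <- ""
  for (p in parts) {
    cur <- paste0(cur, "/", p)
    if (!rhdf5::H5Lexists(fid, cur)) return(FALSE)
  }
  TRUE
}

h5_ensure_file <- function(file) {
  if (!file.exists(file)) rhdf5::h5createFile(file)
  invisible(file)
}

h5_ensure_group <- function(file, path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  cur <- ""
  for (p in parts) {
    cur <- paste0(cur, "/", p)
    if (!h5_exists(file, cur)) rhdf5::h5createGroup(file, cur)
  }
  invisible(cur)
}

h5_write_attrs <- function(file, path, attrs) {
  if (length(attrs) == 0) return(invisible())
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  obj <- rhdf5::H5Oopen(fid, path)
  on.exit(rhdf5::H5Oclose(obj), add = TRUE, after = FALSE)
  for (nm in names(attrs)) {
    v <- attrs[[nm]]
    if (is.null(v)) next
    if (!is.atomic(v)) stop("attribute '", nm, "' is not atomic")
    if (is.logical(v)) v <- as.integer(v)   # HDF5 attrs lack a bool type
    rhdf5::h5writeAttribute(v, obj, nm)
  }
  invisible()
}

h5_write_meta_group <- function(file, path, meta) {
  # nested list -> subgroup with atomic attributes (one level deep)
  h5_ensure_group(file, path)
  flat <- meta[vapply(meta, is.atomic, logical(1))]
  h5_write_attrs(file, path, flat)
}

check_version <- function(file, path) {
  at <- rhdf5::h5readAttributes(file, path)
  v <- at$corrspec_version
  if (is.null(v)) stop("not a corrspec object (missing version attribute)")
  if (!identical(as.character(v), .CS_LAYOUT_VERSION))
    stop("unknown corrspec layout version: ", v)
  at
}

stamp <- function(extra = list()) {
  c(list(corrspec_version = .CS_LAYOUT_VERSION), extra)
}

write_user_attrs <- function(file, path, attrs) {
  gt <- attrs$ground_truth
  attrs$ground_truth <- NULL
  attrs$trajectories <- NULL
  flat <- attrs[vapply(attrs, is.atomic, logical(1))]
  if (length(flat)) h5_write_attrs(file, path, flat)
  if (!is.null(gt)) h5_write_meta_group(file, paste0(path, "/ground_truth"), gt)
}

read_user_attrs <- function(file, path, drop) {
  at <- rhdf5::h5readAttributes(file, path)
  at[c(drop, "corrspec_version")] <- NULL
  at <- lapply(at, function(v) if (length(v) == 1) as.vector(v) else as.vector(v))
  if (h5_exists(file, paste0(path, "/ground_truth"))) {
    gt <- rhdf5::h5readAttributes(file, paste0(path, "/ground_truth"))
    at$ground_truth <- lapply(gt, as.vector)
  }
  at
}

#' Write and read photon traces in HDF5
#'
#' Lossless round trip of a [photon_trace()] including metadata and (for
#' simulated traces) the ground-truth group.
#'
#' @param trace a [photon_trace()].
#' @param file HDF5 file path (created if absent).
#' @param name object name under `/traces`.
#' @return `write_h5_trace` returns the file invisibly; `read_h5_trace`
#'   returns the [photon_trace()].
#' @export
write_h5_trace <- function(trace, file, name = "trace") {
  h5_ensure_file(file)
  path <- paste0("/traces/", name)
  h5_ensure_group(file, path)
  rhdf5::h5write(trace$counts, file, paste0(path, "/counts"))
  h5_write_attrs(file, path, stamp(list(bin_dt = trace$bin_dt,
                                        t_start = trace$t_start,
                                        units = "counts")))
  write_user_attrs(file, path, trace$attrs)
  rhdf5::h5closeAll()
  invisible(file)
}

#' @rdname write_h5_trace
#' @export
read_h5_trace <- function(file, name = "trace") {
  path <- paste0("/traces/", name)
  at <- check_version(file, path)
  if (is.null(at$bin_dt)) stop("missing mandatory attribute bin_dt")
  counts <- as.integer(rhdf5::h5read(file, paste0(path, "/counts")))
  photon_trace(counts, as.vector(at$bin_dt), as.vector(at$t_start),
               attrs = read_user_attrs(file, path,
                                       c("bin_dt", "t_start", "units")))
}

#' Write and read RICS image stacks in HDF5
#'
#' @param stack an [image_stack()].
#' @param file HDF5 file path.
#' @param name object name under `/images`.
#' @return The file (write, invisibly) or the [image_stack()] (read).
#' @export
write_h5_stack <- function(stack, file, name = "stack") {
  h5_ensure_file(file)
  path <- paste0("/images/", name)
  h5_ensure_group(file, path)
  rhdf5::h5write(stack$frames, file, paste0(path, "/frames"))
  g <- stack$geometry
  h5_write_attrs(file, path, stamp(list(
    t_pix = g$t_pix, t_line = g$t_line, s_xi = g$s_xi, s_psi = g$s_psi,
    s_zeta = g$s_zeta, alpha = g$alpha, n_cols = g$n_cols,
    n_rows = g$n_rows, units = "counts")))
  write_user_attrs(file, path, stack$attrs)
  rhdf5::h5closeAll()
  invisible(file)
}

#' @rdname write_h5_stack
#' @export
read_h5_stack <- function(file, name = "stack") {
  path <- paste0("/images/", name)
  at <- check_version(file, path)
  need <- c("t_pix", "t_line", "s_xi", "s_psi", "n_cols", "n_rows")
  if (!all(need %in% names(at)))
    stop("missing mandatory scan-geometry attributes")
  fr <- rhdf5::h5read(file, paste0(path, "/frames"))
  geom <- scan_geometry(as.vector(at$t_pix), as.vector(at$t_line),
                        as.vector(at$s_xi), as.vector(at$s_psi),
                        as.vector(at$s_zeta), as.vector(at$alpha),
                        as.vector(at$n_cols), as.vector(at$n_rows))
  image_stack(array(as.integer(fr), dim(fr)), geom,
              attrs = read_user_attrs(file, path, c(need, "s_zeta",
                                                    "alpha", "units")))
}

#' Write and read correlation functions in HDF5
#'
#' Handles both temporal [acf_curve()] objects and spatial [acf_image()]
#' objects; arrays (including per-point uncertainties) round-trip at full
#' precision.
#'
#' @param acf an [acf_curve()] or [acf_image()].
#' @param file HDF5 file path.
#' @param name object name under `/acf`.
#' @return The file (write, invisibly) or the restored object (read).
#' @export
write_h5_acf <- function(acf, file, name = "acf") {
  h5_ensure_file(file)
  path <- paste0("/acf/", name)
  h5_ensure_group(file, path)
  if (inherits(acf, "acf_curve")) {
    rhdf5::h5write(acf$lag, file, paste0(path, "/lag"))
    rhdf5::h5write(acf$g, file, paste0(path, "/g"))
    if ("sigma" %in% names(acf))
      rhdf5::h5write(acf$sigma, file, paste0(path, "/sigma"))
    h5_write_attrs(file, path, stamp(list(
      type = "curve", n_traces = attr(acf, "n_traces") %||% 1L,
      units = "dimensionless")))
    write_user_attrs(file, path, attr(acf, "cs_attrs") %||% list())
  } else if (inherits(acf, "acf_image")) {
    rhdf5::h5write(acf$g, file, paste0(path, "/g"))
    rhdf5::h5write(acf$xi, file, paste0(path, "/xi"))
    rhdf5::h5write(acf$psi, file, paste0(path, "/psi"))
    if (!is.null(acf$sigma))
      rhdf5::h5write(acf$sigma, file, paste0(path, "/sigma"))
    g <- acf$geometry
    h5_write_attrs(file, path, stamp(list(
      type = "image2d", t_pix = g$t_pix, t_line = g$t_line,
      s_xi = g$s_xi, s_psi = g$s_psi, s_zeta = g$s_zeta,
      alpha = g$alpha, n_cols = g$n_cols, n_rows = g$n_rows,
      units = "dimensionless")))
    write_user_attrs(file, path, acf$attrs)
  } else stop("acf must be an acf_curve or acf_image")
  rhdf5::h5closeAll()
  invisible(file)
}

#' @rdname write_h5_acf
#' @export
read_h5_acf <- function(file, name = "acf") {
  path <- paste0("/acf/", name)
  at <- check_version(file, path)
  has_sigma <- h5_exists(file, paste0(path, "/sigma"))
  if (identical(as.vector(at$type), "curve")) {
    acf_curve(as.vector(rhdf5::h5read(file, paste0(path, "/lag"))),
              as.vector(rhdf5::h5read(file, paste0(path, "/g"))),
              sigma = if (has_sigma)
                as.vector(rhdf5::h5read(file, paste0(path, "/sigma"))),
              n_traces = as.vector(at$n_traces),
              attrs = read_user_attrs(file, path, c("type", "n_traces",
                                                    "units")))
  } else if (identical(as.vector(at$type), "image2d")) {
    geom <- scan_geometry(as.vector(at$t_pix), as.vector(at$t_line),
                          as.vector(at$s_xi), as.vector(at$s_psi),
                          as.vector(at$s_zeta), as.vector(at$alpha),
                          as.vector(at$n_cols), as.vector(at$n_rows))
    drop <- c("type", "t_pix", "t_line", "s_xi", "s_psi", "s_zeta",
              "alpha", "n_cols", "n_rows", "units")
    acf_image(as.matrix(rhdf5::h5read(file, paste0(path, "/g"))),
              as.vector(rhdf5::h5read(file, paste0(path, "/xi"))),
              as.vector(rhdf5::h5read(file, paste0(path, "/psi"))),
              geom,
              sigma = if (has_sigma)
                as.matrix(rhdf5::h5read(file, paste0(path, "/sigma"))),
              attrs = read_user_attrs(file, path, drop))
  } else stop("unknown ACF type attribute")
}

#' Write and read fit results in HDF5
#'
#' Persists the estimates, uncertainties, goodness-of-fit metrics,
#' residual transforms and fitted values of a `ccs_fit`.
#'
#' @param fit a `ccs_fit`.
#' @param file HDF5 file path.
#' @param name object name under `/fits`.
#' @return The file (write, invisibly) or a restored `ccs_fit` (read).
#' @export
write_h5_fit <- function(fit, file, name = "fit") {
  h5_ensure_file(file)
  path <- paste0("/fits/", name)
  h5_ensure_group(file, path)
  rhdf5::h5write(unname(fit$theta_hat), file, paste0(path, "/theta"))
  rhdf5::h5write(unname(fit$stderr), file, paste0(path, "/stderr"))
  rhdf5::h5write(fit$fitted, file, paste0(path, "/fitted"))
  for (rn in names(fit$residuals))
    rhdf5::h5write(fit$residuals[[rn]], file,
                   paste0(path, "/residuals_", rn))
  rhdf5::h5write(as.data.frame(fit$points), file, paste0(path, "/points"))
  h5_write_attrs(file, path, stamp(list(
    param_names = names(fit$theta_hat), ssr = fit$ssr, chi2 = fit$chi2,
    chi2_red = fit$chi2_red, n = fit$n, p = fit$p,
    em_mode = fit$em_mode, kind = fit$spec$kind,
    triplet = fit$spec$triplet, axial = fit$spec$axial,
    converged = fit$converged,
    active_bounds = if (length(fit$active_bounds)) fit$active_bounds
                    else "none")))
  rhdf5::h5closeAll()
  invisible(file)
}

#' @rdname write_h5_fit
#' @export
read_h5_fit <- function(file, name = "fit") {
  path <- paste0("/fits/", name)
  at <- check_version(file, path)
  nm <- as.vector(at$param_names)
  res <- list()
  for (rn in c("raw", "standardized", "decorrelated")) {
    p <- paste0(path, "/residuals_", rn)
    if (h5_exists(file, p)) res[[rn]] <- as.vector(rhdf5::h5read(file, p))
  }
  ab <- as.vector(at$active_bounds)
  structure(list(
    theta_hat = setNames(as.vector(rhdf5::h5read(file, paste0(path, "/theta"))), nm),
    stderr = setNames(as.vector(rhdf5::h5read(file, paste0(path, "/stderr"))), nm),
    ssr = as.vector(at$ssr), chi2 = as.vector(at$chi2),
    chi2_red = as.vector(at$chi2_red), n = as.vector(at$n),
    p = as.vector(at$p), residuals = res,
    fitted = as.vector(rhdf5::h5read(file, paste0(path, "/fitted"))),
    points = tibble::as_tibble(rhdf5::h5read(file, paste0(path, "/points"))),
    spec = model_spec(as.vector(at$kind),
                      triplet = as.logical(as.vector(at$triplet)),
                      axial = as.vector(at$axial)),
    em_mode = as.vector(at$em_mode),
    converged = as.logical(as.vector(at$converged)),
    active_bounds = if (identical(ab, "none")) character(0) else ab),
    class = "ccs_fit")
}

#' Write and read PSF models in HDF5
#'
#' @param psf a [psf_grid()] or [gaussian_psf()].
#' @param file HDF5 file path.
#' @param name object name under `/psf`.
#' @return The file (write, invisibly) or the restored PSF (read).
#' @export
write_h5_psf <- function(psf, file, name = "psf") {
  h5_ensure_file(file)
  path <- paste0("/psf/", name)
  h5_ensure_group(file, path)
  if (inherits(psf, "psf_grid")) {
    rhdf5::h5write(psf$values, file, paste0(path, "/values"))
    h5_write_attrs(file, path, stamp(list(type = "grid", voxel = psf$voxel,
                                          origin = psf$origin,
                                          units = "um")))
  } else if (inherits(psf, "gaussian_psf")) {
    h5_write_attrs(file, path, stamp(list(
      type = "gaussian", w_x = psf$w_x, w_y = psf$w_y, w_z = psf$w_z,
      scale = psf$scale, units = "um")))
  } else stop("psf must be a psf_grid or gaussian_psf")
  rhdf5::h5closeAll()
  invisible(file)
}

#' @rdname write_h5_psf
#' @export
read_h5_psf <- function(file, name = "psf") {
  path <- paste0("/psf/", name)
  at <- check_version(file, path)
  if (identical(as.vector(at$type), "grid")) {
    v <- rhdf5::h5read(file, paste0(path, "/values"))
    psf_grid(array(as.numeric(v), dim(v)), as.vector(at$voxel),
             as.vector(at$origin))
  } else {
    gaussian_psf(as.vector(at$w_x), as.vector(at$w_y), as.vector(at$w_z),
                 as.vector(at$scale))
  }
}

#' Read a 3D bead stack from TIFF
#'
#' Loads a multi-page TIFF (one page per z plane) into a [psf_grid()].
#'
#' @param file TIFF path.
#' @param voxel voxel sizes `c(vx, vy, vz)`, um.
#' @return A [psf_grid()].
#' @export
read_psf_tiff <- function(file, voxel) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF bead stacks")
  pages <- tiff::readTIFF(file, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  psf_grid(arr, voxel)
}

#' Export a posterior to NetCDF (ArviZ-style layout)
#'
#' Writes the equal-weight posterior draws as variables
#' `posterior/<parameter>` with `(chain, draw)` dimensions, plus the
#' log-evidence and sampler diagnostics as global attributes, into a
#' NetCDF-4 file readable by ArviZ-compatible tools.
#'
#' @param post a `ccs_posterior`.
#' @param path output `.nc` file path.
#' @return The path, invisibly.
#' @export
export_posterior <- function(post, path) {
  s <- post$samples
  d_draw <- ncdf4::ncdim_def("draw", "", seq_len(nrow(s)))
  d_chain <- ncdf4::ncdim_def("chain", "", 1L)
  vars <- lapply(colnames(s), function(nm)
    ncdf4::ncvar_def(paste0("posterior/", nm), "", list(d_draw, d_chain),
                     prec = "double"))
  nc <- ncdf4::nc_create(path, vars, force_v4 = TRUE)
  on.exit(ncdf4::nc_close(nc))
  for (i in seq_along(vars)) ncdf4::ncvar_put(nc, vars[[i]], s[, i])
  ncdf4::ncatt_put(nc, 0, "log_z", post$log_z)
  ncdf4::ncatt_put(nc, 0, "log_z_err", post$log_z_err)
  ncdf4::ncatt_put(nc, 0, "n_call", post$n_call)
  ncdf4::ncatt_put(nc, 0, "em_mode", post$em_mode)
  ncdf4::ncatt_put(nc, 0, "corrspec_version", .CS_LAYOUT_VERSION)
  invisible(path)
}

#' @rdname export_posterior
#' @param file `.nc` file written by [export_posterior()].
#' @return `read_posterior_nc` returns a list with the draw matrix and the
#'   evidence attributes.
#' @export
read_posterior_nc <- function(file) {
  nc <- ncdf4::nc_open(file)
  on.exit(ncdf4::nc_close(nc))
  nms <- names(nc$var)
  nms <- nms[startsWith(nms, "posterior/")]
  s <- vapply(nms, function(v) as.vector(ncdf4::ncvar_get(nc, v)),
              numeric(nc$dim$draw$len))
  colnames(s) <- sub("^posterior/", "", nms)
  list(samples = s,
       log_z = ncdf4::ncatt_get(nc, 0, "log_z")$value,
       log_z_err = ncdf4::ncatt_get(nc, 0, "log_z_err")$value,
       em_mode = ncdf4::ncatt_get(nc, 0, "em_mode")$value)
}
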