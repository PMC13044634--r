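#' Drop unstable leading traces or frames
#'
#' Intensity-stability screening before correlation: computes a per-item
#' mean intensity series (per-frame means for an image stack, coarse-bin
#' rates for a photon trace, or a numeric series directly), smooths it
#' with a short running mean, and drops the leading items while the
#' running mean deviates from the tail mean (mean of the final half) by
#' more than `frac`.  Alternatively an explicit index list selects items
#' manually.
#'
#' @param x an [image_stack()], [photon_trace()], or numeric vector of
#'   per-item intensities.
#' @param frac maximal tolerated relative deviation from the tail mean
#'   (default 0.1).
#' @param index optional explicit indices of items to keep (overrides the
#'   drift rule).
#' @param n_bins number of coarse bins used to summarize a photon trace.
#' @param smooth running-mean half-width (items) used to suppress shot
#'   noise in the drift rule.
#' @return A list with `keep` (indices of retained items), `report`
#'   (tibble with one row per item: kept or dropped, with reason), and for
#'   traces `window`, the retained time interval in seconds.
#' @export
select_stable <- function(x, frac = 0.1, index = NULL, n_bins = 200,
                          smooth = 2) {
  if (inherits(x, "image_stack")) {
    m <- apply(x$frames, 1, mean)
    item_dt <- NULL
  } else if (inherits(x, "photon_trace")) {
    n_bins <- min(n_bins, length(x$counts))
    grp <- ceiling(seq_along(x$counts) / (length(x$counts) / n_bins))
    m <- as.vector(tapply(x$counts, grp, mean)) / x$bin_dt
    item_dt <- length(x$counts) * x$bin_dt / length(m)
  } else {
    m <- as.numeric(x)
    item_dt <- NULL
  }
  n <- length(m)
  if (n == 0) stop("empty input")
  if (!is.null(index)) {
    keep <- sort(unique(index))
    if (length(keep) == 0 || any(keep < 1 | keep > n))
      stop("invalid manual index list")
    reason <- ifelse(seq_len(n) %in% keep, NA_character_, "manual exclusion")
  } else {
    tail_idx <- seq.int(floor(n / 2) + 1L, n)
    tail_mean <- mean(m[tail_idx])
    if (tail_mean == 0) stop("zero tail intensity")
    r <- vapply(seq_len(n), function(i) {
      j <- max(1L, i - smooth):min(n, i + smooth)
      mean(m[j])
    }, numeric(1))
    # deviation threshold: the stated fraction of the tail mean, floored
    # at 3x the shot-noise scatter of the smoothed tail so that counting
    # noise alone does not trigger exclusions
    thr <- max(frac * tail_mean, 3 * sd(r[tail_idx]))
    bad <- which(abs(r - tail_mean) > thr)
    cut <- if (length(bad)) max(bad[bad <= ceiling(0.9 * n)] , 0) else 0L
    if (cut >= n) stop("everything excluded by the stability rule")
    keep <- seq.int(cut + 1L, n)
    reason <- ifelse(seq_len(n) <= cut,
                     sprintf("running mean deviates > %g%% from tail",
                             100 * frac), NA_character_)
  }
  report <- tibble::tibble(item = seq_len(n), intensity = m,
                           kept = seq_len(n) %in% keep, reason = reason)
  out <- list(keep = keep, report = report,
              n_kept = length(keep), n_dropped = n - length(keep))
  if (!is.null(item_dt))
    out$window <- c((min(keep) - 1) * item_dt, max(keep) * item_dt)
  out
}

#' Diffusion-concentration pre-analysis screening
#'
#' Quick per-item quality screen before the pooled main fit: each ACF is
#' fitted with the simplest compatible model (single-component isotropic,
#' no triplet) by NLS with uniform errors, and items whose apparent DC or
#' C fall outside explicit ranges -- or beyond `k_mad` median absolute
#' deviations of the cohort median when no ranges are given -- are flagged
#' and excluded.  The per-item values are a screening statistic, not final
#' estimates.
#'
#' @param items list of [acf_curve()] or [acf_image()] objects.
#' @param psf PSF used for the quick fits.
#' @param dc_range,c_range optional explicit acceptance ranges
#'   (um^2/s, nM).
#' @param k_mad robust outlier factor used when ranges are absent.
#' @param priors bounds for the quick fits.
#' @return A list with `table` (tibble: item, DC, C, kept, reason),
#'   `kept` (the retained subset of `items`), and `excluded` (indices).
#' @export
preanalyze_dc_c <- function(items, psf, dc_range = NULL, c_range = NULL,
                            k_mad = 5, priors = prior_spec()) {
  if (length(items) < 1) stop("no items to screen")
  spec <- model_spec("iso1", triplet = FALSE)
  fits <- purrr::map(items, function(it) {
    tryCatch(fit_nls(it, spec, psf, em_ols(), priors = priors),
             error = function(e) e)
  })
  failed <- purrr::map_lgl(fits, inherits, "error")
  DC <- purrr::map_dbl(fits, function(f)
    if (inherits(f, "error")) NA_real_ else unname(f$theta_hat["DC"]))
  C <- purrr::map_dbl(fits, function(f)
    if (inherits(f, "error")) NA_real_ else unname(f$theta_hat["C"]))

  reason <- rep(NA_character_, length(items))
  reason[failed] <- paste("fit failed:",
                          purrr::map_chr(fits[failed], conditionMessage))
  in_rng <- function(v, rng, lab, k) {
    bad <- rep(FALSE, length(v))
    if (!is.null(rng)) {
      bad <- !is.na(v) & (v < rng[1] | v > rng[2])
      list(bad = bad, why = sprintf("%s outside [%g, %g]", lab, rng[1], rng[2]))
    } else {
      med <- median(v, na.rm = TRUE)
      s <- mad(v, na.rm = TRUE)
      if (s > 0) bad <- !is.na(v) & abs(v - med) > k * s
      list(bad = bad, why = sprintf("%s beyond %g MAD of cohort median", lab, k))
    }
  }
  rd <- in_rng(DC, dc_range, "DC", k_mad)
  rc <- in_rng(C, c_range, "C", k_mad)
  reason[is.na(reason) & rd$bad] <- rd$why
  reason[is.na(reason) & rc$bad] <- rc$why

  kept <- is.na(reason)
  table <- tibble::tibble(item = seq_along(items), DC = DC, C = C,
                          kept = kept, reason = reason)
  list(table = table, kept = items[kept], excluded = which(!kept))
}
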