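#' Construct a BOLD run object
#'
#' @param signal voxel x time numeric matrix, arbitrary scanner units.
#' @param tr repetition time in seconds.
#' @param run_id run label.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(signal, tr, run_id = "run") {
  signal <- as.matrix(signal)
  if (ncol(signal) < 1L) stop("`signal` must have at least one time point", call. = FALSE)
  if (!is.finite(tr) || tr <= 0) stop("`tr` must be > 0", call. = FALSE)
  if (any(!is.finite(signal))) stop("`signal` contains non-finite values", call. = FALSE)
  structure(list(signal = signal, tr = as.numeric(tr), run_id = run_id),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("bold_run '%s': %d voxels x %d volumes, TR %.3f s\n",
              x$run_id, nrow(x$signal), ncol(x$signal), x$tr))
  invisible(x)
}

## Discrete-cosine drift basis: components k = 1..K sampled at volume
## midpoints; component k has period 2*T*tr/k seconds.
dct_drift_basis <- function(n_vol, tr, cutoff) {
  k_max <- floor(2 * n_vol * tr / cutoff)
  if (k_max < 1L) return(NULL)
  t_idx <- seq_len(n_vol) - 0.5
  sapply(seq_len(k_max), function(k) cos(pi * k * t_idx / n_vol))
}

#' High-pass filter a BOLD run by discrete-cosine drift removal
#'
#' Projects out the low-frequency discrete-cosine components with period
#' longer than `cutoff` seconds, removing scanner drift while preserving the
#' temporal mean and all faster fluctuations.  The projection is idempotent.
#'
#' @param run a [bold_run()].
#' @param cutoff high-pass cutoff period in seconds; must exceed `2 * tr`.
#' @return A filtered `bold_run`.
#' @export
highpass_filter <- function(run, cutoff = 55) {
  stopifnot(inherits(run, "bold_run"))
  if (!is.finite(cutoff) || cutoff <= 2 * run$tr) {
    stop("`cutoff` must exceed twice the TR", call. = FALSE)
  }
  B <- dct_drift_basis(ncol(run$signal), run$tr, cutoff)
  if (is.null(B)) return(run)
  ## DCT columns are mutually orthogonal and zero-mean: project column-wise
  coef <- crossprod(B, t(run$signal)) / colSums(B^2)  # K x voxels
  filtered <- run$signal - t(B %*% coef)
  bold_run(filtered, run$tr, run$run_id)
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard double-gamma BOLD impulse response (positive gamma peaking
#' near 5 s, undershoot gamma peaking near 15 s with 1/6 relative
#' amplitude), sampled at the TR and normalized so the continuous-time peak
#' equals 1.
#'
#' @param tr sampling interval in seconds.
#' @param duration kernel length in seconds.
#' @param peak_delay,undershoot_delay gamma shape parameters (seconds).
#' @param undershoot_ratio relative amplitude of the undershoot.
#' @return Numeric kernel sampled at `0, tr, 2 tr, ...`, with attribute
#'   `tr`.
#' @export
canonical_hrf <- function(tr, duration = 32, peak_delay = 6,
                          undershoot_delay = 16, undershoot_ratio = 1 / 6) {
  if (!is.finite(tr) || tr <= 0) stop("`tr` must be > 0", call. = FALSE)
  shape <- function(t) {
    stats::dgamma(t, shape = peak_delay, rate = 1) -
      undershoot_ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
  }
  peak <- max(shape(seq(0, duration, by = 0.01)))
  t <- seq(0, duration, by = tr)
  structure(shape(t) / peak, tr = tr, class = "hrf_kernel")
}

## Convolve a volume-sampled time course with an HRF kernel, truncated to
## the input length.
convolve_hrf <- function(x, hrf) {
  n <- length(x)
  full <- stats::convolve(x, rev(hrf), type = "open")
  full[seq_len(n)]
}
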