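#' Ground truth for a simulated laminar BOLD subject
#'
#' Bundles the layer-specific neural amplitudes and noise parameters that the
#' forward model in [simulate_subject()] turns into voxel time courses.  The
#' three gray-matter bins are ordered deep, middle, superficial.  Defaults
#' encode the qualitative laminar physiology the analysis is designed to
#' detect: a stimulus-contrast effect peaked in the middle (granular) bin, a
#' broad feature-attention effect with a superficial peak, and an ascending
#' draining-vein bias that inflates superficial amplitudes.
#'
#' Amplitudes are in raw signal units on top of a DC offset of
#' `dc_offset` scanner units, so an amplitude of 1 is a 1% signal change at
#' the default offset of 100.
#'
#' @param attention per-bin attended-vs-unattended amplitude (deep, middle,
#'   superficial), applied to voxels whose preferred orientation is cued.
#' @param contrast per-bin high-vs-low contrast amplitude.
#' @param baseline per-bin stimulus-driven response common to every block.
#' @param drainage_lambda fraction of each bin's neural signal leaked into
#'   every more superficial bin (ascending-vein model).
#' @param superficial_gain multiplicative bin gain, non-decreasing from deep
#'   to superficial (gradient-echo superficial bias).
#' @param noise_sd marginal SD of the AR(1) voxel noise, signal units.
#' @param ar1_rho lag-1 autocorrelation of the voxel noise, in `[0, 1)`.
#' @param drift_sd SD of the per-voxel linear drift slope, signal units per
#'   volume (each voxel draws its own slope).
#' @param dc_offset constant signal level added to every voxel.
#' @param seed integer seed controlling all randomness for the subject.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(attention = c(deep = 0.25, middle = 0.30, superficial = 0.45),
                         contrast = c(deep = 0.40, middle = 0.80, superficial = 0.50),
                         baseline = c(deep = 2.0, middle = 2.0, superficial = 2.0),
                         drainage_lambda = 0.3,
                         superficial_gain = c(deep = 1.0, middle = 1.3, superficial = 1.6),
                         noise_sd = 1.0,
                         ar1_rho = 0.3,
                         drift_sd = 0.01,
                         dc_offset = 100,
                         seed = 1L) {
  as_bin3 <- function(x, name) {
    if (length(x) != 3L || any(!is.finite(x))) {
      stop(sprintf("`%s` must be 3 finite values (deep, middle, superficial)", name),
           call. = FALSE)
    }
    stats::setNames(as.numeric(x), GM_BINS)
  }
  gt <- list(
    attention = as_bin3(attention, "attention"),
    contrast = as_bin3(contrast, "contrast"),
    baseline = as_bin3(baseline, "baseline"),
    drainage_lambda = as.numeric(drainage_lambda),
    superficial_gain = as_bin3(superficial_gain, "superficial_gain"),
    noise_sd = as.numeric(noise_sd),
    ar1_rho = as.numeric(ar1_rho),
    drift_sd = as.numeric(drift_sd),
    dc_offset = as.numeric(dc_offset),
    seed = as.integer(seed)
  )
  if (!is.finite(gt$ar1_rho) || gt$ar1_rho < 0 || gt$ar1_rho >= 1) {
    stop("`ar1_rho` must lie in [0, 1)", call. = FALSE)
  }
  if (gt$noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (gt$drainage_lambda < 0) stop("`drainage_lambda` must be non-negative", call. = FALSE)
  if (is.unsorted(gt$superficial_gain)) {
    stop("`superficial_gain` must be non-decreasing from deep to superficial",
         call. = FALSE)
  }
  structure(gt, class = "ground_truth")
}

#' Simulated 2AFC psychophysical observer
#'
#' A Weibull-psychometric observer for validating the adaptive staircase:
#' the probability of a correct response at stimulus intensity `x` is
#' `guess + (1 - guess - lapse) * (1 - exp(-(x / threshold)^slope))`.
#'
#' @param threshold true discrimination threshold, stimulus units (e.g. bar
#'   width increment in degrees of visual angle).
#' @param slope Weibull slope (unitless), > 0.
#' @param guess guess rate; 0.5 for a two-alternative forced choice.
#' @param lapse lapse rate in `[0, 0.1]`.
#' @param seed integer seed for the observer's response stream.
#' @return An object of class `simulated_observer`.
#' @export
simulated_observer <- function(threshold, slope = 3.5, guess = 0.5,
                               lapse = 0.02, seed = 1L) {
  if (!is.finite(threshold) || threshold <= 0) {
    stop("`threshold` must be positive", call. = FALSE)
  }
  if (!is.finite(slope) || slope <= 0) stop("`slope` must be > 0", call. = FALSE)
  if (guess < 0 || guess >= 1) stop("`guess` must lie in [0, 1)", call. = FALSE)
  if (lapse < 0 || lapse > 0.1) stop("`lapse` must lie in [0, 0.1]", call. = FALSE)
  structure(
    list(threshold = as.numeric(threshold), slope = as.numeric(slope),
         guess = as.numeric(guess), lapse = as.numeric(lapse),
         seed = as.integer(seed)),
    class = "simulated_observer"
  )
}

#' Probability of a correct response for a simulated observer
#'
#' @param observer a [simulated_observer()].
#' @param intensity non-negative stimulus intensity (vectorized).
#' @return Probability of a correct response at each intensity.
#' @export
observer_p_correct <- function(observer, intensity) {
  if (any(intensity < 0)) stop("`intensity` must be non-negative", call. = FALSE)
  observer$guess + (1 - observer$guess - observer$lapse) *
    (1 - exp(-(intensity / observer$threshold)^observer$slope))
}

#' Draw Bernoulli correct/incorrect responses from a simulated observer
#'
#' @inheritParams observer_p_correct
#' @return Logical vector, `TRUE` for a correct response.
#' @export
simulate_response <- function(observer, intensity) {
  p <- observer_p_correct(observer, intensity)
  stats::runif(length(p)) < p
}
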