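## AR(1) noise matrix (n_voxels x n_vol) with marginal SD `sd` and lag-1
## autocorrelation `rho`; stationary initialization.
ar1_noise <- function(n_voxels, n_vol, sd, rho) {
  E <- matrix(0, n_voxels, n_vol)
  if (sd <= 0) return(E)
  E[, 1] <- stats::rnorm(n_voxels, 0, sd)
  innov_sd <- sd * sqrt(1 - rho^2)
  for (t in seq_len(n_vol - 1L) + 1L) {
    E[, t] <- rho * E[, t - 1L] + stats::rnorm(n_voxels, 0, innov_sd)
  }
  E
}

## Hemodynamic bin signals for one voxel population in one run.
## Returns a 5 x n_vol matrix (wm, deep, middle, superficial, csf).
## `amplitude_fn(bin, block_row)` gives the neural amplitude for the
## population in that bin during that block's stimulus volumes.
population_bin_signals <- function(design, gt, hrf, amplitude_fn) {
  n_vol <- attr(design, "n_volumes")
  stim_vol <- attr(design, "stim_volumes")
  neural <- matrix(0, 3L, n_vol, dimnames = list(GM_BINS, NULL))
  for (i in seq_len(nrow(design))) {
    on <- design$onset_volume[i]
    idx <- on:(on + stim_vol - 1L)
    for (b in GM_BINS) {
      neural[b, idx] <- neural[b, idx] + amplitude_fn(b, design[i, , drop = FALSE])
    }
  }
  conv <- t(apply(neural, 1, convolve_hrf, hrf = hrf))

  ## ascending-vein drainage: each bin receives a leak of the summed neural
  ## signal from all deeper bins, then a multiplicative depth gain
  lam <- gt$drainage_lambda
  g <- gt$superficial_gain
  measured <- rbind(
    deep = g[["deep"]] * conv["deep", ],
    middle = g[["middle"]] * (conv["middle", ] + lam * conv["deep", ]),
    superficial = g[["superficial"]] *
      (conv["superficial", ] + lam * (conv["deep", ] + conv["middle", ]))
  )
  rbind(wm = 0.1 * measured["deep", ],
        measured,
        csf = 0.1 * measured["superficial", ])
}

#' Simulate one laminar BOLD subject with known ground truth
#'
#' Forward model: per gray-matter bin and voxel population, the neural
#' amplitude in each block is `baseline + contrast_amplitude` (high-contrast
#' blocks only) `+ attention_amplitude` (only for the population whose
#' preferred orientation is cued).  The block-wise boxcar is convolved with
#' the canonical HRF, an ascending-vein drainage leak and a superficial
#' multiplicative gain are applied across bins, and each voxel's signal is
#' its depth-weight row times the bin signals of its population, on top of a
#' DC offset, a per-voxel linear drift, and AR(1) noise.  The white-matter
#' and CSF bins carry attenuated (factor 0.1) copies of the deepest and most
#' superficial gray-matter signals so that all five weight columns are
#' exercised.  A single-orientation localizer run is generated analogously
#' with alternating clockwise/counter-clockwise blocks; the non-preferred
#' population responds with `cross_orientation_gain` of the preferred
#' response.
#'
#' @param gt a [ground_truth()].
#' @param n_runs main-task runs (default 3).
#' @param n_blocks blocks per main-task run (default 16).
#' @param n_voxels voxels in the simulated region (default 1000).
#' @param tr repetition time in seconds.
#' @param geometry a [slab_geometry()] for the depth weights.
#' @param localizer_blocks stimulus blocks in the localizer run.
#' @param cross_orientation_gain localizer response of the non-preferred
#'   population relative to the preferred one.
#' @return An object of class `subject_dataset`: list with `runs` (list of
#'   [bold_run()]), `designs` (one `block_design` per run), `localizer`,
#'   `localizer_design`, `depth_weights`, `orientation_truth` (per-voxel
#'   `"CW"`/`"CCW"`), and `ground_truth`.
#' @export
simulate_subject <- function(gt, n_runs = 3L, n_blocks = 16L, n_voxels = 1000L,
                             tr = 3.408, geometry = slab_geometry(),
                             localizer_blocks = 16L,
                             cross_orientation_gain = 0.3) {
  stopifnot(inherits(gt, "ground_truth"))
  stop_if_not_scalar_count(n_runs, "n_runs")
  stop_if_not_scalar_count(n_voxels, "n_voxels")

  weights <- make_depth_weights(n_voxels, geometry, seed = gt$seed)
  W <- unclass(weights)[, , drop = FALSE]
  hrf <- canonical_hrf(tr)

  with_seed_(gt$seed, {
    orientation_truth <- sample(rep(c("CW", "CCW"), length.out = n_voxels))
    is_cw <- orientation_truth == "CW"

    make_voxel_run <- function(design, run_id, amp_fn_for) {
      n_vol <- attr(design, "n_volumes")
      bins_cw <- population_bin_signals(design, gt, hrf, amp_fn_for("CW"))
      bins_ccw <- population_bin_signals(design, gt, hrf, amp_fn_for("CCW"))
      Y <- matrix(gt$dc_offset, n_voxels, n_vol)
      Y[is_cw, ] <- Y[is_cw, ] + W[is_cw, , drop = FALSE] %*% bins_cw
      Y[!is_cw, ] <- Y[!is_cw, ] + W[!is_cw, , drop = FALSE] %*% bins_ccw
      trend <- seq_len(n_vol) - (n_vol + 1) / 2
      slopes <- stats::rnorm(n_voxels, 0, gt$drift_sd)
      Y <- Y + outer(slopes, trend) + ar1_noise(n_voxels, n_vol, gt$noise_sd, gt$ar1_rho)
      bold_run(Y, tr, run_id)
    }

    main_amp <- function(pop) {
      function(bin, block) {
        gt$baseline[[bin]] +
          gt$contrast[[bin]] * (block$contrast == "high") +
          gt$attention[[bin]] * (block$attended == pop)
      }
    }
    loc_amp <- function(pop) {
      function(bin, block) {
        full <- gt$baseline[[bin]] + gt$contrast[[bin]]
        if (block$condition == pop) full else cross_orientation_gain * full
      }
    }

    designs <- lapply(seq_len(n_runs), function(r) {
      build_block_design(n_blocks, seed = gt$seed + 7919L * r, tr = tr)
    })
    runs <- lapply(seq_len(n_runs), function(r) {
      make_voxel_run(designs[[r]], sprintf("run%02d", r), main_amp)
    })
    localizer_design <- build_localizer_design(localizer_blocks, tr = tr)
    localizer <- make_voxel_run(localizer_design, "localizer", loc_amp)

    structure(
      list(runs = runs, designs = designs,
           localizer = localizer, localizer_design = localizer_design,
           depth_weights = weights, orientation_truth = orientation_truth,
           ground_truth = gt),
      class = "subject_dataset"
    )
  })
}

#' Per-subject ground truths for a simulated cohort
#'
#' Derives one [ground_truth()] per subject from a cohort-level ground
#' truth: each subject's per-bin attention and contrast amplitudes receive
#' independent additive Gaussian jitter (`subject_sd`), modelling
#' between-subject variability in effect size and laminar profile, and each
#' subject gets a seed derived from the master seed by a fixed offset.
#'
#' @param n_subjects number of subjects (default 24).
#' @param gt cohort-level [ground_truth()]; its `seed` is the master seed.
#' @param subject_sd SD of the between-subject amplitude jitter,
#'   signal units.
#' @return List of `ground_truth` objects, one per subject.
#' @export
cohort_ground_truths <- function(n_subjects = 24L, gt = ground_truth(),
                                 subject_sd = 0.15) {
  stop_if_not_scalar_count(n_subjects, "n_subjects")
  with_seed_(gt$seed, {
    lapply(seq_len(n_subjects), function(i) {
      g <- gt
      g$attention <- g$attention + stats::rnorm(3, 0, subject_sd)
      g$contrast <- g$contrast + stats::rnorm(3, 0, subject_sd)
      g$seed <- gt$seed + 1000L * i
      g
    })
  })
}

#' Simulate a multi-subject laminar BOLD cohort
#'
#' @inheritParams cohort_ground_truths
#' @param ... passed to [simulate_subject()] (run counts, voxel counts,
#'   geometry, ...).
#' @return List of `subject_dataset` objects.
#' @export
simulate_cohort <- function(n_subjects = 24L, gt = ground_truth(),
                            subject_sd = 0.15, ...) {
  gts <- cohort_ground_truths(n_subjects, gt, subject_sd)
  lapply(gts, simulate_subject, ...)
}
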