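#' Split layer time courses into per-block segments
#'
#' Each block contributes one segment of 10 volumes: the five stimulus
#' volumes followed by the five inter-block-interval volumes, aligned to the
#' attention-cue onset volume.
#'
#' @param layers a `layer_timecourses` (any number of bin rows).
#' @param design the `block_design` of the same run.
#' @return A list of `block_segment` objects, each with elements `values`
#'   (bin x 10 matrix), `condition`, `attended`, `contrast`, `block` and
#'   `run_id`.
#' @export
segment_blocks <- function(layers, design) {
  stopifnot(inherits(layers, "layer_timecourses"), inherits(design, "block_design"))
  n_vol <- ncol(layers)
  seg_len <- attr(design, "block_volumes")
  lapply(seq_len(nrow(design)), function(i) {
    on <- design$onset_volume[i]
    if (on + seg_len - 1L > n_vol) {
      stop(sprintf("block %d is truncated: needs volumes %d-%d of %d",
                   i, on, on + seg_len - 1L, n_vol), call. = FALSE)
    }
    structure(
      list(values = unclass(layers)[, on:(on + seg_len - 1L), drop = FALSE],
           condition = design$condition[i],
           attended = if ("attended" %in% names(design)) design$attended[i] else NA_character_,
           contrast = if ("contrast" %in% names(design)) design$contrast[i] else NA_character_,
           block = design$block[i],
           run_id = attr(layers, "run_id")),
      class = "block_segment"
    )
  })
}

segment_mean <- function(segments) {
  if (!length(segments)) stop("no segments to average", call. = FALSE)
  Reduce(`+`, lapply(segments, `[[`, "values")) / length(segments)
}

#' Attended and unattended mean block time courses per depth bin
#'
#' The attended time course averages, for every block, the segments from
#' the voxel population that preferred the cued orientation (clockwise
#' preferring in attend-clockwise blocks and vice versa); the unattended
#' time course uses the crossed pairing.  Each block contributes exactly one
#' segment to each average.
#'
#' @param cw_segments segments from the clockwise-preferring population
#'   ([segment_blocks()]), possibly pooled over runs.
#' @param ccw_segments matching segments from the counter-clockwise
#'   population.
#' @return List with `attended` and `unattended` bin x 10 matrices and
#'   their `difference`.
#' @export
condition_average_attention <- function(cw_segments, ccw_segments) {
  if (!length(cw_segments) || !length(ccw_segments)) {
    stop("both voxel populations are required", call. = FALSE)
  }
  att_of <- function(segs) vapply(segs, `[[`, character(1), "attended")
  attended <- c(cw_segments[att_of(cw_segments) == "CW"],
                ccw_segments[att_of(ccw_segments) == "CCW"])
  unattended <- c(cw_segments[att_of(cw_segments) == "CCW"],
                  ccw_segments[att_of(ccw_segments) == "CW"])
  if (!length(attended) || !length(unattended)) {
    stop("design must contain both attend-CW and attend-CCW blocks", call. = FALSE)
  }
  att <- segment_mean(attended)
  unatt <- segment_mean(unattended)
  list(attended = att, unattended = unatt, difference = att - unatt)
}

#' High- and low-contrast mean block time courses per depth bin
#'
#' Averages across all high-contrast and all low-contrast blocks, pooling
#' both voxel populations regardless of orientation preference.
#'
#' @inheritParams condition_average_attention
#' @return List with `high` and `low` bin x 10 matrices and their
#'   `difference`.
#' @export
condition_average_contrast <- function(cw_segments, ccw_segments) {
  if (!length(cw_segments) || !length(ccw_segments)) {
    stop("both voxel populations are required", call. = FALSE)
  }
  segs <- c(cw_segments, ccw_segments)
  con <- vapply(segs, `[[`, character(1), "contrast")
  if (!any(con == "high") || !any(con == "low")) {
    stop("design must contain both high- and low-contrast blocks", call. = FALSE)
  }
  high <- segment_mean(segs[con == "high"])
  low <- segment_mean(segs[con == "low"])
  list(high = high, low = low, difference = high - low)
}

#' Mean condition effect over the peak of the block response
#'
#' Averages a difference time course over the volumes covering the peak of
#' the stimulus-driven response: segment volumes 3-6 (1-based), i.e.
#' onset-relative times 6.8, 10.2, 13.6 and 17.0 s at TR 3.408 s.
#'
#' @param diff_timecourse bin x 10 matrix of condition differences.
#' @param peak_window 1-based volume indices of the peak window.
#' @return Named per-bin effect vector.
#' @export
peak_window_effect <- function(diff_timecourse, peak_window = 3:6) {
  if (ncol(diff_timecourse) != 10L) {
    stop("expected 10-volume block segments", call. = FALSE)
  }
  if (any(peak_window < 1L) || any(peak_window > 10L)) {
    stop("`peak_window` must index segment volumes 1-10", call. = FALSE)
  }
  rowMeans(diff_timecourse[, peak_window, drop = FALSE])
}

#' Agranular-granular score of a laminar effect profile
#'
#' Averages the effect from the deep and superficial gray-matter bins
#' (agranular cortex) and subtracts the middle bin (granular cortex).  A
#' positive score indicates a mostly agranular effect; negative indicates a
#' granular effect.
#'
#' @param effect_by_bin numeric length-3 vector (deep, middle, superficial).
#' @return Scalar score.
#' @export
ag_score <- function(effect_by_bin) {
  if (length(effect_by_bin) != 3L || any(!is.finite(effect_by_bin))) {
    stop("`effect_by_bin` must be 3 finite values (deep, middle, superficial)",
         call. = FALSE)
  }
  (effect_by_bin[[1]] + effect_by_bin[[3]]) / 2 - effect_by_bin[[2]]
}
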