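#' Select visually active voxels by a voxelwise z threshold
#'
#' Converts the all-stimuli-vs-baseline contrast t statistics to z scores
#' and keeps voxels exceeding the threshold.  A plain voxelwise threshold is
#' used (no cluster-level correction), so under pure noise about
#' `pnorm(z, lower.tail = FALSE)` of voxels survive.
#'
#' @param localizer_fit a [fit_glm()] result containing the contrast.
#' @param z_threshold voxelwise z threshold (default 2.3).
#' @param contrast name of the activity contrast in the fit.
#' @return Integer vector of selected voxel ids (row indices).  An empty
#'   selection triggers a warning and returns `integer(0)`.
#' @export
select_active_voxels <- function(localizer_fit, z_threshold = 2.3,
                                 contrast = "active") {
  stopifnot(inherits(localizer_fit, "glm_fit"))
  tv <- localizer_fit$t_values
  if (is.null(tv) || !(contrast %in% colnames(tv))) {
    stop(sprintf("fit does not contain contrast '%s'", contrast), call. = FALSE)
  }
  z <- t_to_z(tv[, contrast], localizer_fit$dof)
  ids <- which(z > z_threshold)
  if (!length(ids)) {
    warning("no voxels exceed the activity threshold; returning an empty mask",
            call. = FALSE)
  }
  as.integer(ids)
}

#' Select orientation-preference voxel masks from a localizer contrast
#'
#' Among active voxels, the `n_per_pref` voxels with the most positive
#' orientation-contrast t values form the clockwise-preferring mask and the
#' `n_per_pref` most negative form the counter-clockwise mask.  Only voxels
#' whose t has the matching sign qualify; if fewer than `n_per_pref`
#' qualify, all qualifying voxels are taken.  Ties are broken by ascending
#' voxel id, making the selection invariant to input ordering.
#'
#' @param fit a [fit_glm()] result containing the orientation contrast
#'   (positive = clockwise preference).
#' @param active integer vector of active voxel ids ([select_active_voxels()]).
#' @param n_per_pref maximum voxels per preference (default 500).
#' @param contrast name of the orientation contrast in the fit.
#' @return An object of class `orientation_masks`: a data frame with
#'   columns `voxel_id`, `preference` (`"CW"`/`"CCW"`) and `t`.
#' @export
select_orientation_masks <- function(fit, active, n_per_pref = 500L,
                                     contrast = "orientation") {
  stopifnot(inherits(fit, "glm_fit"))
  if (length(n_per_pref) != 1L || !is.finite(n_per_pref) || n_per_pref < 1) {
    stop("`n_per_pref` must be a positive count", call. = FALSE)
  }
  tv <- fit$t_values
  if (is.null(tv) || !(contrast %in% colnames(tv))) {
    stop(sprintf("fit does not contain contrast '%s'", contrast), call. = FALSE)
  }
  active <- sort(unique(as.integer(active)))
  t_act <- tv[active, contrast]

  take <- function(ids, t, n) {
    ## order by descending |t|, ties by ascending voxel id
    ord <- order(-t, ids)
    ord[seq_len(min(n, length(ord)))]
  }
  cw_pool <- t_act > 0
  ccw_pool <- t_act < 0
  cw_sel <- take(active[cw_pool], t_act[cw_pool], n_per_pref)
  ccw_sel <- take(active[ccw_pool], -t_act[ccw_pool], n_per_pref)

  pref_df <- function(ids, t, label) {
    data.frame(voxel_id = ids, preference = rep(label, length(ids)), t = t,
               stringsAsFactors = FALSE)
  }
  masks <- rbind(
    pref_df(active[cw_pool][cw_sel], t_act[cw_pool][cw_sel], "CW"),
    pref_df(active[ccw_pool][ccw_sel], t_act[ccw_pool][ccw_sel], "CCW")
  )
  masks <- masks[order(masks$preference, masks$voxel_id), , drop = FALSE]
  rownames(masks) <- NULL
  structure(masks, n_per_pref = as.integer(n_per_pref),
            class = c("orientation_masks", "data.frame"))
}
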