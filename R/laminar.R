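#' Unmix voxel time courses into depth-bin time courses
#'
#' Solves, independently at every time point, the least-squares problem
#' `min_L || W L - Y ||^2`, where `W` is the voxel x 5 depth-weight matrix
#' and `Y` the voxel x time signal matrix.  The solution row for each bin is
#' the representative time course of the voxel population at that cortical
#' depth.  A condition-number guard rejects degenerate weight matrices
#' (e.g. all voxels sharing one weight profile).
#'
#' @param weights a [make_depth_weights()] matrix (or any voxel x 5
#'   non-negative matrix with rows summing to 1) aligned with the run's
#'   voxels.
#' @param run a [bold_run()] with matching voxel count.
#' @param max_condition condition-number threshold above which the weight
#'   matrix is rejected as rank deficient.
#' @return An object of class `layer_timecourses`: a 5 x time matrix with
#'   rows `wm, deep, middle, superficial, csf`, plus `tr`, `run_id` and
#'   `normalized` attributes.
#' @export
layer_regression <- function(weights, run, max_condition = 1e8) {
  stopifnot(inherits(run, "bold_run"))
  W <- unclass(weights)[, , drop = FALSE]
  if (ncol(W) != 5L) stop("`weights` must have 5 depth-bin columns", call. = FALSE)
  if (nrow(W) != nrow(run$signal)) {
    stop("`weights` rows must align with the run's voxels", call. = FALSE)
  }
  sv <- svd(W, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > max_condition) {
    stop(sprintf(
      "depth-weight matrix is rank deficient over this voxel population (condition number %.3g)",
      if (sv[length(sv)] > 0) sv[1] / sv[length(sv)] else Inf), call. = FALSE)
  }
  L <- solve(crossprod(W), crossprod(W, run$signal))
  rownames(L) <- ALL_BINS
  structure(L, tr = run$tr, run_id = run$run_id, normalized = FALSE,
            class = c("layer_timecourses", "matrix", "array"))
}

#' Extract the gray-matter bin rows of a layer time-course matrix
#'
#' @param layers a `layer_timecourses` object.
#' @return The 3 x time matrix of deep, middle and superficial rows,
#'   retaining class and attributes.
#' @export
gm_layers <- function(layers) {
  stopifnot(inherits(layers, "layer_timecourses"))
  out <- unclass(layers)[GM_BINS, , drop = FALSE]
  structure(out, tr = attr(layers, "tr"), run_id = attr(layers, "run_id"),
            normalized = attr(layers, "normalized"),
            class = class(layers))
}

#' Z-score layer time courses within layers and within a run
#'
#' Standardizes each depth-bin time course to mean 0 and SD 1 over the full
#' run, across all experimental conditions.  This removes the overall
#' amplitude and variance differences between depths (notably the
#' superficial draining-vein bias) while preserving within-layer differences
#' between conditions.
#'
#' @param layers a `layer_timecourses` object (raw).
#' @return The normalized `layer_timecourses` (attribute
#'   `normalized = TRUE`).
#' @export
znormalize_layers <- function(layers) {
  stopifnot(inherits(layers, "layer_timecourses"))
  M <- unclass(layers)
  mu <- rowMeans(M)
  sd <- apply(M, 1, stats::sd)
  if (any(sd <= .Machine$double.eps * 100)) {
    bad <- rownames(M)[sd <= .Machine$double.eps * 100]
    stop(sprintf("zero-variance depth bin(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  Z <- (M - mu) / sd
  structure(Z, tr = attr(layers, "tr"), run_id = attr(layers, "run_id"),
            normalized = TRUE,
            class = c("layer_timecourses", "matrix", "array"))
}
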