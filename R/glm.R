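#' Build an HRF-convolved design matrix from a block design
#'
#' One regressor per condition: a boxcar spanning each block's stimulus
#' volumes, convolved with the hemodynamic response kernel and truncated to
#' the run length.  The intercept and a linear trend are added as nuisance
#' columns at fit time, not here.
#'
#' @param design a `block_design`.
#' @param tr repetition time in seconds; defaults to the design's TR.
#' @param hrf HRF kernel from [canonical_hrf()].
#' @return An object of class `design_matrix`: a time x condition matrix
#'   with condition labels as column names and `tr` as attribute.
#' @export
build_design_matrix <- function(design, tr = attr(design, "tr"),
                                hrf = canonical_hrf(tr)) {
  stopifnot(inherits(design, "block_design"))
  n_vol <- attr(design, "n_volumes")
  stim_vol <- attr(design, "stim_volumes")
  labels <- sort(unique(design$condition))
  if (any(design$onset_volume + stim_vol - 1L > n_vol)) {
    stop("block onset beyond run length", call. = FALSE)
  }
  X <- matrix(0, nrow = n_vol, ncol = length(labels),
              dimnames = list(NULL, labels))
  for (lab in labels) {
    box <- numeric(n_vol)
    for (on in design$onset_volume[design$condition == lab]) {
      box[on:(on + stim_vol - 1L)] <- 1
    }
    X[, lab] <- convolve_hrf(box, hrf)
  }
  structure(X, tr = tr, condition_labels = labels,
            class = c("design_matrix", "matrix", "array"))
}

#' Fit a voxelwise temporal GLM with condition regressors and contrasts
#'
#' Ordinary least squares per voxel on the condition regressors plus an
#' intercept and a centered linear trend as nuisance terms.  Contrast t
#' statistics use `t = c'b / sqrt(s2 * c'(X'X)^-1 c)`.
#'
#' @param run a [bold_run()].
#' @param design a `design_matrix`.
#' @param contrasts named list of weight vectors over the condition columns
#'   (nuisance columns receive zero weight automatically).
#' @return An object of class `glm_fit` with elements `betas` (voxel x
#'   regressor), `residual_variance`, `dof`, `t_values` (voxel x contrast),
#'   `design_info` (regressor peak heights, condition labels).
#' @export
fit_glm <- function(run, design, contrasts = list()) {
  stopifnot(inherits(run, "bold_run"), inherits(design, "design_matrix"))
  Y <- run$signal
  n_vol <- ncol(Y)
  if (nrow(design) != n_vol) {
    stop("design matrix and run disagree on the number of volumes", call. = FALSE)
  }
  labels <- attr(design, "condition_labels")
  trend <- seq_len(n_vol) - (n_vol + 1) / 2
  X <- cbind(unclass(design), intercept = 1, trend = trend)
  p <- ncol(X)
  if (n_vol <= p + 1L) stop("too few time points for the design", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank deficient", call. = FALSE)

  betas <- t(qr.coef(qrX, t(Y)))                      # voxel x regressor
  fitted <- betas %*% t(X)
  res <- Y - fitted
  dof <- n_vol - p
  s2 <- rowSums(res^2) / dof
  XtXinv <- solve(crossprod(X))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))

  t_values <- NULL
  if (length(contrasts)) {
    t_values <- matrix(NA_real_, nrow = nrow(Y), ncol = length(contrasts),
                       dimnames = list(NULL, names(contrasts)))
    for (i in seq_along(contrasts)) {
      cv <- contrasts[[i]]
      if (length(cv) != length(labels)) {
        stop("contrast length must match the number of conditions", call. = FALSE)
      }
      cf <- c(cv, 0, 0)  # zero weight on intercept and trend
      num <- drop(betas %*% cf)
      den <- sqrt(s2 * drop(t(cf) %*% XtXinv %*% cf))
      t_values[, i] <- num / den
    }
  }

  structure(
    list(betas = betas, residual_variance = s2, dof = dof,
         t_values = t_values,
         design_info = list(condition_labels = labels,
                            regressor_peak = apply(unclass(design), 2, max),
                            XtXinv = XtXinv)),
    class = "glm_fit"
  )
}

#' Percent signal change from a GLM beta
#'
#' Scales the beta by the peak height of its (HRF-convolved) regressor and
#' expresses it relative to the voxel's baseline signal level, as a
#' percentage.
#'
#' @param beta GLM coefficient(s), signal units.
#' @param baseline_mean baseline signal level (> 0), typically the fitted
#'   intercept.
#' @param regressor_peak peak height of the condition regressor.
#' @return Percent signal change.
#' @export
percent_signal_change <- function(beta, baseline_mean, regressor_peak = 1) {
  if (any(!is.finite(baseline_mean)) || any(baseline_mean <= 0)) {
    stop("`baseline_mean` must be positive", call. = FALSE)
  }
  100 * beta * regressor_peak / baseline_mean
}

#' Convert t statistics to z scores by matching tail probabilities
#'
#' @param t t statistics.
#' @param dof degrees of freedom.
#' @return z scores with the same cumulative tail probability.
#' @export
t_to_z <- function(t, dof) {
  z <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  z[pos] <- stats::qnorm(stats::pt(t[pos], dof, lower.tail = FALSE, log.p = TRUE),
                         lower.tail = FALSE, log.p = TRUE)
  z[!pos] <- -stats::qnorm(stats::pt(-t[!pos], dof, lower.tail = FALSE, log.p = TRUE),
                           lower.tail = FALSE, log.p = TRUE)
  z[is.na(t)] <- NA_real_
  z
}
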