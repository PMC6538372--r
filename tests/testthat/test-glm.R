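test_that("design-matrix columns equal a direct convolution oracle", {
  d <- build_block_design(16L, seed = 4L)
  hrf <- canonical_hrf(3.408)
  X <- build_design_matrix(d)
  n_vol <- attr(d, "n_volumes")
  untruncated_sums <- numeric(4)
  for (i in seq_along(attr(X, "condition_labels"))) {
    lab <- attr(X, "condition_labels")[i]
    box <- numeric(n_vol)
    for (on in d$onset_volume[d$condition == lab]) box[on:(on + 4L)] <- 1
    expect_equal(unclass(X)[, lab], direct_convolve(box, as.numeric(hrf)),
                 tolerance = 1e-9, ignore_attr = TRUE)
    ## full (untruncated) response mass is identical across conditions
    untruncated_sums[i] <- sum(box) * sum(hrf)
  }
  expect_equal(max(untruncated_sums) - min(untruncated_sums), 0, tolerance = 1e-9)
})

test_that("single-block columns have causal support and superpose linearly", {
  make_design <- function(onsets, conds) {
    structure(
      data.frame(block = seq_along(onsets), condition = conds,
                 onset_volume = onsets, onset = (onsets - 1) * 2,
                 duration = 5 * 2),
      tr = 2, n_dummy = 0L, block_volumes = 10L, stim_volumes = 5L,
      n_volumes = 80L, class = c("block_design", "data.frame"))
  }
  hrf <- canonical_hrf(2)
  one <- build_design_matrix(make_design(11L, "A"), hrf = hrf)
  expect_true(all(abs(one[1:10, "A"]) < 1e-12))
  expect_gt(max(abs(one[11:80, "A"])), 0.5)

  a <- build_design_matrix(make_design(c(11L, 51L), c("A", "A")), hrf = hrf)
  b1 <- build_design_matrix(make_design(11L, "A"), hrf = hrf)
  b2 <- build_design_matrix(make_design(51L, "A"), hrf = hrf)
  expect_equal(unclass(a)[, "A"], unclass(b1)[, "A"] + unclass(b2)[, "A"],
               tolerance = 1e-9)
  expect_error(build_design_matrix(make_design(79L, "A"), hrf = hrf),
               "beyond run length")
})

test_that("noiseless data are fit exactly", {
  d <- build_block_design(8L, seed = 1L, tr = 2)
  X <- build_design_matrix(d)
  y <- 2 * unclass(X)[, 1] + 5
  fit <- fit_glm(bold_run(matrix(y, 1), 2), X)
  expect_equal(unname(fit$betas[1, 1]), 2, tolerance = 1e-10)
  expect_equal(unname(fit$betas[1, "intercept"]), 5, tolerance = 1e-10)
  expect_lt(fit$residual_variance[1], 1e-20)
  expect_equal(fit$dof, attr(d, "n_volumes") - 6L)
})

test_that("betas and t values match explicit normal-equation arithmetic", {
  d <- build_block_design(8L, seed = 3L, tr = 2)
  X <- build_design_matrix(d)
  n_vol <- nrow(X)
  Y <- withr::with_seed(9L, matrix(rnorm(20 * n_vol), 20))
  cvec <- c(1, -1, 0, 0)
  fit <- fit_glm(bold_run(Y, 2), X, contrasts = list(AvB = cvec))

  Xf <- cbind(unclass(X), 1, seq_len(n_vol) - (n_vol + 1) / 2)
  XtXinv <- solve(t(Xf) %*% Xf)
  B <- XtXinv %*% t(Xf) %*% t(Y)
  expect_equal(unname(fit$betas), unname(t(B)), tolerance = 1e-8)

  cf <- c(cvec, 0, 0)
  res <- t(Y) - Xf %*% B
  s2 <- colSums(res^2) / (n_vol - 6)
  t_oracle <- drop(t(cf) %*% B) / sqrt(s2 * drop(t(cf) %*% XtXinv %*% cf))
  expect_equal(unname(fit$t_values[, "AvB"]), unname(t_oracle), tolerance = 1e-10)
})

test_that("contrast t values are centered under pure noise", {
  d <- build_block_design(8L, seed = 5L, tr = 2)
  X <- build_design_matrix(d)
  Y <- withr::with_seed(13L, matrix(rnorm(1000 * nrow(X)), 1000))
  fit <- fit_glm(bold_run(Y, 2), X, contrasts = list(AvB = c(1, -1, 0, 0)))
  expect_lt(abs(mean(fit$t_values[, "AvB"])), 0.1)
})

test_that("rank-deficient designs are rejected", {
  d <- build_block_design(8L, seed = 1L, tr = 2)
  X <- build_design_matrix(d)
  X2 <- unclass(X)
  X2[, 2] <- X2[, 1]
  Xbad <- structure(X2, tr = 2, condition_labels = attr(X, "condition_labels"),
                    class = class(X))
  run <- bold_run(matrix(rnorm(nrow(X)), 1), 2)
  expect_error(fit_glm(run, Xbad), "rank deficient")
})

test_that("percent signal change scales beta by regressor peak over baseline", {
  expect_equal(percent_signal_change(1, 100), 1)
  expect_equal(percent_signal_change(0, 50), 0)
  expect_equal(percent_signal_change(2.5, 50, regressor_peak = 1), 5)
  expect_equal(percent_signal_change(2, 100, regressor_peak = 1.2), 2.4)
  expect_error(percent_signal_change(1, 0), "positive")
})
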