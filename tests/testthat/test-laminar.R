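test_that("identity depth weights return the voxel time courses themselves", {
  W <- diag(5)
  colnames(W) <- c("wm", "deep", "middle", "superficial", "csf")
  Y <- withr::with_seed(1, matrix(rnorm(5 * 30), 5))
  L <- layer_regression(W, bold_run(Y, 2))
  expect_equal(unclass(L), Y, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("unmixing matches the pseudo-inverse oracle and re-mixes exactly", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      W <- matrix(runif(60 * 5), 60)
      W <- W / rowSums(W)
      colnames(W) <- c("wm", "deep", "middle", "superficial", "csf")
      L_true <- matrix(rnorm(5 * 40), 5)
      Y <- W %*% L_true
      L <- layer_regression(W, bold_run(Y, 2))
      ## pseudo-inverse via SVD, an independent route
      s <- svd(W)
      L_pinv <- s$v %*% diag(1 / s$d) %*% t(s$u) %*% Y
      expect_equal(unclass(L), L_pinv, ignore_attr = TRUE, tolerance = 1e-8)
      expect_equal(unclass(L), L_true, ignore_attr = TRUE, tolerance = 1e-8)
      expect_equal(W %*% unclass(L), Y, tolerance = 1e-8)
    })
  }
})

test_that("degenerate weight matrices are rejected with a diagnostic", {
  W <- matrix(rep(c(0.1, 0.2, 0.4, 0.2, 0.1), each = 20), 20)
  colnames(W) <- c("wm", "deep", "middle", "superficial", "csf")
  run <- bold_run(matrix(rnorm(20 * 10), 20), 2)
  expect_error(layer_regression(W, run), "rank deficient")
})

test_that("z normalization standardizes layers and is affine-invariant", {
  subj <- quick_subject()
  L <- gm_layers(layer_regression(subj$depth_weights, subj$runs[[1]]))
  Z <- znormalize_layers(L)
  expect_equal(unname(rowMeans(Z)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(unclass(Z), 1, sd)), rep(1, 3), tolerance = 1e-9)
  expect_true(attr(Z, "normalized"))

  ## two layers differing only by scale and offset normalize identically
  M <- unclass(L)
  M[2, ] <- 3 * M[1, ] + 10
  L2 <- structure(M, tr = attr(L, "tr"), run_id = attr(L, "run_id"),
                  normalized = FALSE, class = class(L))
  Z2 <- znormalize_layers(L2)
  expect_equal(unclass(Z2)[2, ], unclass(Z2)[1, ], tolerance = 1e-9)

  flat <- structure(matrix(1, 3, 10, dimnames = list(rownames(M)[1:3], NULL)),
                    tr = 2, run_id = "r", normalized = FALSE, class = class(L))
  expect_error(znormalize_layers(flat), "zero-variance")
})

test_that("normalization equalizes bin SDs but keeps condition-effect ordering", {
  ## noiseless subject with a strong superficial bias via drainage + gain
  gt <- ground_truth(noise_sd = 0, ar1_rho = 0, drift_sd = 0, seed = 17L)
  subj <- simulate_subject(gt, n_runs = 1L, n_blocks = 8L, n_voxels = 120L,
                           localizer_blocks = 4L)
  raw <- gm_layers(layer_regression(subj$depth_weights, subj$runs[[1]]))
  ## raw SDs carry the superficial amplitude gradient
  raw_sd <- apply(unclass(raw), 1, sd)
  expect_gt(raw_sd[["superficial"]], raw_sd[["deep"]])
  Z <- znormalize_layers(raw)
  segs_raw <- segment_blocks(raw, subj$designs[[1]])
  segs_z <- segment_blocks(Z, subj$designs[[1]])
  con_raw <- condition_average_contrast(segs_raw, segs_raw)$difference
  con_z <- condition_average_contrast(segs_z, segs_z)$difference
  eff_raw <- peak_window_effect(con_raw)
  eff_z <- peak_window_effect(con_z)
  ## the sign of each bin's contrast effect survives normalization
  expect_equal(sign(eff_z), sign(eff_raw))
})
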