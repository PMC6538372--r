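## Independent oracles used to freeze expected values.

## Monte-Carlo integration of per-bin tissue volume for the slab geometry
## underlying a depth_weights object (same boundary field, independent
## integration route: random point classification instead of interval
## overlap).  Returns expected per-bin volume in voxel units.
mc_bin_volumes <- function(weights, n_points = 4e5, seed = 99L) {
  geom <- attr(weights, "geometry")
  phases <- attr(weights, "phases")
  vs <- geom$voxel_size
  x <- attr(weights, "x"); y <- attr(weights, "y"); z <- attr(weights, "z")
  n_vox <- nrow(weights)
  withr::with_seed(seed, {
    pick <- sample.int(n_vox, n_points, replace = TRUE)
    px <- x[pick] + runif(n_points) * vs
    py <- y[pick] + runif(n_points) * vs
    pz <- z[pick] + runif(n_points) * vs
    zw <- geom$wm_margin + geom$wobble_amplitude *
      sin(2 * pi * px / geom$wobble_wavelength + phases[1]) *
      cos(2 * pi * py / geom$wobble_wavelength + phases[2])
    t3 <- geom$gm_thickness / 3
    depth <- pz - zw
    bin <- cut(depth, c(-Inf, 0, t3, 2 * t3, 3 * t3, Inf),
               labels = c("wm", "deep", "middle", "superficial", "csf"))
    counts <- table(bin)
    as.numeric(counts) / n_points * n_vox
  })
}

## Classical cell-mean one-way repeated-measures ANOVA with Box (GG) epsilon
## from the eigenvalues of the double-centered covariance matrix, and the
## Huynh-Feldt correction of it.  A different computational route from the
## package's orthonormal-contrast projection.
oneway_rm_oracle <- function(cells) {
  n <- nrow(cells); k <- ncol(cells)
  grand <- mean(cells)
  cond_means <- colMeans(cells)
  subj_means <- rowMeans(cells)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_total <- sum((cells - grand)^2)
  ss_err <- ss_total - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fv <- (ss_cond / df1) / (ss_err / df2)
  S <- cov(cells)
  C <- diag(k) - 1 / k
  lam <- eigen(C %*% S %*% C, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam) * 1e-12]
  gg <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  hf <- min(1, (n * (k - 1) * gg - 2) / ((k - 1) * (n - 1 - (k - 1) * gg)))
  list(ss_effect = ss_cond, ss_error = ss_err, F = Fv,
       eps_gg = gg, eps_hf = hf,
       p_gg = pf(Fv, df1 * gg, df2 * gg, lower.tail = FALSE))
}

## Direct (time-domain loop) convolution of a boxcar with a kernel,
## truncated to length n.
direct_convolve <- function(x, h) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (j in seq_along(h)) {
      src <- t - j + 1L
      if (src >= 1L) out[t] <- out[t] + x[src] * h[j]
    }
  }
  out
}

## Batch QUEST posterior: prior times the product of trial likelihoods,
## computed in one pass (oracle for sequential updating).
batch_posterior <- function(state0, intensities, responses) {
  p_grid <- function(x) {
    state0$guess + (1 - state0$guess - state0$lapse) *
      (1 - exp(-(abs(x) / exp(state0$log_grid))^state0$slope))
  }
  post <- state0$posterior
  lik <- rep(1, length(post))
  for (i in seq_along(intensities)) {
    p <- p_grid(intensities[i])
    lik <- lik * if (responses[i]) p else 1 - p
  }
  post <- post * lik
  post / sum(post)
}

## Reference Weibull psychometric (scalar arithmetic, mirrors the model
## definition rather than package internals).
weibull_p_ref <- function(x, threshold, slope, guess, lapse) {
  guess + (1 - guess - lapse) * (1 - exp(-(x / threshold)^slope))
}

## Bin-level forward-model oracle: computes the attended-unattended and
## high-low peak-window effects per gray-matter bin directly from the model
## equations (boxcars, direct time-domain convolution, drainage algebra,
## block bookkeeping), with no voxels, unmixing, or segmentation code.
bin_effects_oracle <- function(gt, design, tr, peak_window = 3:6) {
  n_vol <- attr(design, "n_volumes")
  stim <- attr(design, "stim_volumes")
  hrf <- as.numeric(canonical_hrf(tr))
  bins <- c("deep", "middle", "superficial")
  bin_signals <- function(pop) {
    M <- t(sapply(bins, function(b) {
      box <- numeric(n_vol)
      for (i in seq_len(nrow(design))) {
        amp <- gt$baseline[[b]] +
          gt$contrast[[b]] * (design$contrast[i] == "high") +
          gt$attention[[b]] * (design$attended[i] == pop)
        idx <- design$onset_volume[i]:(design$onset_volume[i] + stim - 1L)
        box[idx] <- box[idx] + amp
      }
      direct_convolve(box, hrf)
    }))
    lam <- gt$drainage_lambda
    g <- gt$superficial_gain
    rbind(deep = g[[1]] * M[1, ],
          middle = g[[2]] * (M[2, ] + lam * M[1, ]),
          superficial = g[[3]] * (M[3, ] + lam * (M[1, ] + M[2, ])))
  }
  Mcw <- bin_signals("CW")
  Mccw <- bin_signals("CCW")
  seg <- function(M, i) M[, design$onset_volume[i] + 0:9, drop = FALSE]
  att <- unatt <- hi <- lo <- 0
  nh <- nl <- 0L
  for (i in seq_len(nrow(design))) {
    scw <- seg(Mcw, i); sccw <- seg(Mccw, i)
    if (design$attended[i] == "CW") {
      att <- att + scw; unatt <- unatt + sccw
    } else {
      att <- att + sccw; unatt <- unatt + scw
    }
    if (design$contrast[i] == "high") {
      hi <- hi + scw + sccw; nh <- nh + 2L
    } else {
      lo <- lo + scw + sccw; nl <- nl + 2L
    }
  }
  n <- nrow(design)
  list(
    attention = rowMeans(((att - unatt) / n)[, peak_window, drop = FALSE]),
    contrast = rowMeans((hi / nh - lo / nl)[, peak_window, drop = FALSE])
  )
}
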