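test_that("identical cells give F = 0 and two-level effects have epsilon 1", {
  cells <- matrix(rep(rnorm(6), 4), 6, 4) + 5
  res <- rm_anova(cells, within = c(cond = 4L))
  expect_equal(res$F, 0, tolerance = 1e-12)

  cells2 <- withr::with_seed(1, matrix(rnorm(12 * 2), 12, 2))
  res2 <- rm_anova(cells2, within = c(cond = 2L))
  expect_identical(res2$eps_gg, 1)
  expect_identical(res2$eps_hf, 1)
  expect_equal(res2$df1, 1L)
})

test_that("one-way results match the classical cell-mean and Box-eigenvalue oracle", {
  cells <- withr::with_seed(42, matrix(rnorm(6 * 3, sd = 2), 6, 3) +
                              outer(rnorm(6), rep(1, 3)) +
                              outer(rep(1, 6), c(0, 1, 3)))
  res <- rm_anova(cells, within = c(cond = 3L), epsilon = "greenhouse-geisser")
  oracle <- oneway_rm_oracle(cells)
  expect_equal(res$ss_effect, oracle$ss_effect, tolerance = 1e-10)
  expect_equal(res$ss_error, oracle$ss_error, tolerance = 1e-10)
  expect_equal(res$F, oracle$F, tolerance = 1e-10)
  expect_equal(res$eps_gg, oracle$eps_gg, tolerance = 1e-10)
  expect_equal(res$eps_hf, oracle$eps_hf, tolerance = 1e-10)
  expect_equal(res$p, oracle$p_gg, tolerance = 1e-10)
})

test_that("factorial F statistics match stats::aov and epsilons match car", {
  set.seed(7)
  n <- 10L
  cells <- matrix(rnorm(n * 12), n, 12)  # A(2) x B(3) x C(2), A slowest
  res <- rm_anova(cells, within = c(A = 2L, B = 3L, C = 2L))

  grid <- expand.grid(C = 1:2, B = 1:3, A = 1:2)[, c("A", "B", "C")]
  long <- data.frame(
    subject = factor(rep(seq_len(n), times = 12)),
    A = factor(grid$A[rep(1:12, each = n)]),
    B = factor(grid$B[rep(1:12, each = n)]),
    C = factor(grid$C[rep(1:12, each = n)]),
    value = as.vector(cells)
  )
  fit <- stats::aov(value ~ A * B * C + Error(subject / (A * B * C)), data = long)
  sm <- summary(fit)
  for (ef in c("A", "B", "C", "A:B", "A:C", "B:C", "A:B:C")) {
    stratum <- sm[[paste0("Error: subject:", ef)]][[1]]
    F_aov <- stratum[trimws(rownames(stratum)) == ef, "F value"]
    expect_equal(res$F[res$effect == ef], F_aov, tolerance = 1e-8,
                 label = paste("F for", ef))
  }

  skip_if_not_installed("car")
  idata <- data.frame(A = factor(grid$A), B = factor(grid$B), C = factor(grid$C))
  mlm <- stats::lm(cells ~ 1)
  ca <- suppressWarnings(
    summary(car::Anova(mlm, idata = idata, idesign = ~ A * B * C, type = 3),
            multivariate = FALSE))
  sph <- ca$sphericity.tests
  for (ef in rownames(sph)) {
    expect_equal(res$eps_gg[res$effect == ef], unname(ca$pval.adjustments[ef, "GG eps"]),
                 tolerance = 1e-8, label = paste("GG eps for", ef))
    expect_equal(min(1, res$eps_hf[res$effect == ef]),
                 min(1, unname(ca$pval.adjustments[ef, "HF eps"])),
                 tolerance = 1e-8, label = paste("HF eps for", ef))
  }
})

test_that("sums of squares are conserved and epsilon bounds hold", {
  for (seed in 1:8) {
    cells <- withr::with_seed(seed, matrix(rnorm(8 * 6), 8, 6) %*%
                                diag(runif(6, 0.5, 2)))
    res <- rm_anova(cells, within = c(A = 2L, B = 3L))
    expect_equal(attr(res, "ss_subject") + sum(res$ss_effect + res$ss_error),
                 attr(res, "ss_total"), tolerance = 1e-9)
    for (i in seq_len(nrow(res))) {
      d <- res$df1[i]
      expect_gte(res$eps_hf[i], res$eps_gg[i] - 1e-12)
      expect_gte(res$eps_gg[i], 1 / d - 1e-12)
      expect_lte(res$eps_gg[i], 1)
      expect_lte(res$eps_hf[i], 1)
    }
  }
})

test_that("long-format input reshapes to the same answer as the cell matrix", {
  n <- 6L
  cells <- withr::with_seed(3, matrix(rnorm(n * 6), n, 6))
  long <- data.frame(
    subject = rep(seq_len(n), times = 6),
    mod = rep(c("attention", "contrast"), each = 3 * n),
    depth = rep(rep(c("a_deep", "b_mid", "c_sup"), each = n), 2),
    value = as.vector(cells)
  )
  r1 <- rm_anova(long, within = c("mod", "depth"))
  r2 <- rm_anova(cells, within = c(mod = 2L, depth = 3L))
  expect_equal(r1$F, r2$F, tolerance = 1e-12)
  expect_equal(r1$eps_hf, r2$eps_hf, tolerance = 1e-12)
  ## incomplete designs are rejected
  expect_error(rm_anova(long[-1, ], within = c("mod", "depth")), "incomplete")
})

test_that("paired t handles toy vectors and degenerate differences", {
  x <- c(1.2, 2.3, 3.1, 4.8, 5.0)
  y <- c(1.0, 2.0, 3.5, 4.0, 4.2)
  res <- paired_t(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(abs(t_manual), 4, lower.tail = FALSE), tolerance = 1e-12)

  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(paired_t(x + 1, x), "unbounded")
  expect_error(paired_t(1, 2), "equal length")
})

test_that("within-subject SE removes offset variance and matches hand arithmetic", {
  ## identical condition profiles, subject offsets only
  base <- c(1, 4, 2, 6)
  cells <- rbind(base, base + 3, base - 2, base + 10)
  expect_equal(unname(within_subject_se(cells)), rep(0, 4), tolerance = 1e-12)

  ## two subjects, two conditions: hand computation
  cells2 <- rbind(c(1, 3), c(2, 8))
  ## normalized scores: subject means 2 and 5, grand mean 3.5
  norm <- cells2 - c(2, 5) + 3.5
  se_hand <- apply(norm, 2, sd) / sqrt(2) * sqrt(2 / 1)
  expect_equal(unname(within_subject_se(cells2)), unname(se_hand), tolerance = 1e-12)

  ## adding a constant to one subject's cells changes nothing
  cells3 <- cells2
  cells3[1, ] <- cells3[1, ] + 7
  expect_equal(within_subject_se(cells3), within_subject_se(cells2), tolerance = 1e-12)
  expect_error(within_subject_se(cells2[, 1, drop = FALSE]), "2 conditions")
})
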