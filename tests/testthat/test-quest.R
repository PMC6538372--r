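test_that("the prior is a normalized Gaussian centered on the starting estimate", {
  st <- quest_init(prior_mean = 0.024, prior_sd = 0.5)
  expect_equal(sum(st$posterior), 1, tolerance = 1e-9)
  expect_equal(exp(st$log_grid[which.max(st$posterior)]), 0.024, tolerance = 1e-3)
  ## scanner staircases start at the measured threshold plus 20%
  measured <- 0.02
  st2 <- quest_init(prior_mean = measured * 1.2)
  expect_equal(exp(st2$log_grid[which.max(st2$posterior)]), 0.024, tolerance = 1e-3)
  expect_error(quest_init(0.02, target_p = 0.4), "strictly between")
  expect_error(quest_init(0.02, target_p = 0.99), "strictly between")
})

test_that("updates keep the posterior normalized and match the batch oracle", {
  st0 <- quest_init(0.02)
  trials <- withr::with_seed(5L, {
    obs <- simulated_observer(0.02, seed = 5L)
    x <- exp(rnorm(40, log(0.02), 0.4))
    list(x = x, r = as.logical(simulate_response(obs, x)))
  })
  st <- st0
  for (i in seq_along(trials$x)) {
    st <- quest_update(st, trials$x[i], trials$r[i])
    expect_equal(sum(st$posterior), 1, tolerance = 1e-9)
  }
  expect_equal(st$posterior, batch_posterior(st0, trials$x, trials$r),
               tolerance = 1e-9)

  ## permuting trial order yields the same final posterior
  perm <- withr::with_seed(9L, sample(seq_along(trials$x)))
  st_perm <- st0
  for (i in perm) st_perm <- quest_update(st_perm, trials$x[i], trials$r[i])
  expect_equal(st_perm$posterior, st$posterior, tolerance = 1e-9)

  ## a very easy trial is nearly uninformative
  st_easy <- quest_update(st0, 10, TRUE)
  expect_lt(max(abs(st_easy$posterior - st0$posterior)), 1e-3)
})

test_that("the recommendation maps the posterior mean to the target accuracy", {
  st <- quest_init(0.02, slope = 3.5, guess = 0.5, lapse = 0.02, target_p = 0.8)
  x <- quest_recommend(st)
  ## symmetric prior: posterior-mean threshold is the prior mean
  expect_equal(quest_threshold(st), 0.02, tolerance = 1e-9)
  p_at_x <- weibull_p_ref(x, quest_threshold(st), 3.5, 0.5, 0.02)
  expect_equal(p_at_x, 0.8, tolerance = 1e-9)
})

test_that("a long session tracks the observer and stabilizes", {
  obs <- simulated_observer(threshold = 0.02, seed = 31L)
  st <- quest_init(prior_mean = 0.02 * 1.2, prior_sd = 0.5)
  sess <- run_simulated_session(obs, st, n_trials = 2000L)
  ## threshold recovery within 5%
  expect_lt(abs(sess$threshold / obs$threshold - 1), 0.05)
  ## recommendations settle: successive changes < 1% over the last 50 trials
  tail_est <- sess$history$posterior_mean[1951:2000]
  expect_lt(max(abs(diff(tail_est)) / tail_est[-1]), 0.01)
  ## per-block sign balancing of the width increments
  signs <- sign(sess$history$intensity)
  blocks <- matrix(signs, nrow = 8)
  expect_true(all(colSums(blocks) == 0))
  ## fixed seed reproduces the full history
  sess2 <- run_simulated_session(obs, quest_init(0.02 * 1.2, 0.5), 2000L)
  expect_identical(sess$history, sess2$history)
})

test_that("a narrower prior yields recommendations closer to the observer's target intensity", {
  obs <- simulated_observer(threshold = 0.02, lapse = 0, seed = 12L)
  f_star <- (0.8 - 0.5) / (1 - 0.5)
  target_x <- obs$threshold * (-log(1 - f_star))^(1 / 3.5)
  rec_error <- function(n_trials) {
    st <- quest_init(0.03, prior_sd = 0.8, lapse = 0)
    sess <- run_simulated_session(obs, st, n_trials)
    abs(abs(sess$history$intensity[n_trials]) - target_x) / target_x
  }
  expect_lt(rec_error(600L), rec_error(8L))
})
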