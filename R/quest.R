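## Weibull psychometric: probability correct at intensity x for threshold T.
weibull_p <- function(x, threshold, slope, guess, lapse) {
  guess + (1 - guess - lapse) * (1 - exp(-(x / threshold)^slope))
}

#' Initialize a QUEST adaptive staircase
#'
#' Places a Gaussian prior over log threshold on a finite grid.  The
#' psychometric model is a Weibull function of stimulus intensity with fixed
#' slope, guess and lapse rates; only the threshold is estimated.  In the
#' scanner protocol the staircase is started at the previously measured
#' threshold plus a 20% increment; pass that value as `prior_mean`.
#'
#' @param prior_mean prior threshold guess, stimulus units.
#' @param prior_sd SD of the Gaussian prior on the natural-log threshold.
#' @param slope Weibull slope.
#' @param guess guess rate (0.5 for 2AFC).
#' @param lapse lapse rate.
#' @param target_p criterion accuracy the staircase targets; must lie
#'   strictly between `guess` and `1 - lapse`.
#' @param grid_halfwidth half-width of the log-threshold grid in prior SDs.
#' @param grain grid spacing in log units.
#' @return An object of class `quest_state` with the grid, normalized
#'   posterior, psychometric shape, and an empty trial history.
#' @export
quest_init <- function(prior_mean, prior_sd = 0.5, slope = 3.5, guess = 0.5,
                       lapse = 0.02, target_p = 0.8, grid_halfwidth = 5,
                       grain = 0.01) {
  if (!is.finite(prior_mean) || prior_mean <= 0) {
    stop("`prior_mean` must be positive", call. = FALSE)
  }
  if (!is.finite(prior_sd) || prior_sd <= 0) stop("`prior_sd` must be > 0", call. = FALSE)
  if (target_p <= guess || target_p >= 1 - lapse) {
    stop("`target_p` must lie strictly between `guess` and `1 - lapse`", call. = FALSE)
  }
  mu <- log(prior_mean)
  log_grid <- seq(mu - grid_halfwidth * prior_sd, mu + grid_halfwidth * prior_sd,
                  by = grain)
  prior <- stats::dnorm(log_grid, mu, prior_sd)
  structure(
    list(log_grid = log_grid, posterior = prior / sum(prior),
         slope = slope, guess = guess, lapse = lapse, target_p = target_p,
         history = data.frame(intensity = numeric(0), response = logical(0))),
    class = "quest_state"
  )
}

#' Update the QUEST posterior with one trial
#'
#' Multiplies the posterior by the likelihood of the observed response under
#' the Weibull psychometric at the tested intensity, for every candidate
#' threshold on the grid, and renormalizes.
#'
#' @param state a `quest_state`.
#' @param intensity tested stimulus intensity (its magnitude drives the
#'   psychometric; a signed increment is recorded as given).
#' @param response `TRUE` for a correct response.
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, intensity, response) {
  stopifnot(inherits(state, "quest_state"))
  p <- weibull_p(abs(intensity), exp(state$log_grid), state$slope,
                 state$guess, state$lapse)
  lik <- if (isTRUE(response)) p else 1 - p
  post <- state$posterior * lik
  total <- sum(post)
  if (total <= 0) stop("degenerate posterior after update", call. = FALSE)
  state$posterior <- post / total
  state$history <- rbind(state$history,
                         data.frame(intensity = intensity, response = response))
  state
}

#' Posterior-mean threshold estimate of a QUEST state
#'
#' @param state a `quest_state`.
#' @return Threshold estimate, stimulus units (exp of the posterior mean of
#'   the log threshold).
#' @export
quest_threshold <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  exp(sum(state$posterior * state$log_grid))
}

#' Recommend the next stimulus intensity
#'
#' Places the next trial at the intensity where the psychometric function of
#' the posterior-mean threshold predicts the target accuracy.
#'
#' @param state a `quest_state`.
#' @return Recommended intensity, stimulus units.
#' @export
quest_recommend <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  f_star <- (state$target_p - state$guess) / (1 - state$guess - state$lapse)
  quest_threshold(state) * (-log(1 - f_star))^(1 / state$slope)
}

#' Run a simulated QUEST session against a synthetic observer
#'
#' Loops recommend -> respond -> update for `n_trials` trials.  Mirroring
#' the task protocol, the sign of the width increment is balanced within
#' blocks of `block_size` trials (half positive, half negative, in seeded
#' random order); the observer's performance depends only on the increment
#' magnitude.
#'
#' @param observer a [simulated_observer()].
#' @param state an initialized `quest_state`.
#' @param n_trials number of trials (>= 1).
#' @param block_size trials per sign-balancing block (even).
#' @return List with `history` (data frame: trial, intensity, response,
#'   posterior-mean threshold after the trial), `threshold` (final
#'   posterior-mean estimate), `prop_correct`, and the final `state`.
#' @export
run_simulated_session <- function(observer, state, n_trials, block_size = 8L) {
  stopifnot(inherits(observer, "simulated_observer"), inherits(state, "quest_state"))
  stop_if_not_scalar_count(n_trials, "n_trials")
  if (block_size %% 2L != 0L) stop("`block_size` must be even", call. = FALSE)
  with_seed_(observer$seed, {
    intensities <- numeric(n_trials)
    responses <- logical(n_trials)
    estimates <- numeric(n_trials)
    signs <- integer(0)
    for (i in seq_len(n_trials)) {
      if (!length(signs)) {
        signs <- sample(rep(c(1L, -1L), block_size / 2L))
      }
      s <- signs[1L]
      signs <- signs[-1L]
      x <- quest_recommend(state)
      r <- simulate_response(observer, x)
      state <- quest_update(state, s * x, r)
      intensities[i] <- s * x
      responses[i] <- r
      estimates[i] <- quest_threshold(state)
    }
    list(
      history = data.frame(trial = seq_len(n_trials), intensity = intensities,
                           response = responses, posterior_mean = estimates),
      threshold = quest_threshold(state),
      prop_correct = mean(responses),
      state = state
    )
  })
}
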