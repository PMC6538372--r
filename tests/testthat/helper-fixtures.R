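## Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## A small noisy subject: 150 voxels, 2 runs of 8 blocks.
quick_subject <- function() {
  cached("quick_subject", {
    gt <- ground_truth(seed = 11L)
    simulate_subject(gt, n_runs = 2L, n_blocks = 8L, n_voxels = 150L,
                     localizer_blocks = 8L)
  })
}

## A noiseless, drainage-free subject for exact-recovery checks.
noiseless_gt <- function(seed = 5L,
                         attention = c(0.25, 0.30, 0.45),
                         contrast = c(0.40, 0.80, 0.50)) {
  ground_truth(attention = attention, contrast = contrast,
               drainage_lambda = 0, superficial_gain = c(1, 1, 1),
               noise_sd = 0, ar1_rho = 0, drift_sd = 0, seed = seed)
}

noiseless_subject <- function() {
  cached("noiseless_subject", {
    simulate_subject(noiseless_gt(), n_runs = 1L, n_blocks = 8L,
                     n_voxels = 120L, localizer_blocks = 8L)
  })
}

## Small config matched to the quick subject.
quick_config <- function(...) {
  pipeline_config(n_subjects = 4L, n_runs = 2L, n_blocks = 8L,
                  n_voxels = 150L, n_per_pref = 75L, ...)
}

## Build a fake glm_fit carrying given contrast t values (for mask tests).
fake_fit <- function(t_values, dof = 100L) {
  structure(list(betas = NULL, residual_variance = NULL, dof = dof,
                 t_values = t_values, design_info = NULL),
            class = "glm_fit")
}
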