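#' Build a balanced randomized block design for the main attention task
#'
#' Four conditions cross attended orientation (clockwise/counter-clockwise)
#' with stimulus contrast (high/low).  Each block occupies 10 volumes: the
#' attention cue plus stimulus block span 5 volumes, followed by 5 volumes
#' of inter-block interval.  Three dummy volumes are prepended to the run
#' timeline for signal stabilization.  The design is balanced: exactly
#' `n_blocks / 4` blocks per condition, in a seeded random order.
#'
#' @param n_blocks number of blocks; must be divisible by 4.
#' @param seed integer seed for the condition permutation.
#' @param tr repetition time in seconds.
#' @param n_dummy dummy volumes prepended to the run.
#' @param block_volumes volumes per block (stimulus + interval).
#' @param stim_volumes volumes spanned by cue + stimulus block.
#' @return An object of class `block_design`: a data frame with one row per
#'   block (`block`, `condition`, `attended`, `contrast`, `onset_volume`
#'   (1-based first volume of the block), `onset` and `duration` in
#'   seconds), with `tr`, `n_dummy` and `n_volumes` attributes.
#' @export
build_block_design <- function(n_blocks = 16L, seed = 1L, tr = 3.408,
                               n_dummy = 3L, block_volumes = 10L,
                               stim_volumes = 5L) {
  stop_if_not_scalar_count(n_blocks, "n_blocks")
  if (n_blocks %% 4L != 0L) {
    stop("`n_blocks` must be divisible by 4 for a balanced design", call. = FALSE)
  }
  conditions <- rep(CONDITION_LABELS, each = n_blocks / 4L)
  order <- with_seed_(seed, sample.int(n_blocks))
  conditions <- conditions[order]
  onset_volume <- n_dummy + (seq_len(n_blocks) - 1L) * block_volumes + 1L
  design <- data.frame(
    block = seq_len(n_blocks),
    condition = conditions,
    attended = ifelse(grepl("^attCW", conditions), "CW", "CCW"),
    contrast = ifelse(grepl("_hi$", conditions), "high", "low"),
    onset_volume = onset_volume,
    onset = (onset_volume - 1L) * tr,
    duration = stim_volumes * tr,
    stringsAsFactors = FALSE
  )
  structure(design,
            tr = tr, n_dummy = as.integer(n_dummy),
            block_volumes = as.integer(block_volumes),
            stim_volumes = as.integer(stim_volumes),
            n_volumes = as.integer(n_dummy + n_blocks * block_volumes),
            class = c("block_design", "data.frame"))
}

#' Build the orientation-localizer block design
#'
#' Stimulus blocks alternate between clockwise and counter-clockwise
#' orientations, each lasting `stim_volumes` volumes and separated by rest
#' blocks of the same length; dummy volumes are prepended.  With the default
#' 16 stimulus blocks of 4 volumes and TR 3.408 s the run lasts 446.4 s.
#'
#' @param n_blocks number of stimulus blocks (rest blocks are implicit).
#' @param tr repetition time in seconds.
#' @param n_dummy dummy volumes prepended to the run.
#' @param stim_volumes volumes per stimulus (and per rest) block.
#' @param first_orientation orientation of the first block.
#' @return A `block_design` whose `condition` column is `"CW"`/`"CCW"`.
#' @export
build_localizer_design <- function(n_blocks = 16L, tr = 3.408, n_dummy = 3L,
                                   stim_volumes = 4L,
                                   first_orientation = c("CW", "CCW")) {
  stop_if_not_scalar_count(n_blocks, "n_blocks")
  first_orientation <- match.arg(first_orientation)
  ori <- rep(c(first_orientation, setdiff(c("CW", "CCW"), first_orientation)),
             length.out = n_blocks)
  cycle <- 2L * stim_volumes  # stimulus block + rest block
  onset_volume <- n_dummy + (seq_len(n_blocks) - 1L) * cycle + 1L
  design <- data.frame(
    block = seq_len(n_blocks),
    condition = ori,
    onset_volume = onset_volume,
    onset = (onset_volume - 1L) * tr,
    duration = stim_volumes * tr,
    stringsAsFactors = FALSE
  )
  structure(design,
            tr = tr, n_dummy = as.integer(n_dummy),
            block_volumes = as.integer(cycle),
            stim_volumes = as.integer(stim_volumes),
            n_volumes = as.integer(n_dummy + n_blocks * cycle),
            class = c("block_design", "data.frame"))
}

#' Total run duration implied by a block design
#'
#' All stimulus and interval durations are expressed in whole volumes, as in
#' a scanner-synchronized protocol, so the run duration is simply the total
#' volume count times TR.  The main task (3 dummies + 16 blocks of 10
#' volumes at TR 3.408 s) gives 555.5 s; the localizer (3 dummies + 16
#' stimulus/rest cycles of 8 volumes) gives 446.4 s.
#'
#' @param n_blocks number of blocks.
#' @param block_volumes whole volumes per block (stimulus + interval).
#' @param tr repetition time in seconds.
#' @param n_dummy dummy volumes at the start of the run.
#' @return Run duration in seconds.
#' @export
compute_run_duration <- function(n_blocks, block_volumes = 10L, tr = 3.408,
                                 n_dummy = 3L) {
  for (nm in c("block_volumes", "n_dummy")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != as.integer(v)) {
      stop(sprintf("`%s` must be a whole number of volumes", nm), call. = FALSE)
    }
  }
  if (length(n_blocks) != 1L || !is.finite(n_blocks) || n_blocks < 0 ||
      n_blocks != as.integer(n_blocks)) {
    stop("`n_blocks` must be a whole number", call. = FALSE)
  }
  (n_dummy + n_blocks * block_volumes) * tr
}
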