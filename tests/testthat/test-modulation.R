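make_layers <- function(M, tr = 3.408, run_id = "r") {
  structure(M, tr = tr, run_id = run_id, normalized = FALSE,
            class = c("layer_timecourses", "matrix", "array"))
}

## segments with a constant value per block, tagged with design conditions
constant_segments <- function(design, value_fn) {
  lapply(seq_len(nrow(design)), function(i) {
    structure(
      list(values = matrix(value_fn(design[i, , drop = FALSE]), 3, 10,
                           dimnames = list(c("deep", "middle", "superficial"), NULL)),
           condition = design$condition[i], attended = design$attended[i],
           contrast = design$contrast[i], block = design$block[i], run_id = "r"),
      class = "block_segment")
  })
}

test_that("a 16-block run splits into 16 aligned 10-volume segments", {
  d <- build_block_design(16L, seed = 6L)
  M <- make_layers(matrix(seq_len(3 * 163), 3))
  segs <- segment_blocks(M, d)
  expect_length(segs, 16L)
  for (i in seq_along(segs)) {
    expect_equal(ncol(segs[[i]]$values), 10L)
    ## segment i starts at dummy offset + 10 * (i - 1) volumes
    expect_equal(segs[[i]]$values[1, 1], M[1, 3 + 10 * (i - 1) + 1])
  }
  ## constant input gives constant segments
  segs_const <- segment_blocks(make_layers(matrix(2, 3, 163)), d)
  expect_true(all(vapply(segs_const, function(s) all(s$values == 2), logical(1))))
  ## truncated final block is rejected
  expect_error(segment_blocks(make_layers(matrix(0, 3, 100)), d), "truncated")
})

test_that("attended/unattended averaging pairs populations with the cue", {
  d <- build_block_design(8L, seed = 2L)
  cw <- constant_segments(d, function(b) as.numeric(b$attended == "CW"))
  ccw <- constant_segments(d, function(b) as.numeric(b$attended == "CCW"))
  avg <- condition_average_attention(cw, ccw)
  expect_true(all(avg$attended == 1))
  expect_true(all(avg$unattended == 0))

  ## identical signals in both populations: no attention effect
  same <- constant_segments(d, function(b) 3)
  null_avg <- condition_average_attention(same, same)
  expect_equal(null_avg$difference, matrix(0, 3, 10), ignore_attr = TRUE)

  ## swapping CW/CCW labels everywhere leaves the attention effect unchanged
  relabel <- function(segs) lapply(segs, function(s) {
    s$attended <- c(CW = "CCW", CCW = "CW")[[s$attended]]
    s
  })
  swapped <- condition_average_attention(relabel(ccw), relabel(cw))
  expect_equal(swapped$difference, avg$difference)
})

test_that("contrast averaging pools populations and subtracts levels", {
  d <- build_block_design(8L, seed = 3L)
  cw <- constant_segments(d, function(b) ifelse(b$contrast == "high", 2, 1))
  ccw <- constant_segments(d, function(b) ifelse(b$contrast == "high", 2, 1))
  avg <- condition_average_contrast(cw, ccw)
  expect_true(all(avg$difference == 1))
  same <- constant_segments(d, function(b) 5)
  expect_true(all(condition_average_contrast(same, same)$difference == 0))
})

test_that("peak-window effect averages segment volumes 3-6", {
  diff <- matrix(rep(c(0, 0, 1, 2, 2, 1, 0, 0, 0, 0), each = 3), 3, 10, byrow = FALSE)
  expect_equal(unname(peak_window_effect(diff)), rep(1.5, 3))
  expect_equal(unname(peak_window_effect(matrix(1, 3, 10))), rep(1, 3))
  expect_equal(unname(peak_window_effect(matrix(0, 3, 10))), rep(0, 3))
  expect_error(peak_window_effect(matrix(0, 3, 8)), "10-volume")
  ## window volumes 3-6 sit at 6.8/10.2/13.6/17.0 s after cue onset
  expect_equal(round(((3:6) - 1) * 3.408, 1), c(6.8, 10.2, 13.6, 17.0))
})

test_that("agranular-granular score is (deep+superficial)/2 - middle and linear", {
  expect_equal(ag_score(c(0, 0, 0)), 0)
  expect_equal(ag_score(c(1, 3, 1)), -2)
  expect_equal(ag_score(c(2, 1, 4)), 2)
  expect_error(ag_score(c(1, NA, 2)), "finite")
  for (i in 1:10) {
    xy <- withr::with_seed(i, list(x = rnorm(3), y = rnorm(3)))
    expect_equal(ag_score(xy$x + xy$y), ag_score(xy$x) + ag_score(xy$y),
                 tolerance = 1e-12)
    expect_equal(ag_score(rep(xy$x[1], 3)), 0, tolerance = 1e-12)
  }
})
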