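#' Write a BOLD run as a 4D NIfTI volume
#'
#' Voxels are stored along the first axis (n x 1 x 1 x time) with the TR in
#' the temporal pixel dimension, which round-trips through any NIfTI-aware
#' tool while keeping the package's flat voxel indexing.
#'
#' @param run a [bold_run()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_bold_run <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  arr <- array(run$signal, dim = c(nrow(run$signal), 1L, 1L, ncol(run$signal)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, run$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a BOLD run from a 4D NIfTI volume
#'
#' @param path NIfTI file written by [write_bold_run()] (or any 4D volume;
#'   voxels are flattened in array order).
#' @param run_id run label to attach.
#' @return A [bold_run()].
#' @export
read_bold_run <- function(path, run_id = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D NIfTI volume", call. = FALSE)
  tr <- RNifti::pixdim(img)[4]
  signal <- matrix(as.numeric(img), nrow = prod(d[1:3]), ncol = d[4])
  bold_run(signal, tr, run_id)
}

#' Write a block design as a BIDS-style events table
#'
#' Columns `onset` (s), `duration` (s), `trial_type`; tab-separated.
#'
#' @param design a `block_design`.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(design, path) {
  stopifnot(inherits(design, "block_design"))
  ev <- data.frame(onset = design$onset, duration = design$duration,
                   trial_type = design$condition)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events table back into a block design
#'
#' @param path events TSV with `onset`, `duration`, `trial_type`.
#' @param tr repetition time in seconds.
#' @param n_dummy dummy volumes preceding the first block.
#' @param block_volumes volumes per block (stimulus + interval).
#' @return A `block_design`.
#' @export
read_events_tsv <- function(path, tr = 3.408, n_dummy = 3L, block_volumes = 10L) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("onset", "duration", "trial_type")) {
    if (!(col %in% names(ev))) stop(sprintf("events file lacks column '%s'", col), call. = FALSE)
  }
  onset_volume <- as.integer(round(ev$onset / tr)) + 1L
  stim_volumes <- as.integer(round(ev$duration[1] / tr))
  design <- data.frame(
    block = seq_len(nrow(ev)),
    condition = ev$trial_type,
    onset_volume = onset_volume,
    onset = ev$onset,
    duration = ev$duration,
    stringsAsFactors = FALSE
  )
  if (all(grepl("^att(CW|CCW)_(hi|lo)$", ev$trial_type))) {
    design$attended <- ifelse(grepl("^attCW", ev$trial_type), "CW", "CCW")
    design$contrast <- ifelse(grepl("_hi$", ev$trial_type), "high", "low")
  }
  n_volumes <- max(onset_volume) + block_volumes - 1L
  structure(design,
            tr = tr, n_dummy = as.integer(n_dummy),
            block_volumes = as.integer(block_volumes),
            stim_volumes = stim_volumes,
            n_volumes = n_volumes,
            class = c("block_design", "data.frame"))
}

#' Write a depth-weight matrix as TSV
#'
#' Columns `voxel_id, w_wm, w_deep, w_mid, w_sup, w_csf`.
#'
#' @param weights a [make_depth_weights()] matrix.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_depth_weights <- function(weights, path) {
  W <- unclass(weights)[, , drop = FALSE]
  df <- data.frame(voxel_id = seq_len(nrow(W)),
                   w_wm = W[, "wm"], w_deep = W[, "deep"], w_mid = W[, "middle"],
                   w_sup = W[, "superficial"], w_csf = W[, "csf"])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a depth-weight TSV
#'
#' @param path TSV written by [write_depth_weights()].
#' @return A `depth_weights` matrix.
#' @export
read_depth_weights <- function(path) {
  df <- utils::read.delim(path)
  W <- as.matrix(df[, c("w_wm", "w_deep", "w_mid", "w_sup", "w_csf")])
  colnames(W) <- ALL_BINS
  structure(W, class = c("depth_weights", "matrix", "array"))
}

#' Write layer time courses as long-format TSV
#'
#' Columns `bin, volume, value, run, normalized`.
#'
#' @param layers a `layer_timecourses`.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_layer_tsv <- function(layers, path) {
  stopifnot(inherits(layers, "layer_timecourses"))
  M <- unclass(layers)
  df <- data.frame(
    bin = rep(rownames(M), ncol(M)),
    volume = rep(seq_len(ncol(M)), each = nrow(M)),
    value = as.vector(M),
    run = attr(layers, "run_id"),
    normalized = isTRUE(attr(layers, "normalized"))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ground truth as JSON
#'
#' @param gt a [ground_truth()].
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_ground_truth_json <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file of configuration fields.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config a [pipeline_config()].
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a full subject dataset to a directory
#'
#' One NIfTI + events TSV per run, the localizer pair, the depth-weight
#' TSV, the orientation-truth TSV and the ground-truth JSON.
#'
#' @param subject a `subject_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject_dataset <- function(subject, dir) {
  stopifnot(inherits(subject, "subject_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(subject$runs)) {
    write_bold_run(subject$runs[[r]], file.path(dir, sprintf("run-%02d_bold.nii.gz", r)))
    write_events_tsv(subject$designs[[r]], file.path(dir, sprintf("run-%02d_events.tsv", r)))
  }
  write_bold_run(subject$localizer, file.path(dir, "localizer_bold.nii.gz"))
  write_events_tsv(subject$localizer_design, file.path(dir, "localizer_events.tsv"))
  write_depth_weights(subject$depth_weights, file.path(dir, "depth_weights.tsv"))
  utils::write.table(
    data.frame(voxel_id = seq_along(subject$orientation_truth),
               preferred = subject$orientation_truth),
    file.path(dir, "orientation_truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_ground_truth_json(subject$ground_truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
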