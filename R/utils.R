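#' @keywords internal
"_PACKAGE"

## Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

## Stable hash of an R object (used for pipeline manifests): serialize to a
## canonical raw vector and fold into a hex digest.  Collision resistance at
## the level needed to detect config changes, not cryptographic use.
object_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2L, xdr = TRUE)
  ## skip the serialization header (version-dependent bytes)
  raw <- raw[-seq_len(14L)]
  v <- as.integer(raw)
  h <- c(2166136261, 16777619, 305419896, 19088743)
  for (k in seq_along(h)) {
    acc <- h[k]
    for (i in seq_along(v)) {
      acc <- (acc * 31 + v[i] * (k + 1) + i) %% 2147483647
    }
    h[k] <- acc
  }
  paste(sprintf("%08x", as.integer(h)), collapse = "")
}

GM_BINS <- c("deep", "middle", "superficial")
ALL_BINS <- c("wm", "deep", "middle", "superficial", "csf")
CONDITION_LABELS <- c("attCW_hi", "attCW_lo", "attCCW_hi", "attCCW_lo")
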