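## Orthonormal contrast rows spanning the (k-1)-dimensional contrast space
## of a k-level factor (each row orthogonal to the unit vector).
orthonormal_contrasts <- function(k) {
  if (k < 2L) stop("factor must have at least 2 levels", call. = FALSE)
  t(qr.Q(qr(stats::contr.helmert(k))))
}

## Build the subjects x cells matrix from long-format data.
cells_from_long <- function(data, dv, within, subject) {
  for (v in c(dv, within, subject)) {
    if (!(v %in% names(data))) stop(sprintf("column '%s' not found", v), call. = FALSE)
  }
  levels <- lapply(within, function(f) {
    lv <- data[[f]]
    if (is.factor(lv)) levels(lv) else sort(unique(as.character(lv)))
  })
  names(levels) <- within
  subjects <- unique(as.character(data[[subject]]))
  grid <- rev(expand.grid(rev(levels), stringsAsFactors = FALSE))  # first factor varies slowest
  key_data <- do.call(paste, c(lapply(within, function(f) as.character(data[[f]])), sep = "\r"))
  key_grid <- do.call(paste, c(grid, sep = "\r"))
  cells <- matrix(NA_real_, length(subjects), nrow(grid),
                  dimnames = list(subjects, key_grid))
  idx <- cbind(match(as.character(data[[subject]]), subjects),
               match(key_data, key_grid))
  if (anyNA(idx)) stop("unmatched design cells", call. = FALSE)
  if (anyDuplicated(idx)) stop("duplicated subject x cell observations", call. = FALSE)
  cells[idx] <- data[[dv]]
  if (anyNA(cells)) stop("incomplete design: every subject needs every cell", call. = FALSE)
  list(cells = cells, levels = levels)
}

#' Repeated-measures ANOVA with sphericity-corrected degrees of freedom
#'
#' Fully within-subject factorial ANOVA for one to three crossed factors.
#' For every effect the sums of squares are obtained by projecting the
#' subjects x cells matrix onto the effect's orthonormal contrast space
#' (Kronecker product of per-factor contrasts), with the matching
#' effect-by-subject interaction as the error term.  Sphericity is assessed
#' per effect from the covariance of the contrast scores:
#' the Greenhouse-Geisser epsilon is `tr(S)^2 / (d * tr(S^2))` and the
#' Huynh-Feldt epsilon is `(n d e_gg - 2) / (d (n - 1 - d e_gg))`, clipped
#' to 1.  Corrected degrees of freedom multiply `(d, d (n - 1))` by the
#' chosen epsilon; two-level effects have `d = 1` and epsilon exactly 1.
#'
#' @param data either a long-format data frame, or a subjects x cells
#'   numeric matrix whose columns enumerate the factor-level combinations
#'   with the first factor varying slowest.
#' @param dv,subject column names of the dependent variable and subject id
#'   (long format only).
#' @param within character vector of within-subject factor names (long
#'   format), or, for a matrix, a named list/vector giving each factor's
#'   number of levels.
#' @param epsilon which correction to apply to the reported p value:
#'   `"huynh-feldt"` (default), `"greenhouse-geisser"`, or `"none"`.
#' @return An object of class `rm_anova`: data frame with one row per
#'   effect (`effect`, `df1`, `df2`, `ss_effect`, `ss_error`, `F`,
#'   `eps_gg`, `eps_hf`, `df1_corr`, `df2_corr`, `p`, `p_uncorrected`).
#'   Attributes carry the subject count and the subject and total sums of
#'   squares.
#' @export
rm_anova <- function(data, dv = "value", within, subject = "subject",
                     epsilon = c("huynh-feldt", "greenhouse-geisser", "none")) {
  epsilon <- match.arg(epsilon)
  if (is.matrix(data)) {
    if (is.null(names(within))) {
      stop("for matrix input, `within` must be a named vector/list of level counts",
           call. = FALSE)
    }
    k <- vapply(within, as.integer, integer(1))
    if (prod(k) != ncol(data)) {
      stop("cell count does not match the factor level counts", call. = FALSE)
    }
    cells <- data
    levels <- lapply(k, seq_len)
  } else {
    cl <- cells_from_long(data, dv, within, subject)
    cells <- cl$cells
    levels <- cl$levels
    k <- vapply(levels, length, integer(1))
  }
  n <- nrow(cells)
  if (n < 2L) stop("at least 2 subjects are required", call. = FALSE)
  factors <- names(k)

  effect_sets <- unlist(lapply(seq_along(factors), function(m) {
    utils::combn(factors, m, simplify = FALSE)
  }), recursive = FALSE)

  rows <- lapply(effect_sets, function(ef) {
    ## Kronecker transform: contrasts for involved factors, normalized mean
    ## vector for the rest (keeps the transform orthonormal so the SS match
    ## the classical cell-mean formulas)
    M <- matrix(1, 1, 1)
    for (f in factors) {
      Mf <- if (f %in% ef) orthonormal_contrasts(k[[f]])
            else matrix(1 / sqrt(k[[f]]), 1, k[[f]])
      M <- M %x% Mf
    }
    d <- nrow(M)
    Yt <- cells %*% t(M)                      # subjects x d contrast scores
    m <- colMeans(Yt)
    ss_eff <- n * sum(m^2)
    ss_err <- sum(sweep(Yt, 2, m)^2)
    df1 <- d
    df2 <- d * (n - 1L)
    ## cells identical across the effect's levels: both SS are rounding
    ## noise; report a null effect rather than a 0/0 ratio
    tol <- 1e-12 * max(sum(cells^2), .Machine$double.xmin)
    degenerate <- ss_eff < tol && ss_err < tol
    Fv <- if (degenerate) 0 else (ss_eff / df1) / (ss_err / df2)
    if (d == 1L || degenerate) {
      gg <- hf <- 1
    } else {
      S <- stats::cov(Yt)
      gg <- sum(diag(S))^2 / (d * sum(S * S))
      hf <- min(1, (n * d * gg - 2) / (d * ((n - 1) - d * gg)))
      hf <- max(hf, gg)
    }
    eps_use <- switch(epsilon, "huynh-feldt" = hf, "greenhouse-geisser" = gg, "none" = 1)
    data.frame(
      effect = paste(ef, collapse = ":"),
      df1 = df1, df2 = df2, ss_effect = ss_eff, ss_error = ss_err, F = Fv,
      eps_gg = gg, eps_hf = hf,
      df1_corr = df1 * eps_use, df2_corr = df2 * eps_use,
      p = stats::pf(Fv, df1 * eps_use, df2 * eps_use, lower.tail = FALSE),
      p_uncorrected = stats::pf(Fv, df1, df2, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  grand <- mean(cells)
  ss_subject <- ncol(cells) * sum((rowMeans(cells) - grand)^2)
  structure(out,
            n_subjects = n, levels = levels, epsilon = epsilon,
            ss_subject = ss_subject,
            ss_total = sum((cells - grand)^2),
            class = c("rm_anova", "data.frame"))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d subjects, %s-corrected p)\n",
              attr(x, "n_subjects"), attr(x, "epsilon")))
  df <- as.data.frame(x)
  df$ss_effect <- signif(df$ss_effect, 5)
  df$ss_error <- signif(df$ss_error, 5)
  df$F <- round(df$F, 3)
  df$eps_gg <- round(df$eps_gg, 3)
  df$eps_hf <- round(df$eps_hf, 3)
  df$df1_corr <- round(df$df1_corr, 2)
  df$df2_corr <- round(df$df2_corr, 2)
  df$p <- signif(df$p, 4)
  df$p_uncorrected <- signif(df$p_uncorrected, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Paired-samples t test with degenerate-difference guards
#'
#' Standard two-sided paired t test on the per-subject differences.  If all
#' differences are exactly zero the test is reported as `t = 0, p = 1`; if
#' the differences are a nonzero constant the t statistic is unbounded and
#' an error is raised instead of returning infinity.
#'
#' @param x,y equal-length per-subject value vectors.
#' @return List with `t`, `df`, `p`, and `mean_difference`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("`x` and `y` must have equal length >= 2", call. = FALSE)
  }
  d <- x - y
  s <- stats::sd(d)
  if (all(d == 0)) {
    return(list(t = 0, df = length(d) - 1L, p = 1, mean_difference = 0))
  }
  if (s <= 1e-10 * abs(mean(d))) {
    stop("differences have zero variance but nonzero mean; t is unbounded",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_difference = unname(ht$estimate))
}

#' Within-subject (Cousineau-Morey) standard errors
#'
#' Removes between-subject offset variance by subtracting each subject's
#' mean and adding back the grand mean, then computes the per-condition
#' standard error of the normalized scores, scaled by the Morey bias
#' correction `sqrt(k / (k - 1))` for `k` conditions.
#'
#' @param cells subjects x conditions numeric matrix (or data frame).
#' @return Named per-condition standard errors.
#' @export
within_subject_se <- function(cells) {
  cells <- as.matrix(cells)
  n <- nrow(cells)
  k <- ncol(cells)
  if (k < 2L) stop("at least 2 conditions are required", call. = FALSE)
  if (n < 2L) stop("at least 2 subjects are required", call. = FALSE)
  norm <- cells - rowMeans(cells) + mean(cells)
  se <- apply(norm, 2, stats::sd) / sqrt(n)
  se * sqrt(k / (k - 1))
}
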