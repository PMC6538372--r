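#' Cortical slab geometry for the depth-weight generator
#'
#' Describes a flat cortical slab: a white-matter margin below the gray
#' matter, a gray-matter sheet of constant thickness whose lower boundary is
#' sinusoidally perturbed in both in-plane directions, and a CSF margin
#' above.  Gray matter is divided into three equal-volume depth bins; for a
#' constant-thickness slab the equivolume rule reduces to equal-thickness
#' thirds.  All lengths in millimetres.
#'
#' @param voxel_size isotropic voxel edge length.
#' @param gm_thickness gray-matter thickness; must be positive.
#' @param wm_margin,csf_margin slab extent below/above gray matter.
#' @param wobble_amplitude amplitude of the sinusoidal boundary perturbation.
#' @param wobble_wavelength in-plane wavelength of the perturbation.
#' @return An object of class `slab_geometry`.
#' @export
slab_geometry <- function(voxel_size = 0.8, gm_thickness = 2.0,
                          wm_margin = 2.4, csf_margin = 2.4,
                          wobble_amplitude = 0.4, wobble_wavelength = 12.8) {
  if (gm_thickness <= 0) stop("degenerate geometry: `gm_thickness` must be > 0", call. = FALSE)
  if (voxel_size <= 0) stop("`voxel_size` must be > 0", call. = FALSE)
  if (wobble_amplitude < 0) stop("`wobble_amplitude` must be >= 0", call. = FALSE)
  if (wm_margin < wobble_amplitude || csf_margin < wobble_amplitude) {
    stop("margins must be at least `wobble_amplitude` so the slab contains the boundaries",
         call. = FALSE)
  }
  structure(
    list(voxel_size = voxel_size, gm_thickness = gm_thickness,
         wm_margin = wm_margin, csf_margin = csf_margin,
         wobble_amplitude = wobble_amplitude,
         wobble_wavelength = wobble_wavelength),
    class = "slab_geometry"
  )
}

## Depth of the WM/GM boundary at in-plane position (x, y) for given phases.
wm_boundary_depth <- function(geom, x, y, phase_x = 0, phase_y = 0) {
  geom$wm_margin + geom$wobble_amplitude *
    sin(2 * pi * x / geom$wobble_wavelength + phase_x) *
    cos(2 * pi * y / geom$wobble_wavelength + phase_y)
}

## Partial-volume fractions of the voxel z-interval [z0, z0 + vs] against the
## five depth bins, given the WM boundary depth zw at one in-plane sub-point.
## Overlap in z is exact (interval intersection); in-plane variation of the
## boundary is handled by averaging over sub-points in the caller.
interval_bin_fractions <- function(z0, z1, cuts) {
  ## cuts: 4 boundaries (wm/deep, deep/middle, middle/sup, sup/csf)
  len <- z1 - z0
  lo <- c(-Inf, cuts)
  hi <- c(cuts, Inf)
  frac <- pmax(0, pmin(z1, hi) - pmax(z0, lo)) / len
  frac
}

#' Generate a partial-volume depth-weight matrix from a synthetic slab
#'
#' Lays voxels on a regular grid through a flat cortical slab and computes,
#' for each voxel, the proportion of its volume overlapping each of five
#' depth bins: white matter, three equal-volume gray-matter bins (deep,
#' middle, superficial) and CSF.  The overlap is exact along depth and
#' averaged over a sub-voxel grid of in-plane sample points, so the
#' sinusoidally perturbed boundary produces realistic mixed rows.  This
#' weight matrix is the spatial design used by [layer_regression()].
#'
#' When the grid holds more voxels than requested, excess voxels are removed
#' from the pure white-matter/CSF margins first, which leaves the balance of
#' gray-matter bin volumes untouched.
#'
#' @param n_voxels number of voxels (rows) to return.
#' @param geometry a [slab_geometry()].
#' @param seed integer seed; controls the random phases of the boundary
#'   perturbation only.
#' @param inplane_samples number of sub-voxel sample points per in-plane
#'   axis used to average over the perturbed boundary.
#' @return An object of class `depth_weights`: an `n_voxels` x 5 matrix with
#'   columns `wm, deep, middle, superficial, csf`, rows summing to 1, with
#'   the voxel grid coordinates attached as attributes.
#' @export
make_depth_weights <- function(n_voxels, geometry = slab_geometry(), seed = 1L,
                               inplane_samples = 5L) {
  stop_if_not_scalar_count(n_voxels, "n_voxels")
  if (!inherits(geometry, "slab_geometry")) {
    stop("`geometry` must be a `slab_geometry` object", call. = FALSE)
  }
  vs <- geometry$voxel_size
  phases <- with_seed_(seed, stats::runif(2, 0, 2 * pi))

  slab_height <- geometry$wm_margin + geometry$gm_thickness + geometry$csf_margin
  nz <- as.integer(ceiling(slab_height / vs))
  n_sticks <- as.integer(ceiling(n_voxels / nz))
  n_xy <- as.integer(ceiling(sqrt(n_sticks)))

  ## stick (in-plane) positions on a voxel-spaced grid
  stick_idx <- seq_len(n_sticks) - 1L
  sx <- (stick_idx %% n_xy) * vs
  sy <- (stick_idx %/% n_xy) * vs

  ## sub-voxel in-plane offsets (cell midpoints)
  off <- (seq_len(inplane_samples) - 0.5) / inplane_samples * vs
  sub <- expand.grid(dx = off, dy = off)

  t3 <- geometry$gm_thickness / 3
  W <- matrix(0, nrow = n_sticks * nz, ncol = 5L,
              dimnames = list(NULL, ALL_BINS))
  xs <- numeric(n_sticks * nz)
  ys <- numeric(n_sticks * nz)
  zs <- numeric(n_sticks * nz)
  z0s <- (seq_len(nz) - 1L) * vs

  for (s in seq_len(n_sticks)) {
    zw <- wm_boundary_depth(geometry, sx[s] + sub$dx, sy[s] + sub$dy,
                            phases[1], phases[2])
    ## accumulate bin fractions over in-plane sub-points, exact in z
    acc <- matrix(0, nrow = nz, ncol = 5L)
    for (j in seq_along(zw)) {
      cuts <- zw[j] + c(0, t3, 2 * t3, 3 * t3)
      for (v in seq_len(nz)) {
        acc[v, ] <- acc[v, ] + interval_bin_fractions(z0s[v], z0s[v] + vs, cuts)
      }
    }
    rows <- (s - 1L) * nz + seq_len(nz)
    W[rows, ] <- acc / length(zw)
    xs[rows] <- sx[s]
    ys[rows] <- sy[s]
    zs[rows] <- z0s
  }

  excess <- nrow(W) - n_voxels
  if (excess > 0L) {
    ## drop margin voxels first: order candidates by gray-matter content
    ## (ascending), ties by descending row index so trimming is deterministic
    gm_content <- W[, "deep"] + W[, "middle"] + W[, "superficial"]
    drop_order <- order(gm_content, -seq_len(nrow(W)))
    drop <- drop_order[seq_len(excess)]
    keep <- setdiff(seq_len(nrow(W)), drop)
    W <- W[keep, , drop = FALSE]
    xs <- xs[keep]; ys <- ys[keep]; zs <- zs[keep]
  }

  structure(W,
            x = xs, y = ys, z = zs,
            geometry = geometry, phases = phases,
            class = c("depth_weights", "matrix", "array"))
}

#' @export
print.depth_weights <- function(x, ...) {
  cat(sprintf("depth_weights: %d voxels x 5 bins (%s)\n",
              nrow(x), paste(colnames(x), collapse = ", ")))
  gm <- colSums(x[, GM_BINS, drop = FALSE])
  cat("GM bin volumes (voxel units):",
      paste(sprintf("%s=%.2f", names(gm), gm), collapse = ", "), "\n")
  invisible(x)
}
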