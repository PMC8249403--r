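#' Uniform orientation grid on SO(3)
#'
#' Builds an approximately uniform covering of rotation space with `n`
#' quaternions (antipodal pairs identified) and uniform prior weights `1/n`.
#' The grid is a seeded low-discrepancy covering: a Halton sequence in the
#' unit cube pushed through the subgroup-algorithm map, with a seeded
#' Cranley-Patterson shift so that different seeds give different (equally
#' uniform) grids. Production-scale grids (tens of thousands of points, as
#' used for full-size particle stacks) are supported; desk-scale defaults are
#' much smaller.
#'
#' @param n number of grid orientations, `>= 1`. `n = 1` returns the identity.
#' @param seed integer seed for the grid shift.
#' @return an object of class `"orientation_grid"`: list with `quaternions`
#'   (`n x 4` matrix, unit rows, canonical sign) and `weights` (length `n`,
#'   summing to 1).
#' @export
build_uniform_orientation_grid <- function(n, seed = 1L) {
  if (n < 1) stopf("n must be at least 1")
  if (n == 1) {
    q <- matrix(c(1, 0, 0, 0), 1, 4)
  } else {
    shift <- withr::with_seed(as.integer(seed), runif(3))
    u <- halton_sequence(n, 3, shift = shift)
    q <- t(apply(u, 1, function(ui) quat_canonical(shoemake_quaternion(ui))))
  }
  structure(list(quaternions = q, weights = rep(1 / n, n)),
            class = "orientation_grid")
}

#' @export
print.orientation_grid <- function(x, ...) {
  cat(sprintf("<orientation_grid> %d quaternions\n", nrow(x$quaternions)))
  invisible(x)
}

#' Local orientation refinement grid
#'
#' Builds the second-round orientation set: around each of the `K` seed
#' orientations (the best-scoring orientations of the coarse round), a local
#' grid of `local_size` small-angle perturbations, giving `K * local_size`
#' quaternions in total (1250 under the defaults `K = 10`, `local_size =
#' 125`). When `local_size` is a perfect cube `l^3` the perturbations form an
#' `l x l x l` grid in rotation-vector space over `[-half_width, half_width]^3`
#' (radians per axis); otherwise a low-discrepancy point set in the same box
#' is used. Every output orientation lies within a geodesic angle
#' `sqrt(3) * half_width` of its seed.
#'
#' @param top_orientations `K x 4` matrix (or length-4 vector) of seed
#'   quaternions.
#' @param local_size perturbations per seed, `>= 1` (default 125).
#' @param half_width half-width of the perturbation box in radians per
#'   rotation-vector axis; sensible values are about the nearest-neighbor
#'   spacing of the coarse grid.
#' @return an `"orientation_grid"` with `K * local_size` quaternions and
#'   uniform weights; seed indices are attached as attribute `"seed_index"`.
#' @export
refine_orientation_grid <- function(top_orientations, local_size = 125,
                                    half_width = 0.1) {
  if (is.null(dim(top_orientations)))
    top_orientations <- matrix(top_orientations, nrow = 1)
  k <- nrow(top_orientations)
  if (k < 1) stopf("at least one seed orientation is required")
  if (local_size < 1) stopf("local_size must be at least 1")
  if (half_width <= 0) stopf("half_width must be positive")

  l <- round(local_size^(1 / 3))
  offsets <- if (l^3 == local_size) {
    ax <- if (l == 1) 0 else seq(-half_width, half_width, length.out = l)
    as.matrix(expand.grid(ax, ax, ax))
  } else {
    # non-cubic sizes: the seed itself plus low-discrepancy points in the box
    rbind(matrix(0, 1, 3),
          (halton_sequence(local_size - 1, 3) * 2 - 1) * half_width)
  }

  out <- matrix(0, k * local_size, 4)
  seed_idx <- integer(k * local_size)
  row <- 0L
  for (i in seq_len(k)) {
    qi <- top_orientations[i, ]
    for (j in seq_len(local_size)) {
      w <- offsets[j, ]
      ang <- sqrt(sum(w^2))
      dq <- if (ang < 1e-15) c(1, 0, 0, 0) else c(cos(ang / 2), sin(ang / 2) * w / ang)
      row <- row + 1L
      out[row, ] <- quat_canonical(quat_multiply(qi, dq))
      seed_idx[row] <- i
    }
  }
  g <- structure(list(quaternions = out, weights = rep(1 / nrow(out), nrow(out))),
                 class = "orientation_grid")
  attr(g, "seed_index") <- seed_idx
  g
}

# Rough nearest-neighbor angular spacing (radians) of an n-point covering of
# SO(3): (volume 8 pi^2 per point)^(1/3) in rotation-vector measure.
grid_spacing_estimate <- function(n) (8 * pi^2 / n)^(1 / 3)
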