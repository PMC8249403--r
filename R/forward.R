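#' Render an ideal (noise-free, CTF-free) particle projection
#'
#' Rotates the bead model, orthographically projects it along the optical
#' axis, and renders each bead as an integrable 2D Gaussian centered at the
#' projected bead position. The Gaussian width is tied to the bead radius by
#' matching the second moment of a uniform ball of that radius
#' (`sigma = radius / sqrt(5)`), and each bead integrates to its electron
#' count, so the pixel sum of the image approximates the molecule's total
#' electron count. The molecule is centered (mean bead position at the box
#' center) before the in-plane shift is applied.
#'
#' Image pixel indices are 0-based with origin at the top-left; the box
#' center is at pixel `(box_size/2, box_size/2)`.
#'
#' @param conf a [conformation()].
#' @param orientation unit quaternion `(w, x, y, z)`.
#' @param shift in-plane offset in pixels, length 2 (default none).
#' @param pixel_size pixel size in Angstrom.
#' @param box_size image side in pixels (even, `>= 16`).
#' @return a `box_size x box_size` matrix of pixel intensities.
#' @export
project <- function(conf, orientation, shift = c(0, 0), pixel_size = 2.2,
                    box_size = 128L) {
  check_box(box_size)
  if (pixel_size <= 0) stopf("pixel_size must be positive")
  if (abs(sqrt(sum(orientation^2)) - 1) > 1e-9)
    stopf("orientation must be a unit quaternion")
  img <- cg_project_cpp(conf$positions, conf$radii, conf$electrons,
                        orientation, shift[1], shift[2], pixel_size,
                        as.integer(box_size))
  # warn (and keep the clipped rendering) if a bead center leaves the box
  ctr <- colMeans(conf$positions)
  rot <- quat_to_rotmat(orientation)
  xy <- t(rot %*% (t(conf$positions) - ctr))[, 1:2, drop = FALSE] / pixel_size
  px <- sweep(xy, 2, c(shift[1], shift[2]) + box_size / 2, "+")
  if (any(px < 0 | px > box_size - 1))
    warning("bead center falls outside the image box; projection is clipped")
  img
}

check_box <- function(box_size) {
  if (box_size < 16 || box_size %% 2 != 0)
    stopf("box_size must be even and at least 16")
  invisible(TRUE)
}

#' Apply a contrast transfer function to an image
#'
#' Multiplies the image's Fourier transform by a phase-contrast CTF with an
#' amplitude-contrast term and a Gaussian B-factor envelope:
#' `CTF(k) = -(sqrt(1 - A^2) sin(chi) + A cos(chi)) exp(-B k^2 / 4)` with
#' `chi = pi * lambda_e * defocus * k^2`, electron wavelength `lambda_e =
#' 0.0197` Angstrom (300 keV), `k` the spatial frequency in 1/Angstrom. The
#' same convention is used for simulation and for likelihood templates, so
#' the two sides of the closed validation loop are exactly consistent.
#'
#' @param img square image matrix.
#' @param defocus defocus in micrometer, `> 0`.
#' @param ctf_amplitude amplitude contrast in `[0, 1]` (default 0.1).
#' @param b_factor B-factor envelope in Angstrom^2 (default 1).
#' @param pixel_size pixel size in Angstrom.
#' @return the CTF-filtered image (real matrix, same size).
#' @export
apply_ctf <- function(img, defocus, ctf_amplitude = 0.1, b_factor = 1,
                      pixel_size = 2.2) {
  img <- as.matrix(img)
  if (nrow(img) != ncol(img)) stopf("image must be square")
  if (defocus <= 0) stopf("defocus must be positive")
  if (ctf_amplitude < 0 || ctf_amplitude > 1)
    stopf("ctf_amplitude must lie in [0, 1]")
  ctf_apply_cpp(img, defocus, ctf_amplitude, b_factor, pixel_size)
}

#' Add SNR-calibrated Gaussian noise to an image
#'
#' Adds i.i.d. zero-mean Gaussian noise whose variance is
#' `Var_circle(signal) / snr`, where `Var_circle` is the pixel variance of
#' the noise-free image within a central circle whose radius scales as
#' 40/128 of the box side (radius 40 px at the reference 128-px box).
#'
#' @param img square image matrix (the noise-free signal).
#' @param snr signal-to-noise ratio, `> 0`. `snr = Inf` returns the image
#'   unchanged.
#' @param rng_seed optional integer; when given, the noise stream is seeded
#'   locally (the surrounding RNG state is untouched) so calls with the same
#'   seed are identical.
#' @return the noisy image.
#' @export
add_noise <- function(img, snr, rng_seed = NULL) {
  img <- as.matrix(img)
  if (snr <= 0) stopf("snr must be positive")
  if (!is.finite(snr)) return(img)
  v <- circle_variance(img)
  if (v < 1e-300) stopf("signal is constant within the measurement circle")
  sigma <- sqrt(v / snr)
  noise_fun <- function() matrix(rnorm(length(img), sd = sigma), nrow(img))
  noise <- if (is.null(rng_seed)) noise_fun()
           else withr::with_seed(as.integer(rng_seed), noise_fun())
  img + noise
}

# Pixel variance within the central circle (radius round(box * 40/128)).
circle_variance <- function(img) {
  n <- nrow(img)
  rad <- round(n * 40 / 128)
  ctr <- n / 2
  ix <- matrix(0:(n - 1), n, n)        # row index = x
  iy <- t(ix)                          # col index = y
  mask <- (ix - ctr)^2 + (iy - ctr)^2 <= rad^2
  var(img[mask])
}

#' Sample path-node indices from a Boltzmann population
#'
#' Draws node indices with probability `exp(-G(s_m)) / sum_k exp(-G(s_k))`,
#' the predetermined population occupancy implied by the ground-truth
#' profile.
#'
#' @param profile a [ground_truth_profile()] (or numeric vector of node free
#'   energies, kBT). `+Inf` entries get zero weight.
#' @param n number of draws.
#' @param rng_seed optional local seed, as in [add_noise()].
#' @return integer vector of node indices in `1..M`.
#' @export
sample_node_index <- function(profile, n = 1, rng_seed = NULL) {
  g <- if (inherits(profile, "gt_profile")) profile$values else as.numeric(profile)
  if (any(is.na(g))) stopf("profile values must not be NA")
  w <- exp(-(g - min(g[is.finite(g)])))
  w[!is.finite(g)] <- 0
  draw <- function() sample.int(length(g), n, replace = TRUE, prob = w)
  if (is.null(rng_seed)) draw() else withr::with_seed(as.integer(rng_seed), draw())
}

#' Generate a synthetic particle stack along a path
#'
#' The forward model of the closed validation loop. For each particle: a
#' path node is drawn from the Boltzmann population of the ground-truth
#' profile, an orientation uniformly on SO(3), an SNR log-uniformly over
#' `snr_range`, and a defocus uniformly over `defocus_range_um`; the node is
#' rendered with [project()], filtered with [apply_ctf()] and degraded with
#' [add_noise()]. Particles are generated centered (no in-plane shift); the
#' likelihood still scans a small shift grid, so downstream inference is
#' shift-tolerant. Everything is drawn from one seeded stream, so a stack is
#' bit-reproducible from `(arguments, seed)`.
#'
#' @param path a [make_path()] object.
#' @param profile a [ground_truth_profile()] with one value per node.
#' @param n_images number of particles, `>= 1`.
#' @param snr_range `(lo, hi)`, SNR sampled log-uniformly (default the
#'   full-scale benchmark range `c(0.001, 0.1)`).
#' @param defocus_range_um `(lo, hi)` defocus range in micrometer (default
#'   `c(0.5, 3)`).
#' @param pixel_size pixel size in Angstrom (default 2.2).
#' @param box_size image side in pixels (default 128).
#' @param ctf_amplitude,b_factor CTF parameters (defaults 0.1 and 1
#'   Angstrom^2).
#' @param seed integer master seed.
#' @return an object of class `"particle_stack"`: list with `images`
#'   (`box x box x n` array), `meta` (data frame with per-particle
#'   `defocus_um`, `pixel_size`, `snr`, `truth_node`, quaternion columns
#'   `qw,qx,qy,qz`), `pixel_size`, `box_size`, and a `provenance` record of
#'   the generating configuration and seed.
#' @export
generate_dataset <- function(path, profile, n_images,
                             snr_range = c(0.001, 0.1),
                             defocus_range_um = c(0.5, 3),
                             pixel_size = 2.2, box_size = 128L,
                             ctf_amplitude = 0.1, b_factor = 1,
                             seed = 1L) {
  if (!inherits(path, "cv_path")) stopf("path must be a cv_path")
  if (n_images < 1) stopf("n_images must be at least 1")
  if (any(snr_range <= 0) || any(defocus_range_um <= 0))
    stopf("snr_range and defocus_range_um must be positive")
  check_box(box_size)
  m <- path_length(path)
  g <- if (inherits(profile, "gt_profile")) profile$values else as.numeric(profile)
  if (length(g) != m) stopf("profile length (%d) must match path nodes (%d)",
                            length(g), m)

  box_size <- as.integer(box_size)
  images <- array(0, c(box_size, box_size, n_images))
  meta <- data.frame(defocus_um = numeric(n_images), pixel_size = pixel_size,
                     snr = numeric(n_images), truth_node = integer(n_images),
                     qw = numeric(n_images), qx = numeric(n_images),
                     qy = numeric(n_images), qz = numeric(n_images))
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n_images)) {
      node <- sample_node_index(g, 1)
      quat <- shoemake_quaternion(runif(3))
      snr <- 10^runif(1, log10(snr_range[1]), log10(snr_range[2]))
      defocus <- runif(1, defocus_range_um[1], defocus_range_um[2])
      ideal <- project(path$nodes[[node]], quat, pixel_size = pixel_size,
                       box_size = box_size)
      img <- apply_ctf(ideal, defocus, ctf_amplitude, b_factor, pixel_size)
      images[, , i] <- add_noise(img, snr)
      meta$defocus_um[i] <- defocus; meta$snr[i] <- snr
      meta$truth_node[i] <- node
      meta[i, c("qw", "qx", "qy", "qz")] <- as.list(quat)
    }
  })
  structure(list(images = images, meta = meta, pixel_size = pixel_size,
                 box_size = box_size,
                 provenance = list(n_images = n_images, snr_range = snr_range,
                                   defocus_range_um = defocus_range_um,
                                   pixel_size = pixel_size, box_size = box_size,
                                   ctf_amplitude = ctf_amplitude,
                                   b_factor = b_factor, seed = as.integer(seed),
                                   M = m, profile = g)),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  cat(sprintf("<particle_stack> %d images, %d x %d px at %.3g A/px\n",
              dim(x$images)[3], x$box_size, x$box_size, x$pixel_size))
  invisible(x)
}

n_images <- function(stack) dim(stack$images)[3]
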