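#' Marginalization settings for the image-node likelihood
#'
#' Collects the numerical settings of the pose marginalization: the coarse
#' (round-1) orientation grid, the in-plane shift scan, the defocus grids and
#' priors of both rounds, and the local (round-2) refinement geometry.
#' Orientation and shift priors are uniform; the defocus prior is Gaussian --
#' broad and centered mid-range in round 1 (where no per-particle information
#' is assumed), centered at each particle's nominal defocus with scale
#' 0.3 micrometer in round 2.
#'
#' @param round1_grid_size orientations in the coarse uniform grid
#'   (desk-scale default 576; production-scale values such as 36864 are
#'   supported).
#' @param max_shift_px half-extent of the in-plane shift scan in integer
#'   pixels (default 4, i.e. a 9 x 9 shift grid).
#' @param n_defocus_r1 defocus grid points in round 1 (default 3, spanning
#'   the observed per-particle defocus range).
#' @param defocus_grid_r1 explicit round-1 defocus grid in micrometer
#'   (overrides `n_defocus_r1`).
#' @param round2_top_k best round-1 orientations refined per image-node pair
#'   (default 10).
#' @param round2_local_size local grid points per refined orientation
#'   (default 125 = 5^3), so the default round-2 set has 10 x 125 = 1250
#'   quaternions.
#' @param round2_half_width half-width (radians per rotation-vector axis) of
#'   each local refinement box; `NULL` (default) uses half the round-1
#'   nearest-neighbor spacing estimate, so the local boxes tile the coarse
#'   grid cell around each seed.
#' @param round2_levels depth of the local refinement (default 1: a single
#'   local grid, the classic two-round scheme). With more levels the local
#'   grid is re-centered on the best marginal orientation and shrunk by the
#'   grid factor at each level, giving pose accuracy well below the coarse
#'   spacing at small extra cost; the reported likelihood comes from the
#'   final level. Levels beyond 1 require a perfect-cube
#'   `round2_local_size`.
#' @param defocus_offsets_r2 defocus grid offsets around each particle's
#'   nominal defocus, micrometer (default `c(-0.3, 0, 0.3)`).
#' @param defocus_scale_r2 scale of the round-2 Gaussian defocus prior,
#'   micrometer (default 0.3).
#' @param ctf_amplitude,b_factor CTF parameters used for the templates
#'   (defaults 0.1 and 1 Angstrom^2, matching the simulator).
#' @param seed integer seed for the orientation-grid construction.
#' @return a list of class `"marginalization_config"`.
#' @export
marginalization_config <- function(round1_grid_size = 576L, max_shift_px = 4L,
                                   n_defocus_r1 = 3L, defocus_grid_r1 = NULL,
                                   round2_top_k = 10L, round2_local_size = 125L,
                                   round2_half_width = NULL, round2_levels = 1L,
                                   defocus_offsets_r2 = c(-0.3, 0, 0.3),
                                   defocus_scale_r2 = 0.3,
                                   ctf_amplitude = 0.1, b_factor = 1,
                                   seed = 1L) {
  if (round1_grid_size < 1 || round2_top_k < 1 || round2_local_size < 1)
    stopf("grid sizes must be positive")
  if (max_shift_px < 0) stopf("max_shift_px must be non-negative")
  if (defocus_scale_r2 <= 0) stopf("defocus_scale_r2 must be positive")
  l <- round(round2_local_size^(1 / 3))
  if (round2_levels > 1 && l^3 != round2_local_size)
    stopf("round2_levels > 1 needs a perfect-cube round2_local_size")
  structure(list(round1_grid_size = as.integer(round1_grid_size),
                 max_shift_px = as.integer(max_shift_px),
                 n_defocus_r1 = as.integer(n_defocus_r1),
                 defocus_grid_r1 = defocus_grid_r1,
                 round2_top_k = as.integer(round2_top_k),
                 round2_local_size = as.integer(round2_local_size),
                 round2_half_width = round2_half_width,
                 round2_levels = as.integer(round2_levels),
                 defocus_offsets_r2 = defocus_offsets_r2,
                 defocus_scale_r2 = defocus_scale_r2,
                 ctf_amplitude = ctf_amplitude, b_factor = b_factor,
                 seed = as.integer(seed)),
            class = "marginalization_config")
}

#' Closed-form per-pose log likelihood
#'
#' Log likelihood of an image given a fixed template (one orientation, shift
#' and defocus), with the Gaussian noise variance, the additive intensity
#' offset and the multiplicative normalization integrated out in closed form
#' (flat priors on offset and normalization, a Jeffreys prior `1/sigma` on
#' the noise scale). Writing `P` for the pixel count and `R` for the residual
#' sum of squares of the image after optimal affine intensity matching to the
#' template,
#' \deqn{\log p = (1 - P/2)\log 2\pi + \frac{P-4}{2}\log 2 +
#'   \log\Gamma\left(\frac{P-2}{2}\right) - \frac{1}{2}\log(P\,c_{tt})
#'   - \frac{P-2}{2}\log R,}
#' with `c_tt` the centered sum of squares of the template. The additive
#' constant depends only on `P`, so likelihoods are comparable across nodes.
#' `R` is floored at `1e-12` times the image's centered sum of squares to
#' keep exact noise-free matches finite.
#'
#' @param image,template square matrices of equal size.
#' @return the log likelihood (a single number).
#' @export
pose_log_likelihood <- function(image, template) {
  p <- length(image)
  if (length(template) != p) stopf("image and template sizes differ")
  sw <- sum(image); sww <- sum(image^2)
  st <- sum(template); stt <- sum(template^2)
  ctt <- stt - st^2 / p
  if (ctt <= 1e-12 * max(1, stt))
    stopf("degenerate (all-constant) template; projection has no contrast")
  cww <- sww - sw^2 / p
  cwt <- sum(image * template) - sw * st / p
  r <- max(cww - cwt^2 / ctt, 1e-12 * cww)
  (1 - p / 2) * log(2 * pi) + (p - 4) / 2 * log(2) + lgamma((p - 2) / 2) -
    0.5 * log(p * ctt) - (p - 2) / 2 * log(r)
}

# Circular 2D shift of a matrix by (dx, dy) (reference implementation).
circshift2 <- function(m, dx, dy) {
  n <- nrow(m)
  ri <- ((seq_len(n) - 1 - dx) %% n) + 1
  ci <- ((seq_len(n) - 1 - dy) %% n) + 1
  m[ri, ci, drop = FALSE]
}

#' Pose-marginalized log likelihood of one image given one node (reference)
#'
#' Plain-R reference implementation of the marginalized likelihood
#' `log p(w | x_m)`: a prior-weighted log-sum-exp of [pose_log_likelihood()]
#' over an orientation grid, an integer shift scan and a defocus grid. The
#' compiled path used by [compute_likelihood_matrix()] implements the same
#' quantity; this version is kept as the readable single-image route and as
#' the cross-check for the compiled one.
#'
#' @param image square image matrix.
#' @param node a [conformation()].
#' @param grid an [build_uniform_orientation_grid()] object.
#' @param config a [marginalization_config()] (shift extent and CTF
#'   parameters are taken from it).
#' @param pixel_size pixel size in Angstrom.
#' @param defocus_grid defocus grid in micrometer (default a single nominal
#'   value 1.75).
#' @param defocus_logprior log prior weights of the defocus grid points
#'   (default uniform); normalized internally.
#' @return the marginal log likelihood (a single number, normalization
#'   independent of the node).
#' @export
image_node_log_likelihood <- function(image, node, grid,
                                      config = marginalization_config(),
                                      pixel_size = 2.2,
                                      defocus_grid = 1.75,
                                      defocus_logprior = NULL) {
  image <- as.matrix(image)
  if (nrow(image) != ncol(image)) stopf("image must be square")
  if (is.null(defocus_logprior)) defocus_logprior <- rep(0, length(defocus_grid))
  defocus_logprior <- defocus_logprior - logsumexp(defocus_logprior)
  shifts <- -config$max_shift_px:config$max_shift_px
  log_shift_w <- -log(length(shifts)^2)
  terms <- c()
  for (o in seq_len(nrow(grid$quaternions))) {
    proj <- project(node, grid$quaternions[o, ], pixel_size = pixel_size,
                    box_size = nrow(image))
    for (d in seq_along(defocus_grid)) {
      tmpl <- apply_ctf(proj, defocus_grid[d], config$ctf_amplitude,
                        config$b_factor, pixel_size)
      base <- log(grid$weights[o]) + defocus_logprior[d] + log_shift_w
      for (dx in shifts) for (dy in shifts) {
        terms <- c(terms, base + pose_log_likelihood(image, circshift2(tmpl, dx, dy)))
      }
    }
  }
  logsumexp(terms)
}

#' Two-round image-node log-likelihood matrix
#'
#' Computes `log p(w_i | x_m)` for every image-node pair, the interface
#' between the imaging model and the profile posterior. Round 1 marginalizes
#' each pair over the shared coarse orientation grid, the shift scan and a
#' broad defocus grid, and records the best-scoring coarse orientations.
#' Round 2 re-marginalizes over a fine image-specific orientation set
#' (local grids around the top `round2_top_k` coarse orientations, pooled
#' over nodes so that every node of an image is refined around the same
#' seeds -- this keeps the quadrature error of the local refinement common
#' to all columns of a row, which matters at desk-scale grid sizes) and a
#' defocus grid centered at the particle's nominal defocus with a Gaussian
#' prior of scale 0.3 micrometer. Both rounds are returned; downstream
#' inference uses round 2 by default.
#'
#' @param stack a [generate_dataset()] stack (or one read with
#'   [read_particle_stack()]).
#' @param path a [make_path()] object.
#' @param config a [marginalization_config()].
#' @return an object of class `"loglik_matrix"`: list with `values` (the
#'   round-2 `I x M` matrix), `round1` (the round-1 matrix), `image_ids`,
#'   `node_ids`, and `config` (the settings actually used, including derived
#'   grids).
#' @export
compute_likelihood_matrix <- function(stack, path, config = marginalization_config()) {
  if (!inherits(stack, "particle_stack")) stopf("stack must be a particle_stack")
  if (!inherits(path, "cv_path")) stopf("path must be a cv_path")
  ni <- n_images(stack); m <- path_length(path)
  if (ni < 1 || m < 1) stopf("stack and path must be non-empty")
  px <- stack$pixel_size; box <- stack$box_size
  defocus <- stack$meta$defocus_um

  # round-1 defocus grid and broad mid-range Gaussian prior
  dg1 <- config$defocus_grid_r1
  if (is.null(dg1)) {
    rng <- range(defocus)
    dg1 <- if (diff(rng) < 1e-9 || config$n_defocus_r1 == 1) mean(rng)
           else seq(rng[1], rng[2], length.out = config$n_defocus_r1)
  }
  d1_center <- mean(range(defocus))
  d1_scale <- max(diff(range(defocus)) / 2, 0.3)
  d1_logw <- -(dg1 - d1_center)^2 / (2 * d1_scale^2)
  d1_logw <- d1_logw - logsumexp(d1_logw)

  grid <- build_uniform_orientation_grid(config$round1_grid_size, config$seed)
  n_orient <- nrow(grid$quaternions)
  half_width <- config$round2_half_width %||% (grid_spacing_estimate(n_orient) / 2)
  local_l <- round(config$round2_local_size^(1 / 3))
  if (local_l^3 != config$round2_local_size)
    stopf("the pipeline needs a perfect-cube round2_local_size (e.g. 27 or 125)")

  round1 <- matrix(0, ni, m)
  round2 <- matrix(0, ni, m)
  orient_score <- matrix(0, ni, n_orient)

  nd1 <- length(dg1)
  orient_of <- rep(seq_len(n_orient) - 1L, each = nd1)     # defocus fastest
  logprior <- rep(log(grid$weights), each = nd1) + rep(d1_logw, n_orient)
  for (node_i in seq_len(m)) {
    nd <- path$nodes[[node_i]]
    templates <- build_templates_cpp(nd$positions, nd$radii, nd$electrons,
                                     grid$quaternions, dg1,
                                     config$ctf_amplitude, config$b_factor,
                                     px, box)
    r1 <- ll_round1_cpp(stack$images, templates, orient_of, logprior,
                        n_orient, config$max_shift_px)
    round1[, node_i] <- r1$ll
    orient_score <- orient_score + r1$orient_ll
  }
  # refinement seeds per image, pooled over nodes: all nodes of an image are
  # refined around the same coarse orientations, so the quadrature error of
  # the local refinement cancels in across-node likelihood comparisons
  k <- min(config$round2_top_k, n_orient)
  topk <- matrix(0L, ni, k)
  for (i in seq_len(ni))
    topk[i, ] <- order(orient_score[i, ], decreasing = TRUE)[seq_len(k)]

  off2 <- config$defocus_offsets_r2
  lw2 <- -(off2)^2 / (2 * config$defocus_scale_r2^2)
  lw2 <- lw2 - logsumexp(lw2)
  for (node_i in seq_len(m)) {
    nd <- path$nodes[[node_i]]
    for (i in seq_len(ni)) {
      seeds <- grid$quaternions[topk[i, ], , drop = FALSE]
      round2[i, node_i] <- ll_refine_iter_cpp(stack$images[, , i], nd$positions,
                                              nd$radii, nd$electrons,
                                              seeds, local_l, half_width,
                                              config$round2_levels, off2, lw2,
                                              defocus[i],
                                              config$ctf_amplitude,
                                              config$b_factor,
                                              px, config$max_shift_px)
    }
  }
  # complete the round-2 orientation quadrature over the rest of SO(3): the
  # refined grids cover only the boxes around the seeds; the round-1 value
  # is the volume-complete coarse marginal and represents the remainder.
  # For sharp orientation landscapes the refined term dominates; for
  # shallow ones (low-SNR images) the global term keeps rows appropriately
  # soft instead of over-sharpening around the best pose.
  v_ref <- k * (2 * half_width)^3
  v_tot <- 8 * pi^2                      # consistent with grid_spacing_estimate
  f_ref <- min(v_ref / v_tot, 0.5)
  round2 <- matrix(
    apply(array(c(log(f_ref) + round2, log(1 - f_ref) + round1),
                c(ni, m, 2)), c(1, 2), logsumexp),
    ni, m)

  used <- config
  used$defocus_grid_r1 <- dg1
  used$round2_half_width <- half_width
  structure(list(values = round2, round1 = round1,
                 image_ids = seq_len(ni), node_ids = seq_len(m),
                 config = used),
            class = "loglik_matrix")
}

#' Construct / subset a log-likelihood matrix object
#'
#' `as_loglik_matrix` wraps a plain `I x M` matrix (for example one computed
#' by an external likelihood engine) so it can be fed to [mcmc_sample()];
#' `subset_loglik` keeps a subset of images (rows), as used for the
#' SNR/defocus/count ablation experiments.
#'
#' @param values `I x M` matrix of `log p(w_i | x_m)`, all finite.
#' @param llmat a `"loglik_matrix"`.
#' @param idx image (row) indices to keep.
#' @return a `"loglik_matrix"`.
#' @export
as_loglik_matrix <- function(values) {
  values <- as.matrix(values)
  if (!all(is.finite(values) | values == -Inf))
    stopf("log-likelihood values must be finite (or -Inf)")
  structure(list(values = values, round1 = NULL,
                 image_ids = seq_len(nrow(values)),
                 node_ids = seq_len(ncol(values)), config = NULL),
            class = "loglik_matrix")
}

#' @rdname as_loglik_matrix
#' @export
subset_loglik <- function(llmat, idx) {
  out <- llmat
  out$values <- llmat$values[idx, , drop = FALSE]
  if (!is.null(llmat$round1)) out$round1 <- llmat$round1[idx, , drop = FALSE]
  out$image_ids <- llmat$image_ids[idx]
  out
}

#' @export
print.loglik_matrix <- function(x, ...) {
  cat(sprintf("<loglik_matrix> %d images x %d nodes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
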