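# Small fixtures shared across tests; everything is generated in code.

# a tiny asymmetric conformation (no special symmetry)
tiny_conf <- function(n_beads = 5, seed = 11) {
  withr::with_seed(seed, {
    pos <- matrix(rnorm(3 * n_beads, sd = 6), n_beads, 3)
    conformation(pos, radii = runif(n_beads, 3, 6),
                 electrons = runif(n_beads, 100, 500))
  })
}

# a small rotor path for likelihood/benchmark tests
small_path <- function(M = 4, total = 45) toy_rotor_path(M, total)

# a small noisy stack with known truth labels
small_stack <- function(n = 8, M = 4, box = 32, seed = 5,
                        snr_range = c(0.05, 0.1)) {
  p <- small_path(M)
  gt <- ground_truth_profile("hsp90_1d", M = M)
  generate_dataset(p, gt, n, snr_range = snr_range, box_size = box,
                   seed = seed)
}

# build a particle_stack directly from an image array (unit-test plumbing)
stack_from_images <- function(imgs, defocus, pixel_size = 2.2) {
  n <- dim(imgs)[3]
  structure(list(images = imgs,
                 meta = data.frame(defocus_um = rep(defocus, length.out = n),
                                   pixel_size = pixel_size, snr = NA,
                                   truth_node = NA, qw = 0, qx = 0, qy = 0, qz = 0),
                 pixel_size = pixel_size, box_size = dim(imgs)[1],
                 provenance = list()),
            class = "particle_stack")
}

# brute-force triple numerical integration over (normalization N, offset mu,
# noise sigma) of the per-pose Gaussian likelihood with flat priors on N and
# mu and a Jeffreys 1/sigma prior -- the independent oracle for the
# closed-form pose_log_likelihood(). Integrates on a dense tensor grid
# around the analytic optimum (range choice does not borrow the closed-form
# value, only the least-squares fit location).
numeric_pose_marginal <- function(image, template, n_grid = 120) {
  w <- as.numeric(image); t <- as.numeric(template)
  P <- length(w)
  X <- cbind(t, 1)
  fit <- lm.fit(X, w)
  nb <- fit$coefficients[1]; mb <- fit$coefficients[2]
  rss <- sum(fit$residuals^2)
  sig_hat <- sqrt(rss / P)
  se_n <- sig_hat / sqrt(sum((t - mean(t))^2))
  se_m <- sig_hat / sqrt(P)
  n_seq <- seq(nb - 10 * se_n, nb + 10 * se_n, length.out = n_grid)
  m_seq <- seq(mb - 10 * se_m, mb + 10 * se_m, length.out = n_grid)
  s_seq <- exp(seq(log(sig_hat / 3), log(sig_hat * 3), length.out = n_grid))
  sww <- sum(w^2); st <- sum(t); stt <- sum(t^2)
  sw <- sum(w); cwt <- sum(w * t)
  # Q(N, mu) on the (N, mu) grid, closed form in the sufficient statistics
  q <- outer(n_seq, m_seq, function(N, mu)
    sww - 2 * N * cwt - 2 * mu * sw + N^2 * stt + 2 * N * mu * st + mu^2 * P)
  dn <- diff(n_seq[1:2]); dm <- diff(m_seq[1:2])
  # trapezoid in log sigma: d sigma / sigma = d log sigma
  dls <- diff(log(s_seq[1:2]))
  terms <- vapply(s_seq, function(sg)
    matrixStats_logsumexp(-P / 2 * log(2 * pi * sg^2) - q / (2 * sg^2)) +
      log(dn) + log(dm), numeric(1))
  # Jeffreys prior: 1/sigma dsigma = dlog(sigma), the grid is log-spaced
  matrixStats_logsumexp(terms) + log(dls)
}

# plain log-sum-exp for matrices/vectors used by the oracle above
matrixStats_logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
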