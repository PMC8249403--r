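#' Smoothness prior on a discretized free-energy profile
#'
#' The weak-smoothness prior `p(G) = 1 / calG^2` with
#' `calG = sum_{m=1}^{M-1} (G(s_{m+1}) - G(s_m))^2` -- a standard normal
#' prior on the discrete differences marginalized over its precision. The
#' prior depends only on differences, so it is invariant to the additive
#' gauge of the profile. For profiles flat to within `calG < 1e-12` the
#' guarded value at `calG = 1e-12` is returned, keeping the log prior
#' defined on that measure-zero set without altering behavior elsewhere.
#'
#' @param g_values numeric vector of node free energies in kBT, length
#'   `M >= 2`.
#' @return the log prior, `-2 * log(calG)`.
#' @export
log_prior <- function(g_values) {
  if (length(g_values) < 2) stopf("a profile needs at least 2 nodes")
  cal_g <- sum(diff(g_values)^2)
  -2 * log(max(cal_g, 1e-12))
}

#' Log posterior of a free-energy profile given a likelihood matrix
#'
#' Up to an additive constant:
#' `log p(G | w) = log p(G) + sum_i log[(1/M) sum_m p(w_i|x_m) e^{-G_m} / Z_1]`
#' with `Z_1 = (1/M) sum_m e^{-G_m}` (the equispaced path quadrature applied
#' to the profile's partition function). Evaluated stably in log space from
#' the stored log likelihoods; adding any constant to a row of the matrix,
#' or to all of `G`, changes the result by a `G`-independent constant only.
#'
#' @param g_values node free energies in kBT (length `M`).
#' @param llmat a `"loglik_matrix"` (or plain `I x M` matrix) of
#'   `log p(w_i | x_m)`.
#' @return the unnormalized log posterior.
#' @export
log_posterior <- function(g_values, llmat) {
  ll <- if (inherits(llmat, "loglik_matrix")) llmat$values else as.matrix(llmat)
  if (length(g_values) != ncol(ll))
    stopf("profile length (%d) must match matrix columns (%d)",
          length(g_values), ncol(ll))
  lz <- logsumexp(-g_values)             # log sum_m e^{-G_m} (the 1/M cancels)
  terms <- apply(sweep(ll, 2, g_values, "-"), 1, logsumexp) - lz
  log_prior(g_values) + sum(terms)
}

#' MCMC settings for posterior sampling
#'
#' @param n_chains number of independent chains `R >= 2` (default 8; two or
#'   more are required for the R-hat diagnostic).
#' @param n_steps Metropolis steps per chain (default 200000).
#' @param step_half_width half-width of the uniform single-node proposal in
#'   kBT (default 0.5, i.e. `delta g ~ U[-0.5, 0.5]`).
#' @param init_range range of the uniform random initialization per node in
#'   kBT (default `c(-2, 2)`).
#' @param burn_in_fraction fraction of each chain discarded before
#'   summarizing (default 0: all draws enter the expectation).
#' @param seed master seed; per-chain streams are derived from it so chain
#'   results are order-independent.
#' @return a list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_chains = 8L, n_steps = 200000L,
                        step_half_width = 0.5, init_range = c(-2, 2),
                        burn_in_fraction = 0, seed = 1L) {
  if (n_chains < 1) stopf("n_chains must be at least 1")
  if (n_steps < 1) stopf("n_steps must be at least 1")
  if (step_half_width <= 0) stopf("step_half_width must be positive")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stopf("burn_in_fraction must lie in [0, 1)")
  structure(list(n_chains = as.integer(n_chains), n_steps = as.integer(n_steps),
                 step_half_width = step_half_width, init_range = init_range,
                 burn_in_fraction = burn_in_fraction, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Sample free-energy profiles from the posterior
#'
#' Random-walk Metropolis over the node values of the profile. Each step:
#' pick one node uniformly, perturb it by `delta g ~ U[-w, w]` kBT, re-center
#' the profile to the `sum_m G_m = 0` gauge, and accept with log probability
#' `min(0, log p(G') - log p(G))`. Initial values are drawn independently and
#' uniformly from `init_range` at each node. All draws are stored (in the
#' sum-zero gauge) and the run is fully reproducible from the master seed.
#'
#' Internally the likelihood term is updated incrementally (a single-node
#' perturbation touches one column of the likelihood sum; the re-centering
#' shift cancels against `Z_1` exactly), with periodic full recomputation to
#' suppress floating-point drift; results are identical to the direct
#' evaluation up to machine precision.
#'
#' @param llmat a `"loglik_matrix"` (or plain `I x M` matrix).
#' @param config an [mcmc_config()].
#' @return an object of class `"posterior_samples"`: list with `draws`
#'   (`n_chains x n_steps x M` array, sum-zero gauge), `acceptance_rate`
#'   (per chain) and `config`.
#' @export
mcmc_sample <- function(llmat, config = mcmc_config()) {
  ll <- if (inherits(llmat, "loglik_matrix")) llmat$values else as.matrix(llmat)
  m <- ncol(ll); ni <- nrow(ll)
  if (m < 2) stopf("at least 2 nodes are required")
  # row-wise stabilization: subtracting a row constant shifts the posterior
  # by a G-independent constant and cancels in acceptance ratios
  rmax <- apply(ll, 1, max)
  rmax[!is.finite(rmax)] <- 0
  p_im <- exp(ll - rmax)                 # I x M, rows O(1)

  r <- config$n_chains; n <- config$n_steps; w <- config$step_half_width
  draws <- array(0, c(r, n, m))
  acc <- numeric(r)
  chain_seeds <- withr::with_seed(config$seed,
                                  sample.int(.Machine$integer.max, r))
  for (ch in seq_len(r)) {
    withr::with_seed(chain_seeds[ch], {
      g <- runif(m, config$init_range[1], config$init_range[2])
      eg <- exp(-g)
      b <- as.numeric(p_im %*% eg)
      s <- sum(eg)
      lp <- log_prior(g) + sum(log(b)) - ni * log(s)
      n_acc <- 0L
      for (it in seq_len(n)) {
        node <- sample.int(m, 1)
        dg <- runif(1, -w, w)
        g_new <- g
        g_new[node] <- g[node] + dg
        d_eg <- exp(-g_new[node]) - eg[node]
        b_new <- b + p_im[, node] * d_eg
        s_new <- s + d_eg
        lp_new <- log_prior(g_new) + sum(log(b_new)) - ni * log(s_new)
        if (log(runif(1)) <= lp_new - lp) {
          g <- g_new
          eg[node] <- eg[node] + d_eg
          b <- b_new; s <- s_new; lp <- lp_new
          n_acc <- n_acc + 1L
        }
        if (it %% 2000L == 0L) {         # refresh against FP drift
          b <- as.numeric(p_im %*% eg)
          s <- sum(eg)
          lp <- log_prior(g) + sum(log(b)) - ni * log(s)
        }
        draws[ch, it, ] <- g - mean(g)   # stored in the sum-zero gauge
      }
      acc[ch] <- n_acc / n
    })
  }
  structure(list(draws = draws, acceptance_rate = acc, config = config),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<posterior_samples> %d chains x %d steps x %d nodes (acceptance %.2f-%.2f)\n",
              d[1], d[2], d[3], min(x$acceptance_rate), max(x$acceptance_rate)))
  invisible(x)
}

post_burn <- function(samples) {
  d <- dim(samples$draws)
  burn <- floor((samples$config$burn_in_fraction %||% 0) * d[2])
  samples$draws[, seq.int(burn + 1, d[2]), , drop = FALSE]
}

#' Summarize posterior profile samples
#'
#' Node-wise posterior mean over all retained draws, shifted so the minimum
#' of the mean profile is zero (only free-energy differences are physical);
#' 5 and 95 percent empirical quantiles per node (shifted by the same
#' constant); per-node split R-hat; and a natural cubic spline through the
#' node means with knots at the nodes.
#'
#' @param samples a [mcmc_sample()] result.
#' @param s_values path parameters of the nodes (default equispaced).
#' @return an object of class `"profile_summary"`: list with `s`,
#'   `mean_profile` (min zero), `ci_low`, `ci_high`, `r_hat`, `shift` (the
#'   constant subtracted), and `spline` (a function of `s`).
#' @export
expected_profile <- function(samples, s_values = NULL) {
  draws <- post_burn(samples)
  d <- dim(draws)
  if (d[1] * d[2] < 1) stopf("no draws to summarize")
  m <- d[3]
  flat <- matrix(draws, d[1] * d[2], m)
  mean_g <- colMeans(flat)
  shift <- min(mean_g)
  mean_g <- mean_g - shift
  ci <- apply(flat, 2, quantile, probs = c(0.05, 0.95), names = FALSE) - shift
  s <- s_values %||% ((seq_len(m) - 1) / (m - 1))
  rh <- tryCatch(r_hat(samples), error = function(e) rep(NA_real_, m))
  structure(list(s = s, mean_profile = mean_g,
                 ci_low = ci[1, ], ci_high = ci[2, ], r_hat = rh,
                 shift = shift,
                 spline = splinefun(s, mean_g, method = "natural")),
            class = "profile_summary")
}

#' @export
print.profile_summary <- function(x, ...) {
  cat(sprintf("<profile_summary> %d nodes, range %.2f kBT, max R-hat %.3f\n",
              length(x$s), max(x$mean_profile), suppressWarnings(max(x$r_hat))))
  invisible(x)
}

#' Split R-hat convergence diagnostic
#'
#' Per-node potential scale reduction factor comparing between-chain to
#' within-chain variance, with each chain split in half (so a single chain
#' that has not mixed also registers). Values at or below 1.1 indicate
#' convergence of the sampling.
#'
#' @param samples a [mcmc_sample()] result with at least 2 chains.
#' @return numeric vector of per-node R-hat values.
#' @export
r_hat <- function(samples) {
  draws <- post_burn(samples)
  d <- dim(draws)
  if (d[1] < 2) stopf("R-hat needs at least 2 chains")
  half <- d[2] %/% 2
  if (half < 2) stopf("chains too short to split")
  m <- d[3]
  out <- numeric(m)
  for (j in seq_len(m)) {
    seqs <- vector("list", 2 * d[1])
    for (ch in seq_len(d[1])) {
      seqs[[2 * ch - 1]] <- draws[ch, seq_len(half), j]
      seqs[[2 * ch]] <- draws[ch, seq.int(half + 1, 2 * half), j]
    }
    means <- vapply(seqs, mean, numeric(1))
    vars <- vapply(seqs, var, numeric(1))
    w <- mean(vars)
    b <- half * var(means)
    if (w < 1e-300) { out[j] <- if (b < 1e-300) 1 else Inf; next }
    var_plus <- (half - 1) / half * w + b / half
    out[j] <- sqrt(var_plus / w)
  }
  out
}

#' Brute-force posterior node means by grid quadrature
#'
#' Dense-grid quadrature of the unnormalized posterior over the sum-zero
#' gauge surface, available for `M <= 3` profiles (at most two free
#' dimensions after gauge fixing). Used as the independent oracle against
#' which the Metropolis sampler is validated.
#'
#' @param llmat a `"loglik_matrix"` or plain matrix with `M <= 3` columns.
#' @param grid_resolution points per free dimension (default 801).
#' @param limit half-range of each free dimension in kBT (default 8).
#' @return numeric vector of node-wise posterior means (sum-zero gauge).
#' @export
brute_force_posterior <- function(llmat, grid_resolution = 801L, limit = 8) {
  ll <- if (inherits(llmat, "loglik_matrix")) llmat$values else as.matrix(llmat)
  m <- ncol(ll)
  if (m > 3) stopf("brute-force quadrature supports M <= 3 only")
  ax <- seq(-limit, limit, length.out = grid_resolution)
  if (m == 2) {
    gmat <- cbind(ax, -ax)
  } else {
    gr <- expand.grid(a = ax, b = ax)
    gmat <- cbind(gr$a, gr$b, -gr$a - gr$b)
  }
  # vectorized over the grid: group identical image rows, evaluate the
  # likelihood term through exp(-G) products (|G_m| <= 2*limit keeps exp in
  # range), and the same guarded prior as log_prior()
  key <- apply(ll, 1, paste, collapse = "\r")
  counts <- table(key)
  u_rows <- ll[match(names(counts), key), , drop = FALSE]
  counts <- as.numeric(counts)
  eg <- exp(-gmat)                       # N x M
  lz <- log(rowSums(eg))
  loglik <- -sum(counts) * lz
  for (u in seq_len(nrow(u_rows))) {
    lu <- u_rows[u, ]
    mx <- max(lu)
    loglik <- loglik + counts[u] * (log(eg %*% exp(lu - mx)) + mx)
  }
  dif2 <- (gmat[, -1, drop = FALSE] - gmat[, -m, drop = FALSE])^2
  cal_g <- pmax(rowSums(dif2), 1e-12)
  lp <- as.numeric(loglik) - 2 * log(cal_g)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  as.numeric(t(gmat) %*% w)
}
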