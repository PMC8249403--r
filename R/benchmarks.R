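#' Toy two-arm rotor conformation
#'
#' A peptide-scale V-shaped bead model mimicking, at desk scale, a
#' two-domain molecule whose conformational change is the closing of one
#' arm towards the other: one arm of beads lies along the x axis, the
#' second arm (at 150 degrees from it in the xy plane when `rotation_deg =
#' 0`, with a small out-of-plane rise to break planarity) bends towards the
#' first arm about the z axis through the pivot at the origin. The bend is
#' distributed along the mobile arm -- bead `k` of the arm rotates by
#' `rotation_deg * k / n_mobile`, so the tip sweeps the full angle while
#' the base barely moves, like a curling finger. A distributed bend changes
#' the internal geometry of the molecule, so no rigid-body motion (which
#' the likelihood marginalizes away) can mimic a change of conformation;
#' a rigid arm rotation, by contrast, is largely absorbed by a compensating
#' global rotation and leaves almost no conformational signal in the
#' images.
#'
#' @param n_beads total bead count (split between the two arms), `>= 3`.
#' @param rotation_deg bend of the mobile arm tip in degrees (positive
#'   closes the V).
#' @param bead_spacing distance between consecutive beads along an arm,
#'   Angstrom (default 2.8, about a C-alpha step).
#' @param bead_radius bead radius in Angstrom (default 3).
#' @param bead_electrons electron count per bead (default 60, about one
#'   residue).
#' @return a [conformation()].
#' @export
make_toy_rotor <- function(n_beads = 12L, rotation_deg = 0,
                           bead_spacing = 2.8, bead_radius = 3,
                           bead_electrons = 60) {
  if (n_beads < 3) stopf("n_beads must be at least 3")
  n_fixed <- ceiling(n_beads / 2)
  n_mobile <- n_beads - n_fixed
  fixed <- cbind(bead_spacing * seq_len(n_fixed), 0, 0)
  a0 <- 150 * pi / 180   # open V at rest; a 120-degree bend leaves 30 degrees
  dir <- c(cos(a0), sin(a0), 0.2)
  dir <- dir / sqrt(sum(dir^2))
  mobile <- outer(bead_spacing * seq_len(n_mobile), dir)
  for (k in seq_len(n_mobile)) {
    th <- -rotation_deg * (k / n_mobile) * pi / 180   # tip bends fully
    rot_z <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                    3, 3, byrow = TRUE)
    mobile[k, ] <- mobile[k, ] %*% t(rot_z)
  }
  pos <- rbind(fixed, mobile)
  conformation(pos, rep(bead_radius, n_beads), rep(bead_electrons, n_beads),
               label = sprintf("toy rotor %.1f deg", rotation_deg))
}

#' Toy rotor path
#'
#' `M` rotor conformations at equal rotation steps from 0 to
#' `total_rotation_deg`, assembled into a path.
#'
#' @param M number of nodes.
#' @param total_rotation_deg full bend range in degrees (default 120, so
#'   `M = 10` gives 13.3-degree tip steps).
#' @param ... passed to [make_toy_rotor()].
#' @return a [make_path()] object.
#' @export
toy_rotor_path <- function(M = 10L, total_rotation_deg = 120, ...) {
  angles <- seq(0, total_rotation_deg, length.out = M)
  make_path(lapply(angles, function(a) make_toy_rotor(rotation_deg = a, ...)))
}

#' Benchmark specification
#'
#' Bundles everything needed to run one controlled free-energy-recovery
#' experiment: the path source, ground truth, imaging conditions,
#' marginalization settings and MCMC settings. The default, `name =
#' "rotor_1d_small"`, is the desk-scale analogue of the full-size 1D
#' chaperone benchmark: a 10-node toy-rotor path populated by the 1D
#' ground-truth double well, 1500 particles in a 32-px box at 1.2 A/px, SNR
#' log-uniform in \[0.01, 0.1\], defocus uniform in \[0.5, 3\] um, and 4 chains
#' of 20000 Metropolis steps.
#'
#' @param name spec name.
#' @param M,n_images,snr_range,defocus_range,box_size,pixel_size imaging
#'   conditions (see [generate_dataset()]).
#' @param total_rotation_deg rotor rotation range, degrees.
#' @param seed master seed for the whole experiment.
#' @param likelihood a [marginalization_config()]; the default uses
#'   desk-scale grids (1152 coarse orientations, a +-1 px shift scan, a
#'   6-point round-1 defocus grid, 10 refined orientations with three
#'   levels of 27-point local grids).
#' @param mcmc an [mcmc_config()].
#' @return a list of class `"benchmark_spec"`.
#' @export
benchmark_spec <- function(name = "rotor_1d_small", M = 10L, n_images = 1500L,
                           snr_range = c(0.01, 0.1), defocus_range = c(0.5, 3),
                           box_size = 32L, pixel_size = 1.2,
                           total_rotation_deg = 120, seed = 7L,
                           likelihood = marginalization_config(
                             round1_grid_size = 1152L, max_shift_px = 1L,
                             n_defocus_r1 = 6L,
                             round2_top_k = 10L, round2_local_size = 27L,
                             round2_levels = 3L,
                             # wider than the auto (spacing/2) box: robust to
                             # ranking noise in the coarse round at low SNR
                             round2_half_width = 0.2575, seed = seed),
                           mcmc = mcmc_config(n_chains = 4L, n_steps = 20000L,
                                              seed = seed + 1L)) {
  structure(list(name = name, M = as.integer(M), n_images = as.integer(n_images),
                 snr_range = snr_range, defocus_range = defocus_range,
                 box_size = as.integer(box_size), pixel_size = pixel_size,
                 total_rotation_deg = total_rotation_deg,
                 seed = as.integer(seed), likelihood = likelihood, mcmc = mcmc),
            class = "benchmark_spec")
}

#' Run a controlled free-energy-recovery benchmark
#'
#' The closed validation loop: generate a synthetic stack from the printed
#' ground truth, compute the two-round likelihood matrix, sample the profile
#' posterior, and score the recovered profile against the truth (both
#' min-shifted). "Populated" nodes are those whose Boltzmann population is
#' at least 5 percent of the maximum; recovery error is reported over them
#' (sparsely populated nodes are dominated by their wide credible bands, not
#' their point estimate).
#'
#' @param spec a [benchmark_spec()].
#' @param keep_stack keep the stack and likelihood matrix in the report
#'   (default TRUE; set FALSE to shrink the object).
#' @return a list of class `"benchmark_report"`: `summary` (round-2
#'   [expected_profile()]), `summary_round1`, `truth` (min-shifted),
#'   `populated` (logical per node), `rmse_populated`, `coverage_populated`
#'   (fraction of populated nodes whose truth lies inside the 5-95 percent
#'   band), `max_r_hat`, `runtime_s`, `spec`, and (optionally) `stack`,
#'   `llmat`, `samples`.
#' @export
run_benchmark <- function(spec = benchmark_spec(), keep_stack = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  path <- toy_rotor_path(spec$M, spec$total_rotation_deg)
  truth <- ground_truth_profile("hsp90_1d", M = spec$M)
  stack <- generate_dataset(path, truth, spec$n_images,
                            snr_range = spec$snr_range,
                            defocus_range_um = spec$defocus_range,
                            pixel_size = spec$pixel_size,
                            box_size = spec$box_size, seed = spec$seed)
  llmat <- compute_likelihood_matrix(stack, path, spec$likelihood)
  samples <- mcmc_sample(llmat, spec$mcmc)
  summary2 <- expected_profile(samples, path$s_values)
  samples1 <- mcmc_sample(as_loglik_matrix(llmat$round1), spec$mcmc)
  summary1 <- expected_profile(samples1, path$s_values)

  report <- score_recovery(summary2, truth)
  report$summary_round1 <- summary1
  report$rmse_populated_round1 <-
    score_recovery(summary1, truth)$rmse_populated
  report$runtime_s <- proc.time()[["elapsed"]] - t0
  report$spec <- spec
  if (keep_stack) {
    report$stack <- stack; report$llmat <- llmat; report$samples <- samples
  }
  class(report) <- "benchmark_report"
  report
}

#' Score a recovered profile against a ground truth
#'
#' @param summary a [expected_profile()] result.
#' @param truth a [ground_truth_profile()] (or numeric node values, kBT).
#' @return list with `summary`, `truth` (min-shifted), `populated`,
#'   `rmse_populated`, `coverage_populated`, `max_r_hat`,
#'   `mean_band_width`.
#' @export
score_recovery <- function(summary, truth) {
  g <- if (inherits(truth, "gt_profile")) truth$values else as.numeric(truth)
  g <- g - min(g)
  pop <- node_populations(g)
  populated <- pop >= 0.05 * max(pop)
  resid <- summary$mean_profile - g
  inside <- g >= summary$ci_low & g <= summary$ci_high
  list(summary = summary, truth = g, populated = populated,
       rmse_populated = sqrt(mean(resid[populated]^2)),
       coverage_populated = mean(inside[populated]),
       max_r_hat = max(summary$r_hat),
       mean_band_width = mean(summary$ci_high - summary$ci_low))
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(paste0("<benchmark_report> %s\n",
                     "  RMSE (populated nodes): %.3f kBT  coverage: %.0f%%\n",
                     "  max split R-hat: %.3f   runtime: %.1f s\n"),
              x$spec$name, x$rmse_populated, 100 * x$coverage_populated,
              x$max_r_hat, x$runtime_s))
  invisible(x)
}

#' Compare 3D-ensemble and image-based free-energy profiles
#'
#' The two routes to the same profile: (a) evaluate the path progress
#' variable [path_cv_value()] for every 3D conformation of an ensemble,
#' histogram the values into as many bins as there are path nodes, and turn
#' bin populations into free energies through the Boltzmann factor (empty
#' bins get `+Inf`); (b) infer the profile from 2D particle images of the
#' same distribution with the full Bayesian pipeline. Both profiles are
#' returned min-shifted over finite entries.
#'
#' @param ensemble list of [conformation()] objects drawn from the
#'   conformational distribution.
#' @param path a [make_path()] object.
#' @param stack particle images drawn from the same distribution.
#' @param lambda_cv path-CV inverse length scale, Angstrom^-2 (default 50).
#' @param config a [marginalization_config()] for the image route.
#' @param mcmc an [mcmc_config()] for the image route.
#' @return list with `s_hist` (bin centers), `profile_3d`, `profile_images`
#'   (node-wise posterior mean), `summary_images` (full
#'   [expected_profile()]).
#' @export
compare_3d_vs_images <- function(ensemble, path, stack, lambda_cv = 50,
                                 config = marginalization_config(),
                                 mcmc = mcmc_config()) {
  m <- path_length(path)
  s_vals <- vapply(ensemble, path_cv_value, numeric(1), path = path,
                   lambda_cv = lambda_cv)
  breaks <- seq(0, 1, length.out = m + 1)
  bin <- pmin(pmax(findInterval(s_vals, breaks, rightmost.closed = TRUE), 1), m)
  counts <- tabulate(bin, nbins = m)
  g3 <- -log(counts / sum(counts))
  g3 <- g3 - min(g3[is.finite(g3)])

  llmat <- compute_likelihood_matrix(stack, path, config)
  samples <- mcmc_sample(llmat, mcmc)
  summ <- expected_profile(samples, path$s_values)
  list(s_hist = (breaks[-1] + breaks[-(m + 1)]) / 2,
       profile_3d = g3, profile_images = summ$mean_profile,
       summary_images = summ)
}
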