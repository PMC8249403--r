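---
title: "Inferring free-energy profiles along a conformational path from cryo-EM particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring free-energy profiles along a conformational path from cryo-EM particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryofep)
```

## The model

A biomolecule at thermal equilibrium visits conformations `x` with density
proportional to `exp(-beta H(x))`. When the relevant motion is essentially
one-dimensional, we describe it by a predetermined *path* `X(s)`,
`0 <= s <= 1`, through conformation space, and ask for the free-energy
profile (potential of mean force) `G(s)` along it: equilibrium populations
follow `rho_G(s) = exp(-G(s)) / Z_1` with `Z_1` the 1D partition function.
Only differences of `G` are physical; `cryofep` works throughout in units
of `kBT` (`beta = 1`).

The data are single cryo-EM particle images `w_1..w_I`, each a noisy,
CTF-filtered 2D projection of the molecule in one unknown conformation and
unknown pose. The path is discretized by `M` nodes `x_m = X(s_m)`,
`s_m = (m-1)/(M-1)`, and all path integrals use the equispaced M-node rule
`int f(s) ds ~ (1/M) sum_m f(s_m)` (the quadrature of record here --
deliberately not a trapezoid rule, so that end nodes carry the same weight
as interior ones). Assuming images are conditionally independent and come
from conformations near the path,

    p(G | w)  ∝  p(G) * prod_i [ (1/M) sum_m p(w_i | x_m) exp(-G_m) / Z_1 ],
    Z_1 = (1/M) sum_m exp(-G_m),

where `p(w_i | x_m)` is the pose-marginalized likelihood that image `i` is
a projection of node `m`. The pipeline therefore has three stages: build
the path, precompute the `I x M` log-likelihood matrix, and sample the
posterior over `{G_m}`.

`p(G)` is a weak-smoothness prior: a standard normal prior on the discrete
differences marginalized over its precision, `p(G) = 1 / calG^2` with
`calG = sum_m (G_{m+1} - G_m)^2`. Two numerical facts about this prior are
worth knowing. First, it diverges at exactly flat profiles; `log_prior()`
guards `calG` below `1e-12`, which keeps the sampler defined on that
measure-zero set without altering behavior elsewhere. Second, for very
small node counts (`M <= 5`) the divergence is non-integrable, so the
posterior is only effectively proper when the data penalize flat profiles
by clearly more than the guard's `-2 log(1e-12) ~ 55` log units; the
package's oracle comparisons for `M = 2, 3` therefore use strongly
informative matrices (hundreds of images). Relatedly, a maximum-a-
posteriori search under this prior collapses into the guarded flat spike
even when the posterior *mean* is accurate -- the spike is tall but carries
negligible mass -- which is why the package reports posterior expectations
and credible intervals, never a MAP point.

## The image-node likelihood

For a fixed pose (orientation `q`, integer in-plane shift, defocus `d`)
the model for an image is `w = N * t + mu + eps`, where `t` is the
rendered, CTF-filtered projection of the node, `N` an unknown
multiplicative normalization, `mu` an unknown additive offset, and `eps`
i.i.d. Gaussian noise of unknown scale `sigma`. `N` and `mu` take flat
priors, `sigma` a Jeffreys prior; all three integrate out in closed form
(`pose_log_likelihood()`), leaving a power of the residual sum of squares
after optimal affine intensity matching. The additive constant depends
only on the pixel count, so likelihoods are comparable across nodes. The
closed form is validated in the test suite against brute-force numerical
triple integration over `(N, mu, sigma)` on 8x8 images.

The remaining pose parameters are marginalized numerically under uniform
priors for orientation and shift and a Gaussian prior for defocus, in two
rounds:

* **Round 1** evaluates every image against a shared quasi-uniform
  orientation grid (a seeded low-discrepancy covering of rotation space;
  `round1_grid_size` of a few hundred at desk scale, tens of thousands
  supported), a small shift scan, and a broad defocus grid spanning the
  observed per-particle range, with a mid-range Gaussian prior. The exact
  round-1 defocus prior is not prescribed by the two-round scheme itself;
  the broad mid-range default is used and recorded in the returned config.
* **Round 2** re-marginalizes around the `round2_top_k` best coarse
  orientations with `l x l x l` rotation-vector grids of half-width
  `round2_half_width` (default: half the coarse nearest-neighbor spacing,
  so the boxes tile the coarse cell), optionally re-centered and shrunk
  over `round2_levels` levels; all evaluated points enter a
  volume-weighted union, i.e. a multi-resolution quadrature of the
  orientation integral. The part of rotation space outside the refined
  boxes is represented by the round-1 marginal (which covers all of SO(3)),
  mixed in with its complementary volume fraction: sharp orientation
  landscapes are dominated by the refined term, while shallow ones --
  typical of low-SNR images -- fall back to the soft coarse marginal
  instead of being over-sharpened around the best pose. The defocus grid is centered at each particle's
  nominal defocus with a 0.3 um Gaussian prior. The classic configuration
  -- ten seeds with 125-point local grids, 1250 refined quaternions -- is
  the default.

Two desk-scale calibration choices deserve emphasis, because they were
made after controlled experiments rather than taken from the standard
recipe:

1. **Pooled refinement seeds.** Selecting refinement seeds independently
   per node makes the local-quadrature error differ between columns of the
   same row; at coarse grid sizes this systematically flattens the
   recovered profile. `compute_likelihood_matrix()` therefore pools the
   round-1 orientation scores over nodes and refines *every* node of an
   image around the same seeds, so the quadrature error is common mode and
   cancels in across-node comparisons. An oracle experiment (refinement
   centered on the exactly-true pose) recovers the profile and motivates
   this choice.
2. **Log-sum-exp everywhere.** All pose sums are log-sum-exp reductions,
   so likelihoods at SNR 0.001 neither underflow nor lose the soft,
   nearly-flat rows that uninformative images should produce.

The plain-R reference implementation (`image_node_log_likelihood()`)
computes the same quantity one image at a time and is tested for exact
agreement with the compiled path; the compiled path does round-1 shift
correlations in real space with wrap-padded templates and round-2
correlations in Fourier space (FFTW), which are mathematically identical
routes.

## Sampling the posterior

`mcmc_sample()` implements a random-walk Metropolis chain over the node
values: initialize each `G_m ~ U[-2, 2]`, then per step pick one node
uniformly, perturb it by `delta g ~ U[-0.5, 0.5]` kBT, re-center to the
`sum_m G_m = 0` gauge, and accept on the log-posterior difference. The
defaults (8 chains of 200,000 steps, all draws retained,
`burn_in_fraction = 0`) mirror full-scale practice; the desk-scale
benchmark uses 4 chains of 20,000 steps, which its convergence diagnostics
justify a posteriori. Because the re-centering shift cancels exactly
against `Z_1` and the prior depends only on differences, the likelihood
term is updated incrementally (one column per step) with periodic full
refreshes against floating-point drift; the draws are identical to direct
evaluation.

Summaries (`expected_profile()`) are node-wise means over all retained
draws, shifted so the minimum is zero, with 5/95 percent empirical
quantiles per node shifted by the same constant, a per-node split R-hat
(each chain halved; at or below 1.1 indicates convergence), and a natural
cubic spline through the node means with knots at the nodes.
`brute_force_posterior()` provides the independent oracle for `M <= 3`:
dense-grid quadrature over the gauge surface, vectorized and
self-converging under grid refinement in the regimes where the posterior
is effectively proper (see above).

## The forward simulator and the benchmark system

`generate_dataset()` draws, per particle: a node from the Boltzmann
weights of a ground-truth profile, an orientation uniform on SO(3)
(subgroup-algorithm sampler), an SNR log-uniform over its range, and a
defocus uniform over its range; it renders the node (one integrable 2D
Gaussian per bead, width `sigma = radius/sqrt(5)` so the second moment
matches a uniform ball, each bead integrating to its electron count),
applies a phase-contrast CTF with amplitude 0.1, B-factor 1 A^2 (read as
A^2 on dimensional grounds) and 300 keV electron wavelength, and adds
white Gaussian noise with variance `Var_circle(signal)/SNR` measured in a
central circle whose radius scales as 40/128 of the box side. Simulated
particles are centered; the likelihood's shift scan exists for real data,
and the desk-scale benchmark config turns it off. The full-scale reference
conditions (13,333 particles, 128-px boxes at 2.2 A/px, SNR log-uniform in
[0.001, 0.1], defocus in [0.5, 3] um) are the documented defaults of the
simulator; the benchmark spec scales them down.

The ground-truth profiles are closed-form: a 1D double well
(`ground_truth_1d()`, basins near `s = 6/19` and `s = 15/19`, the second
shallower by `ln 3`) and a 2D two-basin surface over a 20x20
conformer-model grid (`ground_truth_2d()`, barrier about 2 kBT) with the
three standard probe lines `CV1` (`u = v`, through both basins), `CV2`
(`u = 10`) and `CV3` (`v = 10`).

The benchmark molecule (`make_toy_rotor()`) is a 12-bead, two-arm V
(2.8 A bead spacing, 3 A bead radius, 60 electrons per bead -- residue
scale) whose mobile arm *bends progressively*: bead `k` of the arm
rotates by `angle * k / n_mobile`, like a curling finger, sweeping 120
degrees tip rotation across the default 10-node path, from a 150-degree
open V to a 30-degree closed one. The distributed bend is essential at
desk scale: a rigid arm rotation (the naive toy) is almost entirely
absorbed by the rigid-body pose marginalization -- a compensating global
rotation makes any two nodes nearly indistinguishable in projection -- and
controlled experiments showed chance-level node identification even with
noiseless images and dense orientation grids. A bend changes internal
geometry, which no rigid transform can mimic. For the same reason the
benchmark images use 1.2 A pixels in the 32-px box (the molecule spans
most of the field; the 2.2 A reference pixel belongs to 128-px boxes):
node discrimination scales with the number of informative pixels on the
molecule, and the 32-px budget is spent on the molecule rather than on
empty ice.

What the simulator does *not* emulate: structural noise (side-chain
flexibility, partial occupancy), solvent/ice background, detector MTF,
in-plane translations, dose and beam-induced motion, and off-path
conformations. Passing benchmarks therefore demonstrate the correctness
and calibration of the inference pipeline under its own forward model --
the closed-loop validation this package is designed for -- not performance
on real micrographs, where path quality and likelihood model mismatch
dominate.

## Numerical choices

* CTF convention: `CTF(k) = -(sqrt(1-A^2) sin(chi) + A cos(chi))
  exp(-B k^2/4)`, `chi = pi lambda_e d k^2`, `lambda_e = 0.0197 A`
  (300 keV). Simulation and likelihood share one implementation, so the
  convention cancels in the closed loop.
* Residual floor: the per-pose residual sum of squares is floored at
  `1e-12` times the image's centered sum of squares so exact noise-free
  self-matches stay finite.
* Degenerate templates (all-constant projections) are an error, never a
  silent zero.
* The noise-circle radius generalizes as `round(box * 40/128)` to keep the
  measured area fraction fixed across box sizes.
* Problem sizes: the shipped benchmark runs 1500 particles, a 1152-point
  coarse grid with a 6-point round-1 defocus grid, 10 pooled seeds with
  three 27-point refinement levels, and 4 chains of 20,000 steps -- sizes
  chosen so the full closed loop runs in minutes on one core while leaving
  clear convergence margins (split R-hat well under 1.1).
* Ties in orientation ranking break deterministically (first index), and
  every stage consumes a single seeded RNG stream in a fixed order, so a
  stack, likelihood matrix and posterior summary are bit-reproducible from
  the master seed.

## Known limitations

* The path is an input. Nothing here discovers or improves paths; a poor
  path (compare `CV2`/`CV3` against `CV1` on the 2D surface) produces a
  profile that underestimates barriers, which is a property of the
  projection, not a bug of the inference.
* The orientation quadrature at desk scale is approximate; its residual
  node-comparison error is controlled by the pooled-seed refinement but
  grows at the most compact path conformations, whose orientation
  landscapes are flattest.
* For `M <= 5` the printed smoothness prior is improper near flat
  profiles; conclusions there should rely on strongly informative data (as
  the oracle tests do).
* Real-data ingestion (MRC/MRCS + STAR) is deliberately minimal: mode-0/1/2/6
  MRC, single-value defocus per particle, no astigmatism or higher-order
  CTF terms.
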