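# cryofep

Bayesian inference of one-dimensional free-energy profiles (potentials of
mean force) along a conformational path, from stacks of individual cryo-EM
particle images.

## The problem

Cryo-EM particles are snapshots of single molecules drawn from the thermal
ensemble: the relative abundance of conformations encodes their free
energies. Given a discretized path `x_1 .. x_M` through conformation space
(path parameter `s_m = (m-1)/(M-1)`) and particles `w_1 .. w_I`, the
posterior over the profile `G(s)` (in units of kBT) is

    p(G | w)  ∝  p(G) · Π_i [ (1/M) Σ_m p(w_i | x_m) e^{-G_m} / Z_1 ],
    Z_1 = (1/M) Σ_m e^{-G_m},  p(G) = 1/𝒢²,  𝒢 = Σ_m (G_{m+1} - G_m)²,

where `p(w_i | x_m)` is the likelihood that image `i` is a projection of
node `m`, marginalized over orientation (two-round scheme: a coarse
uniform quaternion grid, then fine local grids around the best coarse
orientations), in-plane shift, defocus (Gaussian prior centered at the
particle's nominal value, scale 0.3 um), and — in closed form — the noise
variance, intensity normalization and offset. The posterior is sampled
with a random-walk Metropolis algorithm over the node values (single-node
proposals, `δg ~ U[-0.5, 0.5]` kBT, sum-zero gauge), yielding the expected
profile, node-wise 5–95% credible intervals, split R-hat diagnostics, and
a cubic-spline interpolant.

The package also contains the forward model needed for closed-loop
validation: residue-level bead models (one bead per residue, tabulated
radii and electron counts; `coarse_grain()` builds them from PDB atom
records), projection, CTF, SNR-calibrated Gaussian noise, and printed
ground-truth free energies (a 1D double well and a 2D two-basin surface
with the CV1/CV2/CV3 probe lines), plus a 3D-ensemble baseline
(Branduardi-style path-CV with an RMSD metric, `λ = 50 Å⁻²`, histogram +
Boltzmann inversion) for comparing image-based and conformation-based
profiles on the same path.

## Worked example

The desk-scale benchmark generates 1,500 synthetic particles of a 12-bead
two-arm molecule whose mobile arm bends by 120 degrees across a 10-node
path, populated by the 1D ground-truth double well; SNR is log-uniform in
[0.01, 0.1], defocus uniform in [0.5, 3] um, boxes 32 px at 1.2 A/px. It
then recomputes the two-round likelihood matrix and samples the posterior
with 4 chains of 20,000 steps:

```r
library(cryofep)
report <- run_benchmark(benchmark_spec(seed = 123))
report
#> <benchmark_report> rotor_1d_small
#>   RMSE (populated nodes): 0.298 kBT  coverage: 89%
#>   max split R-hat: 1.073   runtime: 411.8 s
round(report$summary$mean_profile, 2)
#>  [1] 3.89 1.76 0.54 0.00 0.76 1.13 1.10 1.37 1.32 2.54
round(report$truth, 2)
#>  [1] 4.49 1.88 0.39 0.00 0.68 1.67 1.38 1.09 1.29 1.98
```

Reading the output: `mean_profile` is the posterior-mean free energy at
the path nodes (min-shifted to zero, kBT) — compare with the ground truth
in `report$truth`; the RMSE is taken over the "populated" nodes (Boltzmann
population at least 5% of the maximum; node 1, at 4.5 kBT, holds under 1%
of the particles and cannot be pinned down by 1,500 images), `coverage` is
the fraction of those nodes whose truth lies inside the 5–95% credible
band, and an R-hat at or below 1.1 indicates the chains converged.

The same machinery runs from the shell:

```sh
Rscript inst/cli/cryofep.R simulate  --seed 7 --n-images 500 --out run/
Rscript inst/cli/cryofep.R likelihood --stack run/stack.mrcs --path run/path --out run/
Rscript inst/cli/cryofep.R sample    --llmat run/loglik.csv --chains 4 --steps 20000 --out run/
Rscript inst/cli/cryofep.R benchmark --name rotor_1d_small --out bench/
```

Stacks are MRC/MRCS (mode-2 float) with RELION-style STAR metadata; paths
are directories of per-node CSV coordinate files with a JSON manifest;
likelihood matrices and profile summaries are CSV with JSON config
sidecars.

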