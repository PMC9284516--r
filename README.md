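# oligodeer

DEER distance analysis and ensemble statistics for Cu(II)-labelled
amyloid oligomers.

## What it is for

Cu²⁺ ions bound to the His residues of amyloid-β(1-42) are native
paramagnetic labels: four-pulse DEER (double electron–electron
resonance) measures the dipolar coupling between pairs of such ions and
resolves Cu–Cu separations of 1–8 nm inside small soluble oligomers —
the species thought to carry most of the peptide's cytotoxicity. This
package is for spectroscopists and modellers who want to connect the
two ends of that experiment:

* **measurement side** — simulate four-pulse DEER time traces from a
  known distance distribution, correct the intermolecular background,
  and invert traces back to a distance distribution *P*(*r*) by
  Tikhonov regularization with non-negativity and L-curve selection of
  the regularization parameter;
* **model side** — generate and analyse structural ensembles of
  tetramers built as dimers of dimers (chains A–D): pair-class Cu–Cu
  distance distributions (intra-dimer AB/CD vs inter-dimer
  AC/AD/BC/BD), coordination-plane orientation statistics,
  Shrake–Rupley solvent-accessible surface areas with the
  SASA-ratio definition of an assembled tetramer, rank-based sample
  comparison and representative-configuration selection.

The scientific question the chain answers: is a measured *P*(*r*)
consistent with tetramers assembled from Cu-cross-linked dimers
(unimodal intra-dimer law near 2 nm) or from non-cross-linked dimers
(bimodal law with peaks near 1.0 and 1.6 nm)?

## The model in brief

Dipolar coupling of two electron spins at distance *r* and orientation
*θ*:

    ν(r, θ) = ν₀ r⁻³ (1 − 3 cos²θ),   ν₀ = 52.04 MHz nm³

Powder kernel (isotropic orientation average, Fresnel closed form):

    K(t, r) = ∫ cos(2π ν(r,θ) t) sinθ dθ,  K(0, r) = 1

Signal model with modulation depth λ and 3-D homogeneous background
rate *k*:

    V(t) = exp(−k t) · (1 − λ + λ ∫ p(r) K(t, r) dr)

Inversion (grid 1–8 nm, 201 points; L = discrete second derivative;
α from the L-curve corner):

    p̂ = argmin_{p ≥ 0} ‖K p − F‖² + α² ‖L p‖²

## Worked example

Simulate a measurement from a known truth, invert it, and compare a
synthetic tetramer ensemble against it:

```r
library(oligodeer)

truth <- gaussian_distribution(2.25, 0.2)          # nm
trace <- simulate_deer_trace(truth, deer_acquisition(seed = 7))
fit   <- deer_fit(trace)                           # background + L-curve + Tikhonov
summary(fit)
#> DEER Tikhonov inversion
#>   mode of P(r):      2.155 nm (grid step 0.035 nm)
#>   modulation depth:  0.289
#>   background rate:   0.000508 /ns
#>   alpha:             13.5
#>   form-factor RMSD:  0.06033
#>   peaks (nm):        2.16
```

The recovered mode (2.155 nm) sits within the grid resolution plus the
noise-induced uncertainty of the 2.25 nm truth; the modulation depth
and background rate land on the simulated values (0.3, 5e-4 /ns).

```r
ens <- generate_ensemble(ensemble_spec(n_configs = 200,
                                       intra_mean = 2.1, intra_sd = 0.2,
                                       seed = 1))
report <- run_model_experiment_comparison(ens, config = pipeline_config(seed = 1),
                                          run_filter = FALSE)
report
#> Model-experiment comparison (Cub ensemble)
#>   intra-dimer  Cu-Cu: 2.11 +/- 0.19 nm (n = 400)
#>   inter-dimer  Cu-Cu: 3.60 +/- 0.97 nm (n = 800)
#>   within-dimer plane-normal spread: 20.2 deg
#>   inverted mode 2.08 nm vs ensemble (intra-dimer) mode 2.05 nm
#>   overlap coefficient 0.798
```

Here the trace was forward-simulated from the ensemble's own
intra-dimer distance distribution and re-inverted: the 0.03 nm mode
difference and 0.8 overlap coefficient are the self-consistency of the
whole chain. The same report for a bimodal short-distance world
(`intra_mean = c(1.0, 1.6)`) returns an inverted mode below 1.9 nm
and/or a multimodality flag — the discrimination the method exists for.

A thin command-line front end over the same functions ships in
`inst/cli/oligodeer.R` (subcommands `gen-synthetic`, `simulate-deer`,
`invert-deer`, `analyze-ensemble`, `filter-tetramers`, `compare-dists`,
`pick-representatives`, `run-all`).

## Layout

* `R/` — forward model (`kernel.R`), trace I/O and simulation
  (`trace.R`), inversion and the `deer_fit` class (`inversion.R`,
  `nnls.R`), synthetic ensembles (`ensemble.R`, `pdb.R`), geometry
  (`geometry.R`), SASA (`sasa.R`), statistics (`stats.R`),
  orchestration (`pipeline.R`)
* `vignettes/oligodeer-methods.Rmd` — model assumptions, parameter
  choices, numerical decisions, limitations
* `tests/testthat/` — unit, property and acceptance tests with
  independent oracles (Monte-Carlo kernel average, exhaustive QP
  enumeration, closed-form surface areas)
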