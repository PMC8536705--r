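# oxyuq — variance-based uncertainty mapping for ocean oxygen projections

Projections of ocean deoxygenation hinge on biogeochemical parameters that
contemporary observations cannot constrain: the sinking speed of detritus
*w*, the vertical background diffusivity *κ* and the maximum phytoplankton
growth rate *a*. oxyuq is an R package for asking, gridpoint by gridpoint,
*which* of these parameters a projection's uncertainty comes from — and
therefore *where* in the ocean observations would be most valuable for
constraining it. It is aimed at ocean biogeochemical modellers running
perturbed-parameter ensembles.

## Method

The three parameters are modelled as Gaussians (relative standard
deviation 50% for *w* and *κ*, 25% for *a*; values below a 5%-of-mean
floor are truncated). The ensemble design is a full tensor Gauss–Hermite
quadrature, 5 points per dimension = **125 runs**. For each gridpoint the
output Y — the water-column O₂ minimum, or its projected change — is
expanded in orthonormal (probabilists') Hermite polynomials up to total
order 3,

    Y(ξ) ≈ Σ_α c_α ψ_α(ξ),   c_α = Σ_q w_q Y_q ψ_α(ξ_q),

a spectral projection that is exact on the tensor design for the retained
basis. The variance D = Σ_{α≠0} c_α² then splits exactly into Sobol
fractions: main effects S_w, S_κ, S_a, pairwise interactions S_wκ, S_wa,
S_κa and the triple S_wκa, which sum to 100%. On top of the
decomposition the package computes the mapping diagnostics: ensemble mean
change, noise-to-signal ratio (sd/|mean| of the change, %), contemporary
spread and coefficient of variation, a low-variance mask (sd < 6% of the
mean), regional averages of the Sobol fractions, and benchmarking scores
that flag gridpoints with high spread attributable predominantly to one
parameter.

A synthetic multi-column ocean (steady-state diffusion–remineralization
columns in three regimes: deep-water-formation, tropical
oxygen-minimum-zone, intermediate) generates ensemble archives with the
same structure as a gridded Earth-system-model archive — 125 runs × N
columns × time slices 1850/2000/2100 — so the whole pipeline runs
end-to-end in seconds. External archives with the same schema (NetCDF,
run × gridpoint × time-slice) flow through `read_archive()` +
`analyse_archive()` without the toy model.

## Worked example

```r
library(oxyuq)
report <- run_pipeline(default_config(seed = 42))
print(report)
```

prints (abridged):

```
Ensemble: 125 runs x 100 columns x 3 time slices

Regional Sobol fractions of the projected change (%):
       region n_gridpoints  S_w S_kappa   S_a S_w_kappa
    deepwater            0   NA      NA    NA        NA
 intermediate           40 63.9    25.5 1.068      8.92
     tropical           40 43.4    49.1 0.927      5.90

Diagnostic maps over 100 gridpoints
  mean change (1850 -> 2100): -30.50 .. -4.76 mmol m-3
  noise-to-signal: median 35.1% (0 undefined)
  contemporary CV: median 28.4%; 20 gridpoints masked

Benchmarking scores (spread threshold 61.9 mmol m-3):
   parameter gridpoint     score   spread
1          w        24 66.951473 66.78938
6      kappa        57 41.127612 65.80526
```

Reading: every column deoxygenates by 2100. The deep-water-formation
regime changes most (about −28 mmol m⁻³) but its variance is so small
that all 20 of its columns fall under the low-variance mask — its
projection is insensitive to the three parameters, so its regional Sobol
row is deliberately missing rather than zero. The tropical regime changes
least in absolute terms but carries the highest noise-to-signal, and its
change variance splits mainly between *w* (43%) and *κ* (49%). The
benchmarking listing points to tropical columns as the places where
contemporary observations would best constrain *w* and *κ*.

Stage-by-stage runs (`design`, `simulate`, `fit`, `sobol`, `maps`,
`report`, `all`) are available through the stage functions or the thin
shell wrapper `inst/cli/oxyuq.R`; all products are NetCDF plus TSV
tables, and a seeded run is byte-reproducible.

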