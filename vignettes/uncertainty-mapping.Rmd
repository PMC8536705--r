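---
title: "Mapping parametric uncertainty in ocean oxygen projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping parametric uncertainty in ocean oxygen projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyuq)
```

## The problem

Projections of ocean deoxygenation from biogeochemical models depend on
parameters that observations cannot pin down: the sinking speed of
detritus $w$, the vertical background diffusivity $\kappa$ and the
maximum phytoplankton growth rate $a$ all shape subsurface oxygen, yet
their joint effect on contemporary fields is nearly degenerate. oxyuq
quantifies, gridpoint by gridpoint, how much of the ensemble variance of
a projected quantity — here the water-column oxygen minimum — each
parameter is responsible for, and uses those maps to identify
*benchmarking regions*: places where the contemporary ensemble spread is
both large and attributable predominantly to a single parameter, so that
observations taken there would constrain that parameter and thereby
tighten projections elsewhere.

## Probabilistic model of the parameters

Each parameter is modelled as Gaussian in physical units, specified by a
mean and a relative standard deviation: 50% of the mean for $w$ and
$\kappa$, 25% for $a$. Draws or collocation nodes that fall below a
floor (default 5% of the mean) are clipped there, because negative or
near-zero rates are unphysical. The floor placement is a package choice:
at 5% of the mean it perturbs less than 3% of the prior mass per
parameter (normal CDF at $-1.9\sigma$ for the 50% parameters), and a
test verifies that Sobol indices of smooth outputs move by less than one
percentage point when the floor is switched off. Truncation is applied
to the collocation *nodes only* — quadrature weights are left unchanged —
which corresponds to running a designed simulation whose inputs were
clipped, rather than re-deriving a quadrature for the truncated measure.

The standardized coordinate $\xi = (x - \mu)/(\sigma_{rel}\,\mu)$ maps
physical values to the unit-normal space in which the polynomial basis
lives.

## Collocation design and Polynomial Chaos Expansion

The ensemble design is the full tensor product of one-dimensional
Gauss rules for the standard-normal weight, five points per dimension by
default, hence $5^3 = 125$ runs. Nodes and weights come from the
Golub–Welsch eigendecomposition of the Jacobi matrix of the
probabilists' Hermite recurrence; a five-point rule integrates
polynomials to degree nine exactly, comfortably above anything a
third-order expansion needs.

Each scalar output $Y$ (per gridpoint) is expanded in orthonormal
Hermite polynomials
$\psi_\alpha(\xi) = \prod_i \mathrm{He}_{\alpha_i}(\xi_i)/\sqrt{\alpha_i!}$
over all multi-indices with total order $\le 3$ (20 basis terms). The
coefficients are obtained by *discrete projection* on the design,
$c_\alpha = \sum_q w_q \, Y_q \, \psi_\alpha(\xi_q)$, not by regression:
on a full tensor quadrature the projection is exact for the retained
basis, the constant coefficient is exactly the weighted ensemble mean,
and any output that is itself a cubic polynomial is reproduced at the
nodes to machine precision. Order 3 is the default because in this class
of application higher-order contributions fall below numerical
significance; `max_order` is configurable but no automatic order
selection is attempted.

## Sobol decomposition

For an orthonormal expansion the output variance is
$D = \sum_{\alpha \neq 0} c_\alpha^2$, and the fraction attributable to
a parameter subset $U$ sums the squared coefficients whose non-zero
index positions equal $U$ exactly. This yields three main effects, three
pairwise interactions and the triple interaction, in percent; they
always add to 100% where $D > 0$, and that completeness is asserted on
every synthetic run. The triple interaction is computed and reported
even where a presentation might omit it, precisely so the completeness
identity can be checked. Gridpoints with (numerically) zero variance
get `NA` fractions, never 0 — a zero would falsely assert insensitivity.
Numerical zero is judged relative to the squared mean coefficient
(threshold $10^{-24}$), which absorbs projection roundoff of constant
fields.

## The synthetic column ocean

The generator replaces a full Earth-system model with many independent
water columns, each solved to steady state at three time slices
(preindustrial 1850, contemporary 2000, projected 2100):

$$\frac{d}{dz}\Big[(\kappa + s\,\kappa_{dyn}(z))\,\frac{dO_2}{dz}\Big]
  = J(z), \qquad O_2(0) = O_2^{sat}(T_s), \qquad
  \left.\frac{dO_2}{dz}\right|_{z=H} = 0,$$

with linearized solubility $O_2^{sat} = S_0 - S_1 T$, export flux
$F_0 = F_{max} L\, a/(a + K_a)$, an exponential remineralization profile
$J(z) = (r/w) F_0 e^{-rz/w}$ (consumption integral
$F_0(1 - e^{-rH/w})$), a two-layer dynamic mixing profile
$\kappa_{dyn}(z)$ and a per-slice stratification factor $s \in (0,1]$.
Warming acts through the solubility term and through $s$; a small
per-slice production multiplier represents warming-driven nutrient
decline. The discretization is centred second-order finite volumes with
*harmonic* averaging of cell diffusivities at interfaces — necessary
because $\kappa_{dyn}$ jumps at the mixed-layer base, and harmonic
averaging handles a jump at a face exactly (with arithmetic face values
the scheme degrades to first order and the tropical minimum shifts by
about 2% at the default resolution). Summing the discrete equations
makes the surface influx balance total consumption to machine precision,
which the tests assert at $10^{-8}$ relative on every column. Because
consumption is oxygen-independent, the linear solve can go negative;
profiles are clipped at zero afterwards and flagged, so smooth-response
checks can exclude clipped columns. The default grid is $H = 1000$ m at
$\Delta z = 10$ m; halving $\Delta z$ moves minima by well under 1%.

### Regimes and their rationale

Three regime families give the spatial contrast the diagnostics must
detect, with defaults chosen once from the phenomenology they are meant
to emulate:

* **deepwater** (20% of columns): cold (2 °C preindustrial, +4.5 °C by
  2100), vigorous convective mixing over the top 800 m
  ($\kappa_{ml} = 10^{-2}$ m² s⁻¹), low production, strong
  stratification loss ($s$: 1 → 0.55). Dynamic mixing exceeds the
  background $\kappa$ by orders of magnitude, so the oxygen minimum
  tracks solubility: the projected change is large (about −28 mmol m⁻³)
  but almost independent of $(w, \kappa, a)$.
* **tropical** (40%): warm (24 °C, +1.5 °C), mixing confined to a 50 m
  surface layer, ventilation at depth carried by the background
  $\kappa$ alone. The minimum is low (an oxygen-minimum-zone analogue)
  and responds strongly to all three parameters; the projected change is
  small in absolute terms, so the noise-to-signal ratio is high.
* **intermediate** (40%): temperate values between the two.

Per-column jitter (uniform, ±10–15% on the production factor, ±0.3 °C
on temperature) makes columns within a regime distinct while keeping
the generator bitwise-deterministic given its seed — the single seed in
the pipeline; design, solver and analysis are fully deterministic.

The tropical production decline (multiplier 0.97 by 2100) is kept small
relative to the solubility loss so that *every* column deoxygenates
under warming, matching the scenario-direction property the analysis
assumes; this was checked analytically against the solubility slope
before the defaults were frozen. One structural difference from richer
ecosystem models is acknowledged: with a saturating export law the
growth rate's effective perturbation is only
$K_a/(a+K_a) \cdot 25\% \approx 8\%$, so $a$'s main effect stays in the
percent range everywhere rather than dominating any regime. The toy
model is explicitly not an emulator of any particular Earth-system
model: what transfers is the statistical structure (regime-dependent
sensitivity patterns), never field values. Likewise, independent columns
cannot express lateral transport, so any cross-region imprint of
parameter uncertainty is outside what passing tests demonstrate about
real archives.

## Diagnostics

All ensemble statistics use the quadrature weights by default — the 125
members are collocation nodes, not equiprobable samples, and unweighted
statistics over-count the tail nodes; an `unweighted` switch exists for
comparison with naive ensemble practice. The maps are:

* **mean change** of the minimum, 2100 minus 1850, per gridpoint;
* **noise-to-signal**: ensemble sd of the change over the magnitude of
  the mean change, in percent, with an $\varepsilon$-guard
  ($10^{-6}$ mmol m⁻³) returning `NA` rather than infinities where the
  mean change vanishes;
* **contemporary spread** (sd, mmol m⁻³) and **coefficient of
  variation** (%) of the year-2000 minimum;
* **low-variance mask**: gridpoints where the ensemble sd falls below
  6% of the local mean, where sensitivity fractions would be noise;
* **regional averages**: arithmetic means of the per-gridpoint
  percentage indices over unmasked gridpoints of each region
  (averaging percentages matches the tabulated-average convention;
  pooling variances first is a deliberate non-default), with a
  partition-consistency identity tested: size-weighted regional means
  recover the global mean;
* **benchmark scores**: a parameter's contemporary main effect at
  gridpoints whose spread exceeds a quantile (default: median over
  unmasked gridpoints) of the spread distribution, missing elsewhere;
  the top-scoring gridpoints per parameter are the benchmarking
  regions. The median threshold is a free choice — any "preferably
  high spread" rule fits here — and is configurable.

The package also reports the Spearman rank correlation between the
contemporary coefficient of variation and the projected noise-to-signal
ratio: nothing forces these to coincide spatially, and the number makes
the degree of decoupling explicit (no particular value is asserted; on
the default synthetic world the two happen to be strongly rank-related
because both are driven by the same regime contrast).

## A worked run

```{r pipeline, eval = FALSE}
report <- run_pipeline(default_config(seed = 42))
print(report)
report$regional            # regional Sobol table of the projected change
report$benchmark$top       # benchmarking columns per parameter
```

Problem sizes throughout the package default to the full study
configuration — 125 collocation runs, 100 columns, three slices — which
the steady-state tridiagonal formulation solves in a few seconds; the
test suite uses 27-run ($3^3$) designs and 8–30 columns where full
resolution adds nothing to the property under test.

## Verification strategy

Every layer is checked against something it was not built from:
quadrature nodes against an independently computed Gauss–Hermite rule;
projections against closed-form Hermite expansions and a Monte-Carlo
projection oracle; Sobol indices against analytic variance ratios and a
Saltelli-type Monte-Carlo estimator (main effects via the
$f_B(f_{AB_i} - f_A)$ elementary terms, pairwise via closed two-way
variances from $f_{AB_i} f_{BA_j}$, agreement required within three
Monte-Carlo standard errors on random cubic polynomials, for which the
spectral result is exact); the column solver against its own discrete
flux-balance identity, analytic limits and grid refinement. External
archives enter through a schema-validated NetCDF reader with declared
unit conversions, so the analysis half of the pipeline never depends on
the synthetic generator.

## Limitations

* Steady-state columns: no transient ventilation memory, no seasonal
  cycle, no lateral transport.
* Oxygen-independent remineralization: suboxic columns are clipped and
  flagged rather than modelled with Michaelis–Menten oxygen limitation.
* The three-parameter space is the point of the method, but real
  model uncertainty has many more dimensions; a tensor design does not
  scale past a handful of parameters.
* Sensitivity maps inherit the PCE's smoothness assumption; outputs
  with an atom at zero (heavily clipped columns) are represented in a
  least-squares sense by the cubic expansion.
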