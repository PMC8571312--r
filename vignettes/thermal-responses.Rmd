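---
title: "Models and methods for phytoplankton thermal responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for phytoplankton thermal responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytotherm)
```

This vignette is the package's account of its science: the models it
fits, the assumptions behind them, the tunable parameters and why their
defaults are what they are, and the numerical decisions that a user
auditing results would want spelled out.  Nothing stated here as a result
goes beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## The strain-level model

A strain's thermal performance curve is the Norberg-type reaction norm

$$\mu(T) = a\,e^{bT}\left[1 - \left(\frac{T - z}{w/2}\right)^2\right],$$

the product of an exponential envelope and a downward parabola.  The
parabola fixes the thermal niche: growth is positive exactly on
$(z - w/2,\, z + w/2)$, so $T_{min} = z - w/2$ and $T_{max} = z + w/2$
and the niche width is $w$.  For $b > 0$ the optimum sits above the
midpoint; `derive_traits()` uses the closed form
$T_{opt} = z + (w/2)\,u^*$ with
$u^* = (-2 + \sqrt{4 + b^2 w^2})/(bw)$, the admissible root of the
first-order condition (and $u^* = 0$ when $b = 0$).  The tests verify
this closed form against a dense-grid argmax to $10^{-3}$ °C over $10^4$
random parameter draws.

The curve is deliberately allowed to go negative outside the niche: a
fitted decline rate is information, and clamping inside the model would
distort the likelihood.  Viability semantics (projection, breadth) clamp
at the point of use instead.

### Fitting

`fit_reaction_norm()` maximises a Gaussian likelihood with a constant,
estimated noise scale.  With constant noise the MLE is the least-squares
fit, and the profile scale is $\hat\sigma = \sqrt{SSE/n}$.  Constant
(rather than proportional) noise keeps the likelihood finite at
zero-growth observations, which real compilations contain in numbers.

This curve family is multimodal in its parameters, so the optimiser runs
a deterministic multi-start over $z \in \{5, 10, \ldots, 35\}$ °C,
$w \in \{10, 20, 30, 40\}$ °C and $b \in \{0, 0.05, 0.1\}$ °C⁻¹, with the
scale start taken from the largest observed rate.  Each start is refined
by L-BFGS-B with an analytic gradient on $(\log a, b, z, \log w)$ — the
log transforms make positivity structural — inside the boxes
$b \in (-0.2, 0.4)$ °C⁻¹, $w \in (2, 80)$ °C, $z \in (-20, 60)$ °C,
which bracket every plausible marine strain.  The best negative
log-likelihood wins; exact ties break towards the smaller width, then the
flatter exponential, so refits are reproducible.  A fit requires at least
4 distinct assay temperatures (configurable) and at least one positive
rate.

On noise-free data the generating parameters are recovered to optimiser
tolerance (about $10^{-6}$ here; the tests assert $10^{-3}$).  Under 10 %
observation noise the precision of $\hat T_{opt}$ is governed by the
curvature at the peak: for a narrow-niche strain ($w = 9$ °C) ten
observations put 97 % of estimates within ±0.5 °C of the truth, while for
a wide, flat curve ($w = 24$ °C) the same design spreads roughly twice as
far.  Users comparing optima across strains should expect trait
uncertainty to scale with niche width.

### Breadth, skew and quality control

`performance_breadth()` solves $\mu(T) = f\,\mu_{max}$ (default
$f = 0.2$) on each limb by bisection to $10^{-8}$ °C, and reports the
limb slopes $(1-f)\,\mu_{max}/|T_{opt} - T_{lim}|$ as magnitudes.  For
any $b > 0$ the descending slope exceeds the ascending one — the
left-skewed shape characteristic of thermal performance curves — and the
tests check this across a parameter grid.  The 20 % threshold follows
field observations of species occurring at temperatures where they attain
roughly a fifth of their maximal growth; it is configurable.

An upper thermal limit is only as good as the data constraining it, so
`qc_tmax()` passes a fit only when (i) at least one measurement lies
above the fitted optimum and (ii) the fitted $T_{max}$ extrapolates at
most 5 °C (configurable) beyond the warmest assay.  The cited
compilations apply a QC rule of this kind without printing it; the
two-part rule here is this package's operationalisation, and the margin
is exposed precisely because it is a judgement call.  Strains failing QC
are excluded from capacity analyses but still contribute measurements to
the group envelopes, which do not depend on per-strain limits.

## Group-level temperature dependencies

The maximum growth rate of a functional type is modelled as
$\mu_{max}(T) = a\,e^{bT}$, fitted as the 99th regression quantile of
$\ln \mu$ on $T$.  Fitting an extreme quantile tracks the envelope of the
compilation while using every measurement — unlike mean (OLS) fits,
which estimate the median response, or approaches that keep only each
species' peak rate.  Nonpositive rates cannot be log-transformed and are
dropped first (the count is kept on the object); measurements are pooled
unweighted across strains within a group.

### The exact solver

The pinball loss $\sum_i \rho_\tau(y_i - \alpha - \beta x_i)$ is a linear
program whose optimum interpolates two data points.  The solver profiles
out the intercept — for fixed slope the optimal $\alpha$ is the $\tau$-th
sample quantile of $y - \beta x$ — leaving a convex piecewise-linear
function of $\beta$ minimised by golden-section search (bracket
$\pm 2$ °C⁻¹, widened automatically if pinned), followed by a polish over
lines through the eight smallest-residual points that restores the exact
vertex.  Tests verify loss-optimality against exhaustive two-point search
on every instance up to $n = 12$ and on outlier constructions.  One
consequence worth knowing: at $\tau = 0.99$ a single high outlier only
attracts the fitted envelope when $n < 1/(1-\tau) = 100$; in larger
samples the asymmetric loss already tolerates one point above the line.

### Q10, activation energy, and the reference temperature

The temperature coefficient is $Q_{10} = e^{10b}$ exactly.  The
activation energy converts the same slope to Arrhenius form,
$E_a = b\,k_B\,T_{ref}^2$ in eV with $k_B = 8.617\times10^{-5}$ eV K⁻¹.
The reference temperature is a convention; this package fixes
$T_{ref} = 273.15$ K because that choice reproduces the published
$(Q_{10} \rightarrow E_a)$ pairs for marine compilations (1.88 → 0.41,
2.13 → 0.49, 1.67 → 0.33 eV) to the printed two decimals, which the
acceptance test asserts.  Published coefficient pairs can be wrapped
directly with `exponential_dependency(a, Q10 =)` for evaluation with
`evaluate_mu_max()`; note that compilations fitted under a different
(e.g. Boltzmann–Arrhenius) parameterisation will not satisfy
$\mu_{max}(20) = a\,Q_{10}^2$ and should not be used as arithmetic
oracles.

### Uncertainty

`bootstrap_dependency_ci()` offers two schemes.  The Markov chain
marginal bootstrap (default, 10 000 iterations nominally) resamples the
per-observation score contributions and re-solves one coordinate at a
time — each update is a weighted-quantile step — which makes it cheap on
large compilations.  The pair bootstrap refits the exact solver on
resampled cases and serves as the slower cross-check.  Intervals are
percentile intervals of the draws; the curve band is pointwise (not
simultaneous) and centred at the bootstrap median.  A coverage simulation
in the acceptance suite (500 datasets of $n = 300$ at $\tau = 0.9$, 500
chain steps each) keeps empirical coverage of the true slope between 90
and 99 % for the nominal 95 % interval.  A caveat: at $\tau = 0.99$ the
estimating equations are driven by a handful of envelope points, and MCMB
intervals for groups of only a few hundred measurements can be wide and
off-centre; for small groups prefer the pair bootstrap, or read the MCMB
band as qualitative.

`compare_pft_interaction()` fits one common envelope (M0) versus
group-specific envelopes (M1) and compares them by
$AICc = 2k - 2\hat L + 2k(k+1)/(n-k-1)$, where $\hat L$ is the maximised
asymmetric-Laplace log-likelihood at level $\tau$ (scale profiled as
total loss over $n$) and $k$ counts regression coefficients plus one
scale.  The quasi-likelihood treatment is the standard device for
information criteria on quantile fits; it ranks models, it does not test
them.  `contrast_coefficients()` compares bootstrapped groups pairwise by
percentile intervals on coefficient differences.

## Thermal capacity

Habitat temperature is the baseline-epoch SST of the grid cell containing
the isolation point (nearest-cell, not interpolated — at the resolutions
in use the difference is below the uncertainty of an isolation record);
isolation points falling on land take the nearest ocean cell within a
3-cell window, and the substitution is recorded.  The three metrics are
subtractions against the fitted traits: $TSM = T_{opt} - T_{hab}$,
$WT = T_{max} - T_{hab}$, and the distance to growth equivalence
$DGE = T_{\mu equiv} - T_{hab}$, with $T_{\mu equiv}$ the unique
temperature above the optimum where growth returns to its habitat value,
found by bisection to $10^{-8}$ °C (the curve is strictly decreasing
there, so the root is guarded).  Edge cases are part of the definition:
$DGE = 0$ whenever $T_{hab} \ge T_{opt}$ (the strain is already past its
optimum), and when the habitat sits at or below the cold niche limit the
equivalence collapses onto $T_{max}$, so $DGE = WT$.  On the ascending
limb $TSM \le DGE \le WT$ always, and for a symmetric curve ($b = 0$)
$DGE = 2\,TSM$; both identities are exercised over $10^4$ random draws.
Only strains of known origin whose $T_{max}$ passed QC enter the
capacity table.

Group comparisons use the tie-corrected Kruskal–Wallis statistic with the
epsilon-squared effect size $\epsilon^2 = H/(n-1)$ — the standard
epsilon-squared form; its interval comes from a stratified bootstrap
(1000 resamples, seeded).  Dunn's pairwise $z$ tests use the pooled
tie-corrected rank variance and are reported unadjusted by default, with
`p.adjust` methods available as a switch: reference analyses in this
area report Dunn p-values near the 0.05 boundary without an adjustment,
so the unadjusted value is the comparable one and the choice is left
explicit.  Zonal statistics use the sample (n−1) standard deviation.

## Projection

Each strain's curve is evaluated cellwise on both epoch grids; growth is
zeroed outside the niche, a cell is viable when growth is at least 20 %
of that strain's maximum (inclusive), and proportional change
$(\mu_f - \mu_p)/\mu_p$ is defined only where both epochs are viable —
the threshold guarantees the denominator.  Group maps take the cellwise
median over contributing strains (midpoint convention for even counts),
chosen over the mean for robustness to outlying strains and over the
maximum for sample-size insensitivity.  Zonal summaries average the
median map across defined longitudes per latitude (mean ± sample sd); an
alternative — averaging per-strain zonal means before the median — is
not implemented as the default because the median map is the quantity
being summarised.  Cell areas follow
$A(\phi) = R^2\,\Delta\lambda\,\Delta\phi\,\cos\phi$ with $R = 6371$ km;
on a full 1.25° grid the cells tile the sphere to within 0.5 %, which the
tests check.  Range expansion is the area newly viable in the future;
the expansion percent divides by each strain's own past viable area and
is then averaged over strains (strains with no past range are excluded
from the percent and reported) — the absolute km² figure is the primary
quantity, the percent an interpretation.  Range loss is computed
symmetrically even though expansion is the headline.  Longitudes use
[−180, 180) cell-centre registration throughout.

With no netCDF reader among this package's dependencies, grids live in a
plain `sst_grid` object (axes, value matrix, ocean mask, epoch label)
with a long-format CSV round-trip; adapting a netCDF source is a
five-line matter of passing its axes and matrix to `sst_grid()`.

## The synthetic generator

`simulate_strain_dataset()` emulates the statistical shape of a thermal
growth compilation: strain counts in the four-group proportions
30/32/135/46, per-strain parameters drawn from group distributions chosen
to echo the published contrasts — cyanobacteria with steep envelope
slopes ($b \approx 0.076$ °C⁻¹), low intercepts and warm narrow niches;
diatoms numerous, fast-growing, wide-niched; dinoflagellates flat and
slow; coccolithophores temperate — with assay designs spanning both limbs
(ten temperatures from just above $T_{min}$ to just past $T_{max}$) and
Gaussian observation noise at 10 % of each strain's true maximum.
Observed rates are floored at zero because real growth tables do not
report negative specific rates; the floor mildly truncates noise near the
niche edges and is the reason trait-recovery tests that probe the fitter
itself simulate without it.  The cyanobacterial niche midpoint
(23.5 ± 2.5 °C) is set so that equatorial habitats sit at or above
strain optima under the default SST scenario — the premise of the
warming-response sign structure the projection tests check.

`simulate_sst_fields()` builds the canonical zonal baseline
$T(\phi) = T_{eq} - \Delta T_{pole}\sin^2\phi$ (defaults: 28 °C equator,
30 °C contrast) plus cellwise noise, and a deterministic warming profile
interpolating equatorial and polar amplitudes (defaults 2.5 and 5 °C —
the scale separating a mid-20th-century baseline from an end-of-century
high-emission epoch, with polar amplification).

What the generator does **not** emulate, and what passing tests therefore
do not demonstrate about real data: correlations among a strain's
parameters (real $\mu_{max}$ and niche position covary), latitudinal
sampling bias, between-laboratory methodology differences, digitisation
error, real coastlines and land masks, seasonal habitat variability, and
the spread of a climate-model ensemble.  The synthetic scenario supports
property and sign-structure checks, not quantitative reproduction of
published projection magnitudes, which require the deposited compilation
and CMIP ensemble fields as inputs.

## Filtering conventions

Three compilation rules are encoded, each independently toggleable:
dropping measurements made under continuous light (24 h day length) at or
below 80 µmol photons m⁻² s⁻¹, dropping nitrogen-fixing cyanobacteria,
and dropping fluctuating-nutrient studies.  The light rule fires only on
measured metadata — records lacking light or day-length annotations are
retained, since silently excluding sparsely annotated studies would bias
a compilation — and acts per measurement, not per strain: a strain
assayed at several light levels keeps its compliant measurements.  Every
applied rule appends a provenance row (rule, before, removed, after) to
the dataset, so a compilation documents its own history; the rules are
idempotent and commute.

## Problem sizes and budgets in the tests

The suite chooses simulation sizes that make the statistical assertions
sharp but keep a full run in a few minutes on one core: 500 datasets for
the bootstrap-coverage band, $10^4$ draws for the trait and capacity
invariants, $N = 1500$ for envelope recovery (within 5 %), 200
replicates for noisy trait recovery, and a 2.5° grid with the full
243-strain ensemble for the projection sign structure.  The worked
fixture freezes results from brute-force oracles (exhaustive pair search,
dense-grid argmax, fine-scan roots, direct cell loops) computed once,
so an end-to-end regression is checked against numbers that never passed
through the package's own solvers.

## Known limitations

Temperature is the only driver: no nutrient or light co-limitation,
competition, dispersal kinetics or transient dynamics.  Capacity metrics
assume a static organism at its isolation site.  The quantile envelope
needs substantial data — below a few hundred positive rates per group
the 99th quantile and especially its MCMB interval are fragile.
Alternative thermal performance shapes (Sharpe–Schoolfield, Gaussian,
Brière) and model selection among them are out of scope, as are
Boltzmann–Arrhenius fits on per-species maxima and below-optimum OLS
fits, which this package's quantile approach is designed to replace.
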