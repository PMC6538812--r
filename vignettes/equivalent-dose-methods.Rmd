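---
title: "Methods: the equivalent-dose treatment-response framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the equivalent-dose treatment-response framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqdose)
```

## The problem

Conventional dose-response assays summarize treatment by the extracellular
drug concentration applied to a well. That number conflates what the assay
is actually probing: how much drug gets into the cell and binds its target
(pharmacokinetics, PK) and how the cell population responds to the bound
drug (pharmacodynamics, PD). Two cell lines that differ only in the
expression of an efflux pump will show very different extracellular EC50s
while being equally sensitive to the drug that actually reaches their DNA.

`eqdose` implements a mechanistic framework for doxorubicin treatment of
cultured tumor cells that separates the two: a compartmental uptake model
whose output — the peak nucleus-bound drug concentration, called the
**equivalent dose** — is a biophysically grounded measure of delivered
effect, plus inverse procedures that use it to quantify how co-administered
sensitizers (efflux-pump inhibitors, DNA-repair inhibitors) shift single
rate constants, using only population-scale cell-count data.

## Drug uptake model

Doxorubicin moves between three compartments — extracellular (`C_E`), free
intracellular (`C_F`) and nucleus-bound (`C_B`), all in nM:

$$
\begin{aligned}
\dot C_E &= k_{FE}\,C_F/v - k_{EF}\,C_E\\
\dot C_F &= k_{EF}\,v\,C_E - (k_{FE}+k_{FB})\,C_F\\
\dot C_B &= k_{FB}\,C_F
\end{aligned}
$$

with influx `k_EF`, efflux `k_FE` and net binding `k_FB` (all 1/h), and
`v = v_E/v_I` the extracellular-to-intracellular volume ratio. `k_FB` is a
*functional* net binding rate: it lumps DNA binding with repair, which is
exactly why a DNA-repair inhibitor registers as an increase in `k_FB`.
Saturable transport, drug metabolism and dissociation from DNA are outside
the model's scope. The volume-weighted total `v C_E + C_F + C_B` is
conserved between media changes, which is the standard solver diagnostic
(`pk_total_mass()`).

A treatment schedule is a sequence of instantaneous media replacements:
each event resets `C_E` while `C_F`, `C_B` are continuous. Between events
the system is linear with constant coefficients, so `simulate_pk()` solves
each segment *exactly* through an eigendecomposition of the 3x3 system
matrix (the eigenvalues are provably real; a Pade scaling-and-squaring
exponential covers the measure-zero defective cases). An adaptive `lsoda`
path is kept as an independent cross-check; the two agree to better than
1e-6 relative in the test suite, and per-segment mass drift of the exact
path is at the 1e-15 level.

**Equivalent dose.** `equivalent_dose()` returns the maximum of `C_B` over
the course. Since `dC_B/dt = k_{FB} C_F \ge 0`, `C_B` is non-decreasing and
the maximum sits at the end of the simulated window. Because a small amount
of free drug keeps binding after washout, the simulation is extended past
the horizon until `C_F` falls below 1e-6 of its peak (capped at 500 h; the
segment solution is exact, so the extension costs only the stopping check).
The tail is only applied when the course actually ends in a washout —
otherwise extending would silently simulate a longer treatment.

## Population response model

Cell counts follow logistic growth with a time-dependent death rate
switched on at treatment time `t = 0`:

$$
\frac{dN}{dt} = \bigl(k_p - k_d(t)\bigr)\,N\Bigl(1-\frac{N}{\theta}\Bigr),
\qquad
k_d(t) = (1-\lambda)\,k_{d,a} + \lambda\,k_{d,b}\,r\,t\,e^{1-rt} \;(t\ge 0)
$$

The constant kernel `k_d_a` represents an immediately induced, stable death
rate (apoptosis-like); the transient kernel rises to its maximum `k_d_b`
at `t = 1/r` and decays, allowing recovery (mitotic-catastrophe-like, a
protracted process — with `r` in the 0.02–0.08/h range the peak falls 12–50
hours after treatment). `theta` is the plate's carrying capacity and acts
as an absorbing ceiling.

Two deliberate choices here:

* **The kernel weight `lambda` is fixed, not fitted.** The likelihood
  depends on `(lambda, k_{d,a}, k_{d,b})` only through the products
  `(1-\lambda)k_{d,a}` and `\lambda k_{d,b}` — three parameters, two
  degrees of freedom. Fitting all three is structurally non-identifiable,
  so `fit_pd()` holds `lambda` at a configured value (default 0.5) and
  estimates the rate amplitudes.
* **The solver is a closed form.** Substituting `y = 1/N` linearizes the
  equation and its forcing integral collapses analytically, giving the
  time-changed logistic
  `N(t) = \theta N_0 e^{G(t)} / (\theta + N_0(e^{G(t)}-1))` with
  `G(t) = \int_0^t (k_p - k_d)`, where `G` is available in closed form for
  this kernel. `simulate_counts()` evaluates this exactly by default and
  keeps `lsoda` (rtol 1e-10) as the cross-checked adaptive path; they agree
  to ~3e-10 relative. The exact path is what makes the fitting and the
  end-to-end studies fast.

## Fitting

All three fitters (`fit_pk`, `fit_pd`, `hill_fit`) are bounded nonlinear
least squares (Levenberg–Marquardt via `minpack.lm`), with a
Latin-hypercube multistart (log-uniform over the bounds) plus a
data-driven starting guess, deterministic given a seed. 95% confidence
half-widths come from the local curvature (`J'J`); a residual at a bound is
flagged and its CI reported as degenerate. Choices worth knowing:

* The uptake observable is `C_F + C_B`: whole-cell fluorescence cannot
  separate free from bound drug.
* `v_ratio` is **not** fitted — only `k_EF * v_ratio` is identifiable from
  intracellular data — so it is fixed from configuration. The package
  default is `1.5e5`, chosen so that the reference uptake assay (1 uM
  applied for 8 h, rates at the reference values) peaks around 1.4 uM
  intracellular, making the ~50 nM measurement noise a few percent of
  signal. This matches the precision regime of published uptake fits; with
  a naive geometric guess of 1e4 the bound-drug plateau (~16 nM) would sit
  far below the noise floor and the net binding rate would be essentially
  unidentifiable.
* `fit_pd` defaults to a raw-count loss, but the pipeline uses the
  log-count loss, which is the correct likelihood for the multiplicative
  lognormal count noise the generator produces (and that real confluence
  counting roughly exhibits).
* `hill_fit` reports both the Hill midpoint parameter `EC50` and the
  absolute half-response dose `D50` (where the fitted curve crosses
  survival 0.5). The midpoint trades off against the floor `E_inf`, which
  is extrapolated when a line's data do not reach its floor; `D50` is
  interpolated within the data and is the robust statistic for comparing
  dose scales across cell lines. A survival profile flat across doses is
  flagged non-identifiable instead of returning a meaningless EC50.

## The inverse problem: response surface, matching, rate estimation

For monotherapy the equivalent dose is known exactly from the fitted PK
rates, so the monotherapy response parameters `p = (k_{d,a}, k_{d,b}, r)`
can be laid out as a function of `D_eq`. `build_response_surface()`
interpolates them piecewise-linearly through the condition nodes — exact at
the nodes, no extrapolation — following the non-parametric interpolation
philosophy: no functional form is assumed between response parameters and
dose.

The pipeline (`analyze_sensitizer_study()`) applies two non-parametric
regularizations to the fitted surface before matching: the node parameters
are projected onto the qualitative monotone dose-response shape (death
rates non-decreasing, induction rate non-increasing in dose; isotonic
regression), which removes spurious matching branches created by node fit
noise, and interpolation uses a monotone cubic (Fritsch-Carlson) rather
than linear chords — on a 2-fold dose grid the chords of a saturating
response run below the curve and bias matched doses upward mid-gap. The
exported `build_response_surface()` default remains the raw local-linear
rule.

A co-treatment condition is assigned the equivalent dose whose monotherapy
parameters it best matches in the L2 sense,
`D_est = argmin_D ||(p_est(D) - p_fit)/s||_2`
(`estimate_equivalent_dose()`; dense 512-point scan plus golden-section
refinement, robust to the kinks of a piecewise-linear surface). The
normalization `s` defaults to each dimension's node range — raw scales
differ by orders of magnitude. The pipeline additionally inflates `s` by
the pooled (median) curvature CI of each parameter across fits: when the
transient is weak, `(k_d_b, r)` lie on a likelihood ridge and scatter far
beyond their true variation, and the inflation stops those dimensions from
dominating the distance. Matches that land on the surface boundary, that have a second, distant
near-optimal minimum, or whose residual is far above that of other
conditions at the same doxorubicin dose are flagged; flagged matches are
excluded from the downstream pooling (they carry no interior dose
information), except that a sensitizer level is never left empty.

`estimate_kx()` then solves the constrained inverse problem: find the
target rate (`k_FE` or `k_FB`) per sensitizer level minimizing
`G(k_x) = sum_i (D_{est,i} - D_i(k_x))^2`, where `D_i(k_x)` is the model
equivalent dose of condition `i`'s course with the target rate substituted
and all other rates fixed to the monotherapy fit — each sensitizer is
assumed to act on a single rate. Monotonicity in sensitizer concentration
is enforced *exactly* by optimizing a base value plus non-negative
increments of the transformed rate: `k_x` itself for an increasing target
(DNA-repair inhibition raising `k_FB`), `1/k_x` for a decreasing one
(efflux inhibition lowering `k_FE`). Starting values come from per-level
scalar root solves of `D(k_x) = median(D_est)` (the model dose is monotone
in either rate), isotonized, then polished jointly; the polished solution
is never accepted if it is worse than the seed, so the optimizer can never
lose to the null.

## What the synthetic data emulate — and what they do not

`study_design()` encodes the reference experimental design: a 2-fold
doxorubicin dilution series (5000 down to ~10 nM) applied for 24 h and
washed out; three mid-range doxorubicin doses crossed with seven 2-fold
sensitizer levels; an uptake assay at 1 uM with washout at 8 h, sampled
every 25 min for 24 h; daily cell counts for 15 days with a 3-day
pre-treatment phase; six replicates; additive Gaussian uptake noise
(sigma = 50 nM) and multiplicative lognormal count noise (CV = 5%); counts
truncated once the mean reaches 95% of capacity, where nucleus counting
degrades. The ground-truth PD map has saturating death-rate curves and a
falling induction rate (half-saturations 600–900 nM on the equivalent-dose
axis, i.e. mid-grid); the ground-truth sensitizer effects are Hill-type
curves of the target rate (efflux 0.313 -> 0.046/h; net binding rising up
to 4-fold).

These generators reproduce the *statistical structure* the analysis
assumes: ODE-exact means, the stated noise models, replicate wells and
dilution grids, with a machine-readable truth bundle. They do **not**
emulate single-cell heterogeneity, cell-cycle structure, density-dependent
drug effects, drift in microscope gain, or segmentation errors beyond the
stated noise — so a green test suite demonstrates correctness of the
estimators under the model's own assumptions, not robustness to every
failure mode of real microscopy data.

On the imaging side, `gen_spectral_stack()` forward-synthesizes
`I_j = L (sum_f S_f T[f,j]) + noise` from known fluorophore maps, a mixing
matrix and an illumination field, and the pipeline
(`estimate_illumination` -> `correct_illumination` -> `unmix_signals` ->
`signal_to_concentration`) inverts it. The illumination estimator
median-filters with a disc (radius 50 px by default — larger than a cell),
averages over timepoints, fits a degree-2 polynomial surface and
normalizes to max 1. The median of a *curved* field over a disc is a
smoothed field, so the refit is accurate to ~2% RMS, not exact; the
unmixing and calibration stages, by contrast, are exact linear algebra and
recover noiseless inputs to solver precision. Segmentation is
threshold-plus-8-connected-components; the extracellular compartment
excludes a 2-px guard band around the cell mask to avoid edge bleed.

## Numerical and robustness notes

* Simulation sizes in the test suite are chosen to finish in minutes on a
  laptop: 100 random rate sets for the conservation/agreement invariants,
  20 replicate datasets for the recovery studies, one full synthetic
  sensitizer study per target (11 monotherapy + 21 co-treatment
  conditions) for the end-to-end checks, 40x50-px image fixtures.
* The recovered sensitizer curve inherits two structural error sources
  that no estimator choice removes: the `(k_d_b, r)` likelihood ridge
  under daily sampling (the transient kill integral `k_{d,b}e/r` is well
  determined, its split is not), and the flattening of the response map at
  high dose, which amplifies parameter noise into equivalent-dose error
  wherever `dp/dD` is small. Both are visible in the acceptance numbers
  as the gap between near-exact noiseless round-trips and ~10% errors
  under noise.
* All generator and fitter randomness flows through explicit seeds; the
  global RNG state is restored after each call.

## Limitations

The framework shares the model's biological limits: first-order kinetics
with static rates, no saturation of transport or binding, population-level
determinism (no heterogeneity or evolution), and a functional `k_FB` that
cannot be decomposed into binding versus repair without additional
measurements. Comparisons *across* cell lines require all rates to be
estimated per line; within a line, the equivalent dose supports comparing
arbitrary schedules and quantifying sensitizer effects on single rates.
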