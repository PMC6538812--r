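# eqdose

Mechanistic PK/PD modeling of doxorubicin treatment response in cultured
tumor cells, built around the **equivalent dose**: the peak concentration
of drug bound to the nucleus, predicted by a three-compartment uptake
model, as a unified measure of delivered effect.

Conventional dose-response summaries (Hill curves against the applied
extracellular concentration) conflate drug delivery with drug effect. Two
cell lines differing only in efflux-pump expression show very different
extracellular EC50s while being equally sensitive to the drug that reaches
their DNA. `eqdose` separates the two processes and uses the separation to
*measure* them: it quantifies how sensitizing co-treatments (efflux-pump
inhibitors, DNA-repair inhibitors) shift individual rate constants, using
only population-scale cell-count data.

## The models

Uptake (concentrations in nM; `v` = extracellular/intracellular volume
ratio):

```
dC_E/dt = k_FE C_F / v  -  k_EF C_E
dC_F/dt = k_EF v C_E    -  (k_FE + k_FB) C_F
dC_B/dt = k_FB C_F
```

The equivalent dose `D_eq` of a treatment schedule is `max_t C_B(t)`;
since `C_B` is non-decreasing, it is evaluated at the end of the course
plus a washout tail. `k_FB` is a functional net binding rate (binding
mixed with DNA repair), which is why DNA-repair inhibition registers as an
increase in `k_FB`.

Population response: logistic growth with a time-dependent death rate
switched on at treatment,

```
dN/dt = (k_p - k_d(t)) N (1 - N/theta)
k_d(t) = (1-lam) k_d_a + lam k_d_b r t e^(1 - r t),   t >= 0
```

mixing a stable (apoptosis-like) and a transient (mitotic-catastrophe-
like) kernel.

The inverse framework: monotherapy response parameters
`p = (k_d_a, k_d_b, r)` are interpolated against their exactly-known
equivalent doses (`build_response_surface`); each co-treatment condition
is assigned the dose whose monotherapy parameters it best matches in a
normalized L2 sense (`estimate_equivalent_dose`); and the sensitizer-
modulated rate is estimated per sensitizer level by monotonically
constrained least squares on those matched doses (`estimate_kx`),
optimizing `1/k_FE` for efflux inhibitors and `k_FB` for repair
inhibitors.

## Worked example

```r
library(eqdose)

## the reference cell line's uptake parameters (1/h)
p <- pk_params(k_EF = 3.08e-6, k_FE = 0.313, k_FB = 0.0212)

## 1 uM doxorubicin applied at t = 0, washed out at 8 h
crs <- treatment_course(c(0, 8), c(1000, 0), horizon_h = 24)
d <- equivalent_dose(p, crs)
round(as.numeric(d), 1)
#> [1] 234.6

## an efflux-pump inhibitor that lowers k_FE from 0.313 to 0.046 1/h
p_inh <- pk_params(k_EF = 3.08e-6, k_FE = 0.046, k_FB = 0.0212)
round(as.numeric(equivalent_dose(p_inh, crs)), 1)
#> [1] 1166.9
```

The same 1 uM course delivers five times the bound drug once efflux is
inhibited — that factor, not the unchanged extracellular concentration, is
what the cells respond to.

A full synthetic sensitizer study, generated and analyzed end to end
(uptake fit, per-condition response fits, surface matching, constrained
rate estimation):

```r
design <- study_design()                # 2-fold dose grids, 6 replicates
base <- pk_params(3.08e-6, 0.313, 0.0212)
study <- gen_sensitizer_study(base, design, target = "k_FB", seed = 1)
ana <- analyze_sensitizer_study(study, design, target = "k_FB")
rbind(recovered = signif(ana$kx$k_x, 3), truth = signif(study$truth$kx, 3))
#>             [,1]   [,2]   [,3]   [,4]   [,5]  [,6]  [,7]
#> recovered 0.0259 0.0311 0.0334 0.0416 0.0584 0.115 0.115
#> truth     0.0241 0.0287 0.0386 0.0540 0.0689 0.0781 0.0823
```

The recovered per-level `k_FB` values rise monotonically (the constraint
is exact) and track the generating Hill-type curve. With count noise at
the designed 5% CV the per-level relative errors here run from 7% to
~40% (median ~15%): the response map saturates at high dose, so
parameter noise is amplified into dose error exactly where the sensitizer
effect is largest — see the methods vignette for the error budget.

The imaging pipeline (illumination correction, spectral unmixing,
signal-to-concentration calibration) is exercised the same way from
forward-synthesized stacks; see `?unmix_stack` and the methods vignette
(`vignettes/equivalent-dose-methods.Rmd`).

A thin command-line front end over these functions is included at
`inst/cli/eqdose.R` (subcommands `simulate-pk`, `eqdose`, `fit-pk`,
`fit-pd`, `fit-hill`, `generate`, `run`).

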