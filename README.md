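# nscglioma

Multistage modelling of glioma incidence across the human lifespan from
neural stem cell (NSC) dynamics.

Glioma incidence rises with age to a peak at roughly 80 years and then
declines. `nscglioma` implements a mechanistic explanation: gliomas
arise from randomly occurring oncogenic mutations accumulating in the
adult NSC pool, a population that shrinks exponentially with age while
its surviving cells divide progressively faster. The package is aimed at
quantitative cancer biologists and epidemiologists who want to confront
that mechanism with registry-style age-binned incidence data, explore
what the minimum number of oncogenic hits implies for the shape of the
curve, and quantify the contribution of age-related proliferative
changes.

## The model

A cell that has lived to age *t* has undergone

&nbsp;&nbsp;&nbsp;&nbsp;*D(t) = ∫₀ᵗ r(s) ds*

divisions, where the division rate *r(t)* interpolates linearly from
251 divisions/cell/year in the young adult to 318 in the aged adult
(empirical 48-hour time-lapse estimates of 1.37 and 1.74 divisions per
48 h, annualised). Each division mutates any given coding gene with
probability *u*; with *n₀ = 29* glioma proto-oncogenes among *G =
18,440* coding genes, the per-division oncogenic hit probability is
*u₀ = n₀·u*, and the number of oncogenic hits by age *t* is
Poisson-distributed with intensity *λ(t) = u₀·D(t)* (an approximation
of the exact binomial that the package also provides and validates
against). Transformation requires at least *n*<sub>min</sub> hits
arriving in a permitted temporal order: of the *x*! orders in which *x*
hits can arrive, on average *S* transform, so the per-cell
transformation probability is

&nbsp;&nbsp;&nbsp;&nbsp;*P₁(t) = Σₓ₌ₙ₋ₘᵢₙ^{n₀} (S/x!) · λ(t)ˣ e^{−λ(t)}/x!*

— an Armitage–Doll-type multistage law that sums over every sufficient
hit count rather than privileging one. With *N(t) = N₀·e^{−kt}* NSCs
remaining at age *t*, the probability that at least one has transformed
is *P(t) = 1 − (1 − P₁(t))^{N(t)}*; scaled by 100,000 this is the
prevalence, and its numerical derivative is the incidence per 100,000
person-years. The decay constant *k* and sequence multiplicity *S* are
calibrated against age-grouped incidence tables; *u* and *N₀* are
supplied by the user from published estimates (the package deliberately
ships no default for either).

## Worked example

```r
library(nscglioma)

# Where must the NSC pool decay sit for the incidence peak to fall at
# 80 years, given n_min = 5 hits and the rising division-rate schedule?
cal <- calibrate_peak_age(target_age = 80, n_min = 5, u = 1e-7, N0 = 1e5,
                          S = 30, grid = simulation_grid(dt = 0.01))
cal
#> <nsc_peak_calibration> k_hat = 0.04042 /y places the incidence peak at 80.000 y (target 80.0 y)
```

A decay constant of about 0.04 per year — the pool falling to ~3% of
its birth size by age 85 — places the modelled incidence maximum exactly
at the demographic peak. The fitted curves are an ordinary tibble:

```r
dplyr::slice(cal$curves[c("t", "r", "D", "N", "prevalence", "incidence")],
             seq(2001, 10001, by = 2000))
#> # A tibble: 5 × 6
#>       t     r      D      N prevalence incidence
#>   <dbl> <dbl>  <dbl>  <dbl>      <dbl>     <dbl>
#> 1    20  267.  5178. 44553.    0.00698   0.00151
#> 2    40  283. 10671. 19850.    0.114     0.0104
#> 3    60  298. 16479.  8844.    0.438     0.0216
#> 4    80  314. 22602.  3940.    0.932     0.0262
#> 5   100  318  28952.  1756.    1.41      0.0191
```

Incidence (last column, per 100,000 person-years) rises steeply through
mid-life, peaks at 80, and declines as the stem cell pool empties.
Calibration against an age-binned table recovers generating parameters
from noisy data:

```r
tab <- generate_synthetic_table(synthetic_table_spec(
  noise = "lognormal", sigma = 0.1, seed = 42,
  grid = simulation_grid(dt = 0.01)))   # truth: k = 0.04, S = 30
fit <- fit_incidence_model(tab, n_min = 5, u = 1e-7, N0 = 1e5,
                           grid = simulation_grid(dt = 0.01))
fit
#> <nsc_fit> multistage NSC incidence calibration
#>   n_min = 5: k_hat = 0.04297 /y, S_hat = 39.97
#>   objective = 5.607e-05 over 18 bins, peak at 74.7 y, not feasible
```

With 10% multiplicative noise on 18 bins the decay constant comes back
within ~7% of truth; `feasible` reports whether the fit both matches the
table (objective below tolerance) and peaks inside the demographic
window (75–85 years) — here the noisy peak lands just outside it.
`tidy()`/`glance()` give broom-style summaries, `autoplot()` plots
curves, fits and bootstrap bands, `sweep_n_min()` compares hit
requirements, and `parametric_bootstrap()` puts percentile confidence
bands on the incidence curve. A command-line interface covering the same
operations is installed at
`system.file("cli", "nscglioma", package = "nscglioma")`.

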