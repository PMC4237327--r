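---
title: "A multistage neural-stem-cell model of glioma incidence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multistage neural-stem-cell model of glioma incidence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nscglioma)
```

## The model and its assumptions

`nscglioma` treats glioma initiation as the first oncogenic
transformation event in the adult neural stem cell (NSC) pool. The model
composes four ingredients, each with an explicit biological assumption:

1. **Division history.** Every surviving NSC divides at the
   population-average rate $r(t)$, accumulating
   $D(t) = \int_0^t r(s)\,ds$ divisions by age $t$. The default
   schedule interpolates linearly from 251 divisions/cell/year at age 0
   to 318 at age 85 (annualised from rodent time-lapse measurements of
   1.37 and 1.74 divisions per 48 h) and clamps to the endpoint values
   outside that window. Assumption: rodent-derived per-cell kinetics
   transfer to the human pool, and a single deterministic rate describes
   every cell.

2. **Mutation accumulation.** Each division mutates a given coding gene
   with probability $u$, constant across life, and all genes mutate
   with equal probability. With $n_o = 29$ glioma proto-oncogenes among
   $G = 18{,}440$ coding genes, an oncogenic hit occurs per division
   with probability $u_o = n_o u$. The hit count after $D$ divisions is
   Binomial$(D, u_o)$, approximated by Poisson$(\lambda = u_o D)$. The
   package implements both; the binomial (computed in log space) serves
   as the exact reference, and the approximation error follows the
   classical $x^2/(2D)$ envelope, comfortably below 1% at the division
   counts ($\ge 10^4$) a cell actually reaches within the first years of
   life.

3. **Transformation.** A cell transforms once it has acquired at least
   $n_{\min}$ oncogenic hits in a permitted temporal order. Of the $x!$
   orders in which $x$ hits can arrive, on average $S$ transform, giving
   per-cell probability
   $P_1(\lambda) = \sum_{x = n_{\min}}^{n_o} \frac{S}{x!}
   \frac{\lambda^x e^{-\lambda}}{x!}$.
   Every sufficient hit count contributes, unlike the classical
   Armitage–Doll formulation with a single privileged stage count; with
   the ordering factor disabled (see the seam below) and $k = 0$ the
   model reproduces the classical power law — log incidence against log
   age has slope $n_{\min} - 1$ — which the test-suite verifies by
   regression.

4. **Population risk.** The pool declines exponentially,
   $N(t) = N_0 e^{-kt}$, and
   $P(t) = 1 - (1 - P_1(t))^{N(t)}$ is the probability that at least
   one NSC has transformed. Prevalence is $10^5 P(t)$; incidence is its
   numerical derivative, in cases per 100,000 person-years.
   Transformation is identified with clinical incidence: there is no
   latency, competing mortality, or diagnosis-lag correction.

A consequence worth knowing: because $N(t)$ decays, $P(t)$ is *not*
globally nondecreasing. Once the relative growth of per-cell risk drops
below the pool's decay rate (roughly $n_{\min} r(t)/D(t) < k$), the
modelled prevalence — risk carried by the currently surviving pool —
declines and the incidence turns slightly negative. At demographically
calibrated decay constants ($k \approx 0.04$/y) this happens only beyond
the 100-year horizon, but at larger $k$ it is visible late in life. The
synthetic-table generator therefore clamps bin rates at zero, as a
registry would never report a negative rate, and the calibration applies
the same clamp to the model side of the comparison. For users who prefer
the per-person-still-unaffected reading, the curves also carry a hazard
variant, `incidence / (1 - P)`.

## Parameters

| Parameter | Units | Default | Origin |
|---|---|---|---|
| `u` | per gene per division | **none** (required) | published single-division mutation-probability estimates; order $10^{-7}$. Deliberately not defaulted: it anchors the model's absolute scale. |
| `G`, `n_onco` | counts | 18,440 / 29 | coding-genome size and the packaged glioma proto-oncogene set |
| `n_min` | count | — | the scientific question; swept 1–29 by `sweep_n_min()` |
| `S` | sequences | 1 in `mutation_params()` | calibrated; capped at $n_{\min}!$ under the default ordering model |
| `r_young`, `r_aged` | divisions/cell/year | 251, 318 | annualised 48-h time-lapse counts (183 periods/year; 182.5 would round 1.37 down to 250, so 183 is used to reproduce both printed integers) |
| `t_start`, `t_end` | years | 0, 85 | the rate anchors; the underlying kinetics are young-adult vs aged measurements, so anchoring at birth is a modelling choice, exposed as config |
| `N0` | cells | **none** (required) | histology scaling chain (cells/section → cells/mm → tract totals); examples use $10^5$ |
| `k` | 1/year | fitted in $[10^{-4}, 1]$ | calibrated against demographic data |
| `dt`, `t_max` | years | 0.001, 100 | simulation grid (below) |

## What the generator emulates — and what it does not

`generate_synthetic_table()` stands in for registry data (e.g.
CBTRUS-style tables), which the package does not redistribute. It
reproduces the *structure* of such data: 5-year age bins plus an
open-ended `85+` bin, mean incidence per 100,000 person-years per bin,
an incidence curve rising to a peak near old age (the default generating
parameters are $k = 0.04$/y, $S = 30$, $n_{\min} = 5$, $u = 10^{-7}$,
$N_0 = 10^5$), and multiplicative observation noise, modelled as
mean-one lognormal so noisy tables are unbiased for the generating
curve.

It does not emulate the *absolute magnitude* of registry rates: under
the factorial-capped ordering model, $S \le n_{\min}!$ bounds the
product $N_0 S$ that sets the scale, and the default conditions yield
peak rates of order $10^{-2}$ per 100,000 rather than tens. Nor does it
emulate Poisson count noise tied to bin population sizes (that is the
parametric bootstrap's job), registry artefacts such as age heaping, or
any real mis-specification — the generator is the model itself, so
parameter-recovery tests demonstrate identifiability and correctness of
the machinery, not that the mechanism is true of real gliomas.

## Numerical choices

- **Grid.** $dt = 0.001$ y reproduces headline quantities; halving it
  moves the peak age by under 0.01 y (tested). Calibration and bootstrap
  work re-run the model hundreds of times and use $dt = 0.01$ y, the
  coarsest step the grid constructor allows; the test-suite and the
  acceptance script state which they use. Horizons are 100 y.
- **Derivative.** Central differences in the grid interior; second-order
  one-sided stencils at both endpoints, so the derivative is exact for
  quadratics everywhere.
- **Probability arithmetic.** The binomial pmf is assembled in log space
  (`lchoose` + `log1p`); $P = 1 - (1-P_1)^N$ uses `expm1`/`log1p`;
  $P_1$ uses the Poisson-term recurrence $p_x = p_{x-1}\lambda/x$
  seeded at $e^{-\lambda}$ (which agrees with `dpois` to machine
  precision and is an order of magnitude faster over a dense age grid);
  probabilities below $10^{-300}$ flush to zero.
- **Fractional divisions.** $\lambda = u_o D$ accepts real-valued $D$
  from the rate integral; the binomial reference rounds $D$ to the
  nearest integer and is used only at test scale.
- **Calibration.** $S$ enters the small-$P$ incidence linearly, so it is
  profiled in closed form as the weighted least-squares scale of a
  unit-$S$ run, clipped to $(0, n_{\min}!]$; only $k$ is searched. The
  profiled objective is flat away from a narrow basin around the best
  $k$, so a 25-point log-spaced scan brackets the minimum before
  golden-section refinement — a plain bounded search over
  $[10^{-4}, 1]$ reliably stalls on the flat shoulder. Weights are
  relative, $w_b = 1/\max(\text{obs}_b, \text{floor})^2$ with a floor
  of 1 per 100,000 person-years; for tables far below that scale the
  weighting degrades gracefully to absolute least squares.
- **Degenerate inputs.** All-zero tables are rejected; an all-zero
  incidence curve makes the peak age an error; boundary maxima are
  flagged, not errors; `n_min > n_onco` returns probability zero with a
  warning; prevalence leaving the rare-event regime ($P > 0.5$ at the
  horizon) warns but still returns the exact expression.

## Design choices where the design was open

- **The ordering factor.** The transformation weighting is implemented
  behind a seam (`ordering`): the default `"fraction"` model reads $S$
  as the average number of transforming orders among the $x!$ possible
  ones, giving $p_x = S\lambda^x e^{-\lambda}/(x!)^2$ and the cap
  $S \le x!$; `"all"` makes every order transforming (recovering the
  plain Poisson tail, and with it the classical power law);
  `"permutation"` normalises $S$ by the number of ordered $x$-gene
  selections from the oncogene set, $n_o!/(n_o - x)!$, for readings in
  which $S$ counts gene-sequence identities rather than order
  fractions. One scalar $S$ applies to every sequence length, a
  deliberate simplification.
- **$N_0$–$S$ identifiability.** In the small-$P$ regime incidence
  depends on $N_0$ and $S$ only through $N_0 S$, so calibration holds
  $N_0$ fixed and fits $S$; a message records this on every fit.
- **Bootstrap scheme.** What exactly is resampled is a genuinely open
  design question for registry-shaped data; the package implements a
  parametric per-bin scheme — event counts drawn
  Binomial(`sample_size` × bin-width person-years, fitted rate /
  $10^5$), rates rebuilt, model refitted per replicate — because it is
  the only scheme constructible from the artefacts the package has. The
  sample size is config-exposed (default 100,000, the rate
  denominator); statistical checks of band behaviour use larger sizes
  so per-bin counts are in the Gaussian regime.
- **Feasibility.** A calibration is "feasible" when its objective is
  below a tolerance (default 0.25) *and* its peak falls in 75–85 y, the
  demographic window around the observed peak; both are config.
- **Open-ended bins.** `85+` maps to $[85, t_{\max}]$ when compared to
  model curves; bins are half-open $[lo, hi)$ in continuous years.
- **Package shape.** The package is tidyverse-native — tibble-first
  returns, broom-style `tidy()`/`glance()`, `autoplot()` — because
  every object it manipulates (tables, curves, reports, bands) is
  naturally tabular.

## Known limitations

- The cell-of-origin is fixed as the NSC; glial-progenitor alternatives
  are out of scope.
- Mutation rate is constant across life: no genomic-instability
  feedback, telomere effects, or gene-specific rates.
- No stochastic population dynamics, spatial niche structure, or
  quiescent/active compartments; $N(t)$ is a deterministic exponential.
- No tumor growth, latency, or grade structure between transformation
  and incidence; no cohort life-tables or competing mortality.
- The 23 glioma-tagged symbols in the packaged oncogene file are a
  synthetic reconstruction from well-established cancer-gene-census
  annotations; the set's size (29) and its six named other-tumour-type
  additions are the enforced invariants, and only the size enters the
  mathematics.
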