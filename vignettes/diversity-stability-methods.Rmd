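---
title: "Methods: biodiversity effects, stability decompositions, and path analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biodiversity effects, stability decompositions, and path analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divstab)
```

# Scope

`divstab` analyses long-term sown-diversity grassland experiments: plots sown
along a species-richness gradient (1, 2, 4, 8, 16 species drawn from a
60-species pool in four functional groups), harvested annually, with every
pool species also grown in monoculture-reference plots. The package covers
four linked analyses — additive partitioning of biodiversity effects,
temporal stability and synchrony over rolling windows, power-law slope
decompositions of richness–stability relationships, and recursive path
analysis — plus a synthetic data generator with known ground truth.

# Additive partitioning

For a mixture of $N$ species with observed yields $O_i$ and monoculture
yields $M_i$, relative yields are $\mathrm{RY}_i = O_i/M_i$ and
$\mathrm{RYT} = \sum_i \mathrm{RY}_i$. The net biodiversity effect
partitions exactly:

$$\mathrm{NE} = \sum_i O_i - \frac{\sum_i M_i}{N}
  = \underbrace{(\mathrm{RYT}-1)\,\overline{M}}_{\mathrm{CE}}
  + \underbrace{(N-1)\,\mathrm{cov}(M_i, \mathrm{RY}_i - 1/N)}_{\mathrm{SE}}$$

with the covariance in the $\sum(x-\bar x)(y-\bar y)/(N-1)$ convention, so
that $(N-1)\,\mathrm{cov}$ is the raw cross-product sum and
$\mathrm{NE} = \mathrm{CE} + \mathrm{SE}$ holds to machine precision on
every record — the test suite asserts this at $10^{-9}$.

Conventions that the underlying formulas leave open were fixed as follows:

* **Monoculture failure.** $\mathrm{RY}_i$ is undefined when $M_i = 0$, so a
  species without a usable monoculture yield that year is dropped and the
  partition is computed over the remaining $N_\mathrm{used}$ species; NE is
  computed over the same reduced set so the additive identity is preserved.
  Fewer than two usable species leaves the record with NA effects and a
  reason code. Zero *mixture* biomass is kept ($\mathrm{RY}_i = 0$); only
  monoculture failure excludes.
* **Multiple monoculture plots.** $M_i$ is the mean over that species'
  monoculture plots in that year; the community relative yield divides plot
  yield by the plot-weighted mean yield of all monoculture plots that year.
* **Windowed effects.** Species and monoculture biomass are summed over the
  window years first, then the identical formulas are applied; a species is
  excluded only if its *summed* monoculture yield is zero. Under alternating
  dominance (different species doing well in different years), annual
  selection effects scale up to an interannual complementarity effect, which
  is why windowed CE can exceed the mean of annual CEs.
* **Outliers.** Extreme CE/SE values (driven by tiny $M_i$) are flagged
  outside $[Q_1 - m\,\mathrm{IQR},\; Q_3 + m\,\mathrm{IQR}]$ with $m = 6$ by
  default. The verbal rule "more than six times above or below the upper or
  lower quartile" is ambiguous; the fence form is the standard convention
  the rule cites, and $m$ is exposed as an argument. Quartiles use linear
  interpolation (R `quantile` type 7); fences are pooled across years by
  default with a per-year option, since either reading is defensible. A
  degenerate IQR of 0 flags nothing, as does $m = \infty$.

# Stability and synchrony

Over each window, per plot: $\mu_\mathrm{net}$ and $\sigma_\mathrm{net}$
are the temporal mean and sample SD ($n-1$) of the community yield series,
and $\sigma_i$ the per-species SDs with zeros filled in for years a sown
species was not recorded (sown-by-design convention: a sown species that
never appears contributes $\sigma_i = 0$). Then

$$\mathrm{CV}_\mathrm{net} = \sigma_\mathrm{net}/\mu_\mathrm{net}, \quad
  \theta = \frac{\sigma_\mathrm{net}}{\sum_i \sigma_i}, \quad
  \mathrm{CV}_\mathrm{pop} = \frac{\sum_i \sigma_i}{\mu_\mathrm{net}},$$

with stability $\mathrm{CV}_\mathrm{net}^{-1}$, asynchrony $1-\theta$, and
population stability $\mathrm{CV}_\mathrm{pop}^{-1}$. The square-root form
of the synchrony index ($\sqrt{\sigma^2_\mathrm{net}/(\sum_i\sigma_i)^2}$)
is algebraically identical for non-negative arguments. The identity
$\mathrm{CV}_\mathrm{net} = \theta \cdot \mathrm{CV}_\mathrm{pop}$ holds by
construction and is asserted on every emitted record. Some sources print
"CV" as mean-over-SD; this package uses the standard SD-over-mean for
`cv_net` and its inverse for `stability`, which is the quantity every
downstream analysis actually uses. $\theta \in [0,1]$ because the SD of a
sum is at most the sum of SDs; monocultures have $\theta \equiv 1$.

Degenerate windows are flagged, not dropped silently: a plot missing a
window year, all-constant species series ($\theta$ undefined), or zero mean
yield (CVs undefined) each carry a reason string. A constant community
series gives infinite stability, which downstream log-scale fits exclude by
their finiteness filter.

**Window enumeration.** All `n - width + 1` consecutive windows are
returned, plus `floor(n/width)` non-overlapping windows spread evenly
between the first and last year. The even spread (rather than greedy
packing from the first year) is deliberate: for 17 years and width 5 it
yields 2003–2007, 2009–2013, 2015–2019, i.e. the three independent windows
that span the full experiment including its final years.

# Power-law slopes and their exact decompositions

Per year (or window), responses are regressed on $\log(\text{sown
richness})$ by OLS: $\sqrt{\mathrm{ANPP}}$, $\log \mathrm{RY}$, NE, CE, SE
on the original scale, $\log \mathrm{RYT}$. The log–log slopes are power
exponents $b$. Because least squares is linear in the response for a shared
regressor set, on a common plot set

$$b_{\mathrm{CV}_\mathrm{net}^{-1}} = b_\mathrm{mean} - b_\mathrm{SD},
\qquad
b_{\mathrm{CV}_\mathrm{net}^{-1}} = b_{\theta^{-1}} +
b_{\mathrm{CV}_\mathrm{pop}^{-1}}$$

hold exactly, and the package asserts both at $10^{-9}$. The often-quoted
asynchrony form $b_\mathrm{async} + b_{\mathrm{CV}_\mathrm{pop}^{-1}}$
uses $\log(1-\theta)$, which cannot satisfy the sum identity exactly
(log of a difference is not a difference of logs); both slopes are
computed and both gaps reported, so the discrepancy is visible rather than
hidden. Monocultures are necessarily excluded from asynchrony fits
($\log 0$ undefined), and the common-set rule re-applies after exclusion
so the identities always refer to one shared plot set.

Because biodiversity effects are on the absolute yield scale, which drifts
over years, per-year NE/CE/SE slopes are additionally divided by that
year's grand-mean plot yield (`relative_effect_slopes`). Temporal trends
are OLS fits of slope series on time (or log of the 1-based time index);
p-values are two-sided t-tests with no multiple-testing correction, since
per-time slopes are reported raw. Mixed-effects structure (block and plot
random effects, AR(1) residuals) is deliberately replaced by this
per-time-OLS-plus-trend design: it estimates exactly the quantities the
slope figures display and keeps every step unit-testable. Block effects
can be large in real fields; this is a known limitation, not an oversight.
Note the $\sqrt{\mathrm{ANPP}}$ fits are the one scale-dependent response
(their slope changes under unit rescaling); all log–log slopes are
unit-invariant and tested as such.

# Recursive path analysis

The default model links log richness (SR) to windowed CE and SE, these
three to windowed productivity (ANPP), all four to population stability,
SR/CE/SE to asynchrony, and asynchrony plus population stability — and
only they — to community stability. CE–SE and asynchrony–population
stability residuals are free to covary. Node transforms: log for SR, ANPP,
population and community stability; CE is min–max scaled to $(\epsilon,1]$
with $\epsilon = 10^{-3}$ then logged ($\epsilon$ is needed because the
minimum maps to 0; the choice only compresses the lowest CE value and is
exposed as an argument); SE and asynchrony enter untransformed. All nodes
are standardized.

Estimation is equation-wise least squares on the recursive system. For an
acyclic model whose only covariances involve terminal disturbances, these
point estimates coincide with maximum-likelihood SEM estimates; rather than
assuming this silently, a test checks that Wright's tracing rule over the
fitted coefficients reproduces observed richness–node correlations within
0.02 on data generated from the model itself. Fit indices ($\chi^2$,
RMSEA) are out of scope, and the data-specific practice of pruning extreme
values until RMSEA reaches zero is replaced by the same quartile-fence
filter used for annual effects, applied to windowed CE/SE before fitting —
a general, reproducible rule rather than a dataset-tuned loop.

Inference is a nonparametric bootstrap over rows (plots): each replicate
resamples, re-standardizes, refits; percentile intervals and sign-crossing
two-sided p-values (floored at $2/n_\mathrm{boot}$) are reported. Indirect
effects are products of chain coefficients recomputed per replicate; total
effects add the direct edge replicate-wise. Group comparisons (e.g. the
three non-overlapping windows) require disjoint observation sets — the
same plot may appear in different windows, since each window contributes
distinct observations, but refitting the same window twice is rejected.
Letters are assigned from maximal cliques of the "not significantly
different" graph at unadjusted $\alpha = 0.05$.

# The synthetic generator

Biomass of species $i$ in plot $j$ (richness $N$) in year $t$ is

$$\frac{m_{0i}}{N}\; w_{ij}\; e^{-\max(d_0 - d_1 \log_2 N,\,0)\,t}\;
  e^{u_t + v_{it} + \epsilon_{ijt}},$$

with lognormal baselines $m_{0i}$, a common year effect $u_t$, a
species-year deviation $v_{it}$ shared across plots (one "good year" per
species everywhere — the assumption that makes monoculture-based relative
yields informative), independent residual noise, and optional dropout to
zero exercising the monoculture-failure path. Multiplicative log-normal
noise keeps biomass positive and makes CVs comparable across richness
levels. The dominance weight is $w_{ij} = e^{\lambda z_i}$ ($z_i$ the
standardized log baseline, $\lambda$ = `sel_link`) *normalized to mean 1
within the plot's composition*: normalization makes `sel_link` a pure
selection control — it redistributes yield toward productive species
(covariance between $M_i$ and $\mathrm{RY}_i$, hence SE > 0) without
inflating RYT, so CE stays at zero in expectation. An unnormalized
multiplier would raise mean RYT above 1 by Jensen's inequality and
confound selection with apparent complementarity.

Defaults (`jena_like`): 17 years from 2003, baseline log-mean $\log 400$
g/m² with log-SD 0.4 (typical temperate grassland yields), $d_0 = 0.06$
(6%/year monoculture decline), $d_1 = 0.015$ (so the 16-species decline is
$0.06 - 0.015 \cdot 4 = 0$: monocultures decline fastest, the richest
mixtures are nearly flat), $\sigma_\mathrm{year} = 0.2$,
$\sigma_\mathrm{species\text{-}year} = 0.25$, $\sigma_\mathrm{resid} =
0.15$, `sel_link` 0.2, dropout 2%/year. No field estimates of these
variance components exist at this granularity; the magnitudes are
illustrative choices made once, documented here, and used unchanged by the
tests and the acceptance script. The other presets isolate single
mechanisms (`null`, `complementarity_growth`, `asynchrony`, `selection`).

What the generator emulates: richness-dependent productivity decline,
shared year effects, species-specific asynchronous fluctuations,
selection-style dominance, monoculture failure. What it does not:
block/spatial structure, temporally autocorrelated weather, plant–soil
feedback, species turnover or evolution, and real harvest measurement
error. Passing recovery tests therefore show the estimators recover the
mechanisms they target under the stated noise model — not that every
conclusion transfers to field data with those unmodeled features.

# Problem sizes and numerical choices

Unit and recovery tests run on a reduced 16-species pool (functional split
3/4/5/4) with 6 compositions per level at richness 1–8 and 6–10 simulated
years; Monte-Carlo checks use 20 replicates for sign tests and 100 for the
type-I calibration of trend tests (nominal 5%, upper binomial bound 11/100
at the 0.5% level). These sizes were chosen as the smallest at which the
targeted effects are unambiguous. The full-scale checks (identity suite
and the acceptance script) use the complete 78-mixture/60-monoculture
design over 17 years. Identity assertions use $10^{-9}$; exact-arithmetic
checks (standardization, chain products, reproducibility) use $10^{-12}$
or `identical`. Window enumeration requires width ≥ 2 (temporal variance
undefined below), and slope/trend fits require ≥ 3 distinct predictor
values, else the record is skipped with a reason.

# Known limitations

* No mixed-effects or temporal-autocorrelation modelling; per-time OLS
  slopes are unbiased but their per-time p-values ignore plot-level
  repeated measurement (trend tests across times are the intended
  inference).
* Equation-wise path estimation reports no global fit statistic; model
  adequacy is assessed by the tracing-rule check, residual correlations,
  and per-equation R².
* The pooled outlier fence treats all years as one population; with strong
  secular drift in effect magnitudes, the per-year option is preferable.
* The letter display uses unadjusted pairwise tests, by design mirroring
  the unadjusted convention it reproduces.
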