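---
title: "Spatial interaction models for county-lines distribution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial interaction models for county-lines distribution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

County-lines drug distribution runs phone-ordered supply lines from a hub
city (London, in the data that motivates this package) into other police
force territories. The observable datum is a count: the number of detected
lines from the origin to each destination territory in a given year. The
question the package addresses is which *territorial logic* best explains
how those counts distribute across destinations — raw population pull,
the spatial arrangement of intervening population, or a benefit/cost
balance over social covariates — and which covariates matter.

The unit of analysis is the police force territory. The two Greater London
forces (Metropolitan and City of London) are merged into a single origin
territory (`mergeLondon()`), leaving one origin and, in the motivating
configuration, 37 English destination territories observed over two years
(2019 and 2020).

```{r, message = FALSE}
library(countylines)
study <- makeStudy(syntheticConfig(seed = 1, n_destinations = 10))
study
```

## The three flow models

All models distribute a fixed total outflow $T_i$ (the observed yearly
total of detected lines) across destinations, so
$\sum_j T_{ij} = T_i$ holds by construction for each of them.

**Gravity.** $T_{ij} = T_i\, m_j^b d_{ij}^c \big/ \sum_{k \ne i} m_k^b
d_{ik}^c$, with destination population $m_j$ and distance $d_{ij}$ in km.
It is the benchmark for the "traditional" reading that populous, nearby
places attract lines. The distance exponent $c$ is deliberately an
unconstrained real: the model is implemented exactly in this power-law
form, and a fitted $c < 0$ recovers the familiar inverse-distance decay
while $c > 0$ is also representable. The origin-mass factor cancels in the
normalisation and is not a parameter.

**Retail** (entropy-maximising). Destination utility
$u_j = \sum_n \alpha_n \log w_j^{(n)} - \beta c_{ij}$ combines benefit
rates $w_j^{(n)}$ (covariates per 100 000 inhabitants) with a travel-time
cost ($c_{ij}$ in minutes, $\beta$ per minute), and
$T_{ij} = T_i\, e^{u_j} / \sum_k e^{u_k}$. The sign of a fitted
$\alpha_n$ says whether the covariate attracts ($\alpha_n > 0$) or repels
($\alpha_n < 0$) lines. Five covariates are supported: hospital
admissions by drug misuse and by drug poisoning, police officers (FTE),
gross disposable household income, and knife-crime events.

**Radiation** (intervening opportunities). Opportunities are proportional
to population, $n = \rho p$, and the flow to $j$ is proportional to the
absorption probability
$$P(1 \mid n_i, n_j, n_{ij}) =
  \frac{[(n_i + n_j + n_{ij})^r - (n_i + n_{ij})^r]\,(n_i^r + 1)}
       {[(n_i + n_{ij})^r + 1]\,[(n_i + n_j + n_{ij})^r + 1]},$$
where $n_{ij}$ counts opportunities of territories *strictly* closer to
the origin than $j$ (the circle-of-radius-$d_{ij}$ convention; ties on the
boundary are excluded, and both endpoints are). The denominator of the
flow normalisation sums $P(1 \mid n_i, n_k, n_{ik})$ over destinations
$k$: the $k$-th term uses the opportunities intervening between $i$ and
$k$. The free parameters are $\rho > 0$ (opportunities per person) and the
absorption exponent $r > 0$.

## Calibration

Two penalised losses are available over the $N$ destinations
(`gaussianLoss()`, `poissonLoss()`):

$$\mathcal{L}_G = \frac{1}{2N} \sum_j (T_j^{data} - T_j^{model})^2
  + \lambda \lVert\theta\rVert^2, \qquad
  \mathcal{L}_P = \frac{1}{N} \sum_j \big[T_j^{model}
  - T_j^{data}\log T_j^{model}\big] + \lambda \lVert\theta\rVert^2,$$

with $\lambda = 1$ by default and the ridge applied to the whole free
parameter vector, $\beta$ included. The Poisson form is the natural one
for count data; the Gaussian form is kept as a benchmark. A zero observed
count degenerates gracefully in both (the Poisson term reduces to
$T_j^{model}$); a nonpositive modelled flow facing a positive count is an
error rather than a silent `-Inf`.

`fitModel()` minimises the penalised loss with a deterministic multi-start
scheme: a fixed coarse grid of starts per family (gravity $b \in \{0, .5,
1\}$, $c \in \{-.5, 0, .5\}$; radiation $\rho \in \{0.5, 2, 8\}$, $r \in
\{0.5, 1, 2\}$ on the log scale, which also enforces positivity; retail
alphas at 0 with $\beta \in \{0, 0.005, 0.02, 0.1\}$), each refined by
`nlminb` to a loss tolerance of 1e-8, and the best point polished by
Nelder–Mead. There is no randomness in the optimiser, so refits are
byte-reproducible. On flat directions (e.g. perfectly symmetric
destinations) the ridge penalty breaks the tie toward $\theta = 0$.
Non-convergence is flagged on the `ModelFit`, never silent.

For model comparison (`crossValidate()`), every specification is trained
on one year and validated on the other (twofold cross-validation — the
radiation model's land-slice structure leaves no finer balanced split).
Validation predictions are rescaled to the validation year's observed
total, since the outflow constraint is part of every model. Three metrics
are reported:

* Sørensen–Dice $S = 2\sum_j \min(T_j^{data}, T_j^{model}) /
  (\sum_j T_j^{data} + \sum_j T_j^{model})$, in $[0,1]$;
* $\mathrm{BIC} = 2\log M - 2\log\hat L$, with $\hat L$ the unpenalised
  likelihood at the optimum (Poisson log-likelihood includes the
  $\log T^{data}!$ term so its value is well defined) and $M$ by default
  the whole modelled sample across both years ($M = 2N$; a per-training-year
  variant is available). The $2\log M$ form is implemented exactly as
  stated; a conventional $k \log M$ form exists behind the `k` argument
  of `bic()` but is never the default;
* log-scale MSE $\frac{1}{N}\sum_j (\log(T_j^{data}+1) -
  \log(T_j^{model}+1))^2$. The additive offset of 1 admits zero counts;
  `offset = 0` excludes zero pairs instead and reports how many were
  dropped. Reports should state the offset used.

The retail covariate search enumerates all $\sum_{i=0}^{5}\binom{5}{i} =
32$ subsets (`enumerateRetailVariants()`), so one loss/training-year grid
is $1 + 1 + 32 = 34$ specifications and a two-year, one-loss study yields
68 fit records. `rankModels()` sorts by log-MSE (default), $S$ or BIC,
breaking ties by fewer covariates and then spec id; its minimum-variable
filter keeps, among retail variants, only the subsets of the best
variant's covariate set — with two active covariates that is exactly four
rows (both, each alone, none).

```{r}
specs <- specGrid("poisson", "2019")
length(specs)
m <- crossValidate(specs[1:3], study)
m[, c("id", "params", "S", "bic", "log_mse")]
```

## The synthetic generator

`makeStudy()` produces studies with the statistical structure the analysis
assumes, plus the ground truth needed for recovery tests. Design choices,
made once:

* **Geography**: centroids uniform in a 600 km box (England's scale),
  resampled until every pair is at least 10 km apart; distances are planar
  Euclidean; travel times are distance at 1 km/min with symmetric
  multiplicative log-normal noise (sd 0.15), emulating road networks
  whose times are roughly, not exactly, proportional to distance.
* **Populations and covariates**: log-normal. Destination populations at
  meanlog $\log(1.1\times10^6)$, sdlog 0.45 (English police-territory
  scale; the origin is fixed at 8.9M). Per-100k covariate rates at
  realistic magnitudes — e.g. misuse admissions around 90 per 100k (sdlog
  0.5), police around 220 per 100k (sdlog 0.2), knife crime around 50 per
  100k with sdlog 0.8, reflecting the genuinely wide spread of knife-crime
  rates across forces. Raw covariates are stored as territory aggregates
  (rate × population / 1e5), so the uniform per-100k normalisation
  recovers the rates; household income is likewise stored as an aggregate
  so the same formula applies to it.
* **Counts**: independent Poisson draws per destination and year, with
  means given by a ground-truth flow model scaled to a fixed yearly
  outflow. The Poisson assumption is exactly the one the Poisson loss
  encodes; no published generative model for detected lines exists, so
  this is an assumption, stated as such. Default totals are 2000 (2019)
  and 1700 (2020), matching the observed scale and the 2020 decline.
* **Truth**: retail with $\beta = 0.014$ per minute,
  $\alpha_{knife} = -0.013$ and $\alpha_{misuse} = -7.74\times10^{-3}$ —
  the magnitudes of the best published fit — so recovery tests exercise
  realistic signal strengths.
* **Region tag**: the 16 destinations nearest the origin are tagged
  `"south"`, giving the concentration statistics a meaningful subset.

What the generator does **not** emulate: the hard social border between
the 'south' of England and the rest (no model in the comparison reproduces
it either — the synthetic south is defined by proximity, not by a
discontinuity); police take-downs netting against new detections (counts
are treated as one balance); and between-year drift (the two years are
i.i.d. draws from one truth). Passing tests therefore demonstrate correct
calibration and selection behaviour under the stated assumptions, not that
real detected-line data satisfy those assumptions.

## Problem sizes and numerical notes

The bundled tests calibrate at 37 destinations for recovery experiments
(20 replicate seeds at yearly outflows of $10^3$ and $10^5$, where the
averaged estimates recover the truth and the bias shrinks with outflow)
and 3–15 destinations for oracle comparisons: an exhaustive grid search on
a 3-destination instance must agree with `fitModel()` to the grid
resolution, and intervening populations must match exhaustive enumeration.
Retail utilities are computed in log space with a max-shift before
exponentiation; gravity weights are likewise accumulated as $b\log m +
c\log d$ before exponentiation, so large populations cannot overflow.
Per-seed retail $\alpha$ estimates at these signal strengths are noisy
(the softmax Fisher information per covariate is of order
$T_i \cdot \mathrm{var}(\log w)$, giving a per-seed standard error
comparable to the $|\alpha|$ values themselves at $T_i = 10^5$), which is
why recovery is assessed on the average across seeds.

## Known limitations

* Only single-origin studies are modelled; multi-hub structure is out of
  scope.
* The admissions covariates can be normalised per 100k (default) or per
  hospital bed per capita; which normalisation produced the published
  headline models is not decidable from the available description, so both
  are exposed and the default follows the per-population variable naming.
* GeoJSON output is attribute annotation only — observed, modelled and
  difference (model − data, positive = overestimation) per territory;
  no cartography.
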