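# countylines

Spatial interaction modelling of county-lines drug distribution: which
territorial logic explains how detected supply lines from a hub city
(London) distribute across destination police force territories?

The package fits and compares three single-origin flow models, each
constrained to the observed yearly total outflow
`T_i = sum_j T_ij`:

* **gravity** — `T_ij ∝ m_j^b d_ij^c`, population pull with a power of
  distance (the "traditional model" benchmark);
* **radiation** — flow proportional to the absorption probability
  `P(1 | n_i, n_j, n_ij)` with opportunities `n = ρ·population` and
  intervening opportunities `n_ij` (territories strictly closer to the
  origin than the destination), absorption exponent `r`;
* **retail** (entropy-maximising) — softmax shares of the utility
  `u_j = Σ_n α_n log w_j^(n) − β c_ij`, where `w_j^(n)` are per-100k
  covariate rates (drug-misuse and drug-poisoning hospital admissions,
  police officers, gross disposable household income, knife crime) and
  `c_ij` is the travel time in minutes.

Calibration minimises a Gaussian or Poisson penalised loss with an L2
ridge (`λ = 1`) by a deterministic multi-start optimiser. All `2^5 = 32`
retail covariate subsets are enumerated alongside one gravity and one
radiation spec per loss and training year, compared by twofold
cross-validation across the two study years and ranked by Sørensen–Dice
index `S`, `BIC = 2 log M − 2 log L̂`, and log-scale MSE. A synthetic
study generator with known ground truth makes every stage testable
without any data download; `differenceMap()` exports model-minus-data
attributes to GeoJSON.

## Worked example

```r
library(countylines)

study <- makeStudy(syntheticConfig(seed = 42))
study
#> LinesStudy: origin 'london', 37 destinations, years 2019, 2020
#>   total lines per year: 2019=1955, 2020=1612
#>   synthetic study with stored ground truth (family 'retail')

fit <- fitModel(ModelSpec("retail", c("misuse", "knife"), "poisson", "2019"),
                study)
fit
#> ModelFit: retail[knife+misuse]/poisson/2019
#>   theta: alpha_knife=0.008124, alpha_misuse=-0.0306, beta=0.01399
#>   train loss -207.588 | logLik -91.2297 | converged TRUE
```

The travel-time cost β is recovered almost exactly (truth 0.014/min); the
covariate exponents are weakly identified at this outflow (~2000 lines per
year) and wander on single draws — which is precisely why model selection
below cross-validates, and why recovery tests average over seeds.

```r
res <- runStudy(list(simulate = list(seed = 42), losses = "poisson"))
head(res$ranking[, c("rank", "id", "params", "S", "bic", "log_mse")], 4)
#>   rank                        id                params         S       bic    log_mse
#> 1    1 retail[none]/poisson/2019          beta=0.01396 0.9563800  379.8231 0.08911581
#> 2    2 retail[none]/poisson/2020          beta=0.01357 0.9745350  380.0703 0.13312128
#> 3    3   gravity[-]/poisson/2019   b=-0.0489, c=-1.915 0.8881853  884.7986 0.95409454
#> 4    4 radiation[-]/poisson/2019 rho=0.0009258, r=1.63 0.7590641 1914.6581 1.15634757
```

The retail family wins decisively over gravity and radiation (validation
`S` 0.956 vs 0.888 and 0.759; far lower BIC and log-MSE). The default
ranking applies the minimum-variable filter, so only retail variants
nested in the best variant's covariate set are shown. The share of lines
concentrated in the 16 origin-nearest ("south") territories:

```r
south <- destinationIds(study)[rowData(study)$region_tag == "south"]
round(100 * concentrationShare(lineCounts(study)[, "2019"], south), 2)
#> [1] 93.5
```

To run the same pipeline on real data, drop the five CSVs under a
directory and point `runStudy(list(data_dir = ...))` at it:
`territories.csv` (`id,name,population,lon,lat,region_tag`),
`covariates.csv` (`id` + `misuse_admissions,poisoning_admissions,
police_officers,gdhi,knife_crimes,hospital_beds`), `od_distance.csv` /
`od_travel_time.csv` (square matrices, id header, km / minutes between
each territory's most populous place), `lines.csv`
(`origin,destination,year,count`). Use `mergeLondon()` first if the two
Greater London forces are separate rows. A thin command-line wrapper
lives in `inst/scripts/clm.R` (`simulate` and `run` subcommands).

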