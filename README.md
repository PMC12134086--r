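# crabfate

Fate-tracking analysis of coral-dwelling gall crab (Cryptochiridae)
populations.

Gall crabs are obligate coral symbionts: each crab occupies a skeletal
dwelling (pit, tunnel or gall) on one host colony for life. Revisiting
tagged host colonies across survey time points makes individual-level
population processes observable through dwelling status changes. This
package is for reef ecologists running — or re-analysing — such
longitudinal symbiont surveys: it turns colony/dwelling observation tables
into classified events, turnover and mortality rates, and the inference
built on them, and it ships a synthetic survey generator emulating a
4-site × 3-transect × 5-time-point design with a mid-study bleaching
disturbance, so every stage can be exercised and tested without field
data.

## What it computes

**Events** per dwelling and transitional period (TR*r* = T*r−1* → T*r*):
colonization (`not_yet_present → occupied`), background extinction by
host-tissue overgrowth (`occupied → overgrown`), and host-mortality-driven
extinction (`occupied → empty_on_dead_skeleton`). Vacated states are
absorbing; re-occupation fails validation.

**Rates** per colony and period, with the accounting identity
`D_curr = D_prev + C − E − HM` enforced:

    turnover              = (E′ + C) / (D_prev + D_curr) × 100
    background mortality  = E  / D_prev × 100
    disturbance mortality = HM / D_prev × 100

where `E′` optionally includes host-mortality extinctions
(`include_hm`, default `TRUE`). Zero denominators yield *undefined*
(`NA`), never 0.

**Turnover model** — zero-one-inflated beta (BEINF) regression by maximum
likelihood: `y ~ BEINF(μ, σ, ν, τ)` with
`logit(μ) = β0 + β_site + β_period`, shared dispersion σ ∈ (0,1) (beta
shapes `a = μ(1−σ²)/σ²`, `b = (1−μ)(1−σ²)/σ²`), zero-probability ν, and
one-probability-given-nonzero τ, both intercept-only on the logit scale.

**Mortality tests** — colony-level permutation tests: a multi-sample
trend test of background mortality across TR1..TR4 (ANOVA-numerator
statistic, direction = sign of the slope of period means) and a
two-sample pre/post-disturbance test of disturbance mortality
(`mean(post) − mean(pre)`), with exact enumeration on small samples and
add-one Monte-Carlo p-values otherwise.

**Thermal stress** — daily means, hotspots and Degree Heating Weeks from
logger series under the NOAA convention: hotspot = anomaly above the MMM
when ≥ 1 °C, DHW = trailing 84-day hotspot sum / 7 (°C-weeks); bleaching
threshold = MMM + 1 °C (30.9 → 31.9 °C for the default regional MMM).

**Community statistics** — Hellinger transform, centred PCA, PERMANOVA
with transect nested in site (nesting-aware permutation), SIMPER with
exact Bray-Curtis conservation, and Hill diversity N0/N1/N2.

## Worked example

```r
library(crabfate)

cfg <- sim_config(seed = 42)          # the default study design
ds  <- simulate_fate_tracking(cfg)    # 516 tagged colonies, T0..T4

events <- classify_all_events(ds)
table(events$event_type)
#>              colonization                extinction host_mortality_extinction
#>                       135                        65                       186

rates <- transition_rates(ds)
rates <- rates[rates$colony_id %in% filter_analysis_set(ds)$kept, ]
head(aggregate_rates(rates, "turnover_pct"), 4)
#>   site transition  n      mean       se
#> 1   AF          1 38  9.671148 3.743057
#> 2   AF          2 43 25.453203 5.889385
#> 3   AF          3 43 33.157153 6.481259
#> 4   AF          4 36 42.989418 7.459801

keep <- !is.na(rates$turnover_pct)
fit_beinf(rates$turnover_pct[keep] / 100, site = rates$site[keep],
          time_point = rates$transition[keep], baseline_site = "AS")
#> Zero-one-inflated beta (BEINF) regression fit
#>   n = 578 (zeros: 298, ones: 131); logLik = -480.328; AIC = 980.66
#>   sigma = 0.2583  nu = 0.5156  tau = 0.4679  converged: TRUE
#>   logit-mean coefficients:
#> (Intercept)      siteAF      siteRR      siteSN time_point2 time_point3
#>     -0.9355     -0.2625     -0.0722     -0.2303      0.1279      0.3082
#> time_point4
#>      0.1684

sp <- pre_post_split(rates[rates$site == "AS", ], disturbance_time_point = 2)
two_sample_perm_test(sp$pre, sp$post, n_perm = 9999, seed = 1)
#> Permutation test (two_sided): stat = 29.8547, p = 0.0001 [Monte-Carlo (add-one), 9999 permutations]
```

Reading the output: about half the colony-periods show zero turnover
(ν ≈ 0.52 — uninhabited or static colonies stay that way) while τ ≈ 0.47
of the nonzero ones are complete replacements, the signature
both-boundaries inflation that motivates the BEINF model. Disturbance
mortality at site AS rises by ~30 percentage points after the simulated
bleaching event (p = 1e-4), the pattern the pre/post permutation test is
built to detect.

The `analysis/` directory holds the same workflow as numbered drivers
(`01_simulate.R` … `06_community.R`); each is a thin script over these
functions that prints what it found and writes its tables under
`results/`. `run_pipeline()` executes all stages in one call and is
byte-identical across runs with the same seed.

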