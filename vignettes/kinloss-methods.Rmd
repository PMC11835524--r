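---
title: "Estimating orphanhood and grandparent caregiver loss from vital statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating orphanhood and grandparent caregiver loss from vital statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinloss)
```

## The estimation problem

Orphanhood — a child under 18 experiencing the death of one or both
parents — is rarely observable directly: death registrations do not list
the decedent's surviving minor children. This package implements a
demographic attribution approach that reconstructs child bereavement from
aggregate registration data alone. Each decedent of age `a`, sex `s` and
race/ethnicity `r` in year `y` is attributed the *expected* number of
surviving children of each age `b`,

$$C_{y,a,s,r,b} = \mathrm{FR}_{y-b,\,\mathrm{band}(a-b),\,s,\,r} \times p^{\text{survive}}_{y-b,\,b+1},$$

the fertility rate of their stratum in the child's birth year times the
probability that a child born then is still alive. Multiplying band-mean
expected children by cause-specific death counts gives the parental-death
attribution `O^death`; correcting for children who lose both parents
(same-year losses via the opposite-sex mid-band hazard, averaged over the
two attributions; prior-year losses via lagged hazards) gives
de-duplicated new orphanhood; accruing incidence over the current and
previous 17 years with single-age child-survival discounting gives
prevalence, with cohorts that reach age 18 dropping out. Grandparent
caregiver loss applies survey co-residence proportions to deaths at ages
30+ (each deceased caregiver is credited a minimum of one grandchild),
and combined caregiver loss de-duplicates grandchildren already counted
under orphanhood.

### Assumptions inherited from the estimator

* **Independence of parental deaths.** The double-loss corrections assume
  the other parent dies independently, occupies the *same* age band and
  race/ethnicity, and has population-average mortality. Couple-level
  joint mortality (shared accidents, infectious disease, assortative
  frailty) is deliberately out of scope.
* **Fertility uncorrelated with mortality.** Decedents are assigned
  population-average fertility histories. The dampened-fertility
  sensitivity scenarios (`dampen_fertility()`) bound the consequences:
  rates taper along a cumulative-logistic curve to zero or half in the
  death year, with onset 0, 1 or 3 years before death.
* **Children share the parent's race/ethnicity**, and the child-survival
  probability in the attribution is not race-indexed while the child
  hazards in the prevalence accrual are — both used exactly as defined.
* **One child per deceased grandparent caregiver** — a deliberate
  minimum.

## The mid-band hazard and the scale of the double-loss corrections

The probability that the opposite-sex parent dies is taken from standard
life-table quantities: with `q = D/(P + D/2)` the annual death proportion
of a band of width `n`, the mid-band hazard is

$$ {}_{n}h_x = \frac{1}{n}\,\frac{2q}{2-q} = \frac{D}{nP}, $$

an algebraic identity the test suite checks to 1e-12 over a randomized
grid. Note that `ₙh_x` is an annualized *density* across the band: for
five-year adult bands it is about one fifth of the annual death
probability `D/P`. The same-year and prior-year double-loss corrections
built on it are therefore conservative — in the family-level
microsimulation, where the exact overlap is enumerable, the corrections
remove roughly one fifth of the true both-parents overlap (the test suite
measures both sides). Because the overlap itself is small at realistic
mortality (the corrections stay under 5% of the parental-death
attribution, and about 1% at the default study conditions), the net
effect on combined incidence is a positive bias of a few percent, which
the oracle comparisons quantify rather than hide; by-parental-sex
incidence, which the correction scale barely touches, recovers
enumerated truth to about 1% at 2×10⁵ families. Users comparing maternal
plus paternal counts with combined counts should expect the difference
to understate true double orphanhood.

## The synthetic study population

`sim_config()` / `simulate_cohort()` build an annual discrete-time
microsimulation of couples and their children:

* **Couples.** Mother birth cohorts are uniform over the range that keeps
  reproductive ages inside the simulated window (default 1985–2019). The
  father's age is sampled from the male fertility schedule relative to a
  fixed maternal reference age, independent of the mother's age — the
  estimator itself assumes no couple-age correlation.
* **Births** occur before deaths within a year and require both parents
  alive at the start of the year, the mother aged 15–49 and the father
  15–77; the birth probability is the maternal-band rate (with optional
  dampening near either parent's death). Realized rates at young maternal
  ages consequently sit slightly below the configured schedule (the
  partner must exist and be of reproductive age); the pipeline consumes
  the *realized* rates, so the estimator is unaffected.
* **Deaths** follow band-constant annual hazards by age, sex and group
  (defaults rise from about 1 per 1,000 at ages 15–19 to 0.15 at 85+,
  with a 1.4× male and 1.3× group-B multiplier — national orders of
  magnitude), with causes drawn from a configured five-cause mix.
  Children face single-age hazards (6 per 1,000 in infancy down to
  0.15–0.5 per 1,000).
* **Grandparents** (the mother's parents, 22–35 years older) carry
  caregiver roles — skip-generation 1%, most-responsible 2%,
  housing-only 3% per grandparent — and enter the emitted data only
  through the realized co-residence proportions. The emitted mortality,
  natality and population tables describe the *parental generation*, the
  closed population whose births and deaths are both tracked; mixing in
  a generation whose own children are untracked would break the
  fertility-attribution identity the estimator relies on.

`true_kin_loss()` enumerates the exact estimand from the line list: a
child counts as newly orphaned in the year of the first qualifying
parental death (dying in that same year still counts for incidence,
never for later prevalence); prevalence counts living children under 18
who ever experienced the loss, so the stock–flow identity holds exactly.

### What passing oracle tests do and do not show

The microsimulation satisfies the estimator's assumptions by
construction (independent parental deaths, fertility independent of
mortality, shared race). Agreement therefore validates the *bookkeeping*
— attribution, banding, lagging, survival discounting, aging-out — not
the assumptions themselves. Real vital statistics add everything the
generator omits: couple mortality correlation, differential fertility of
decedents, migration, misreported race and cause, multiple births, and
re-partnering. The oracle comparisons run at 2×10⁵ families (about
190,000 children), where enumerated counts are large enough that
per-year Monte Carlo noise is a few percent; the summed-over-years
comparison is the sharper one.

## Numerical and design choices

* **Band midpoints** are `(lo + hi + 1)/2` for closed bands; the open
  85+ band uses 87.5 and width 5.
* **Prior-loss lags.** For a child aged `b`, the prior-loss probability
  averages, for each lag `i = 1..b−1`, the five single-age lagged
  opposite-sex hazards of the parental band, sums over lags and **caps
  the cumulative probability at 1** (preventing negative incidence).
  Lagged ages below 15 take hazard 0; lagged years before data coverage
  reuse the earliest covered year (mirroring the constant-before
  assumption used for fertility), with a strict mode that errors
  instead.
* **Hazard-grid completion.** Opposite-sex lookups can name (band, sex)
  strata with no population; `complete_hazards()` fills them from the
  nearest younger band. These cells multiply essentially zero
  attribution weight.
* **Negative corrected incidence** is floored at 0 with a warning; how
  to treat it is genuinely open, and flooring keeps prevalence
  accumulation monotone.
* **Band-mean expected children** average single ages over the band
  intersected with the sex-specific parental range (mothers 15–66,
  fathers 15–94).
* **Caregiver prevalence** starts its survival product at lag 0 — unlike
  the orphanhood accrual, whose incidence already conditions on survival
  through the loss year — because the grandparent contributions derive
  from cross-sectional data. Implemented exactly as defined; the
  asymmetry is intentional and flagged here.
* **De-duplication defaults**: 11% of skip-generation grandchildren and
  11% of single co-residing parents already bereaved, 70% of non-skip
  households with both parents present, a 6/12-year residual exposure
  window. All configurable via `dedup_params()`.
* **Parent-hazard aggregation** weights band mortality rates by the
  birth composition of parental ages, renormalized over bands with
  population exposure; the wide paternal 55–77 natality band spreads its
  weight equally over the overlapping five-year bands.
* **Uncertainty.** Poisson replicates are rank-coupled (co-monotone)
  across years within each stratum — marginals stay exactly Poisson
  (checked by a Kolmogorov–Smirnov comparison at 10⁴ replicates) while
  temporal dependence is maximized; coupling across strata is not
  applied. 90% margins of error divide by 1.645 (the survey convention);
  normal draws for ratios and proportions truncate at 0. Summaries use
  the type-7 quantile (linear interpolation between order statistics),
  declared in the run log. Percent changes are computed per replicate
  before summarizing; the change-of-medians is also reported for
  transparency. Default 1,000 replicates; a mandatory seed makes runs
  byte-identical.
* **State estimation.** Suppressed cells (< 10 in the synthetic
  suppressor, mirroring public tabulations) are imputed with 2 (state)
  or 1 (state × race) *before* the η rescaling; η and ν fall back to 1
  with a flag when a stratum is entirely suppressed, preserving totals
  and auditability. ν is deliberately not age-specific, so within-state
  age composition is preserved and state sums match national incidence
  (the conservation test bounds the discrepancy at 0.5%). Fertility
  series interpolate by tricube-weighted local *linear* regression with
  span 0.85; trailing gaps carry the last observed value; under four
  observations the series falls back to carry-forward with a warning.
  Reliability screens exclude strata with more than two age bands under
  20 births (or deaths) and flag race-summed estimates more than 20%
  below the state estimate.
* **Problem sizes.** The test suite runs the full oracle at 2×10⁵
  families and the structural checks at 10³–10⁵; the acceptance script
  uses the same scales. These sizes put enumerated event counts in the
  hundreds-to-thousands per year, the smallest scale at which the
  stochastic comparisons are informative.

## Limitations

Counts become real-valued after comparability adjustment and are never
re-rounded. Duplicate stratum keys are always an error, never summed.
The package does not parse fixed-width registration files, reconstruct
bridged-race populations, or fetch any external portal; inputs are
normalized long-format CSV/TSV tables. The grandparent caregiver module
is a minimum-burden estimate by construction (one grandchild per
caregiver, no adjustment for loss of multiple grandparents), and its
validation is structural (proportion algebra, conservation,
de-duplication arithmetic) rather than oracle-based, because the
cross-sectional survey construction has no exact microsimulation
counterpart in the emitted tables.
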