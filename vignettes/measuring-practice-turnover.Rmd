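---
title: "Measuring practice-level GP turnover from consultation registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring practice-level GP turnover from consultation registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

In salaried, team-based primary care systems, administrative consultation
registries record *who provided care where and when*, but not contract types
or resignations. Measuring how fast the physician workforce of a primary care
centre (PCC) turns over therefore requires inferring both "being part of the
workforce" and "leaving" from the care-provision record itself. This package
implements that inference and the downstream association analysis.

Two definitions carry the whole measurement model:

* **Regular workforce.** A physician belongs to the regular workforce of
  practice *j* in calendar month *m* when they provided consultations on at
  least `min_days` distinct days at *j* during *m*. The default threshold is
  10 days; 15 and 20 days are the standard sensitivity settings. Days, not
  visits, are counted: several consultations on one day count once.

* **Spell.** A spell is a maximal period of regular care provision by one
  physician at one practice. It ends when at least `gap_days` (default 365)
  pass between consecutive consultations, so leaves of up to one year do not
  end a spell. Its duration is the number of days between the first and the
  last consultation. A spell whose last consultation lies within `gap_days`
  of the data end is *censored*: its termination cannot be confirmed.

## Turnover rates

For each practice-month with a regular workforce, the monthly turnover rate at
horizon *h* is

$$\mathrm{Turnover}_{jm} = 100 \times
  \frac{\#\{\text{members of } (j,m) \text{ whose spell ends within } h \text{ months}\}}
       {\#\{\text{members of } (j,m)\}},$$

where "ends within *h* months" means the spell's last consultation falls on or
before the last day of month *m + h*. The default horizon is 12 months;
6, 18, 24, 36, 48 and 60 months trace the spell-survival profile. Only months
whose full horizon fits inside the data window are emitted.

Monthly rates move slowly, so they are aggregated by averaging: over the
defined months of each practice-year (`annual_turnover()`), and over a
practice's years into a time-invariant practice-level rate
(`practice_average()`). Practice-years with *no* regular workforce in any
month — typically the opening year of a recently established practice —
receive the mean of the practice's observed years (`impute_missing()`), and
the imputation count is reported.

When employment records identify permanently employed physicians, a
supplementary measure avoids the spell construction entirely
(`permanent_turnover()`): the share of physicians employed on 31 January whose
employment ends during that calendar year. Hires after 31 January are excluded
from numerator and denominator alike, keeping the rate at or below 100.

Finally, `mixture_share()` reads the gap between the overall rate and the
permanent-staff rate as a two-component mixture,
$overall = (1-s)\,permanent + s\,temporary$, and solves for the temporary
share *s*; with an overall rate near 30%, a permanent rate near 14% and
temporary spells essentially always ending within a year, *s* comes out near
one fifth.

### Censoring

The last consultation of a censored spell may or may not be a true exit.
`monthly_turnover()` exposes three policies for members whose censored spell
"ends" inside the horizon: `as_ongoing` (default, conservative: the member is
counted as staying), `as_ended` (the observed last consultation is taken as
an exit) and `exclude` (the member is dropped from both numerator and
denominator). Members whose recorded end lies beyond the horizon are
unaffected. The choice matters only near the end of the data window: when the
horizon of a month reaches into the final gap-length of data, `as_ongoing`
suppresses every exit whose confirming silence extends past the data end. The
end-to-end script therefore uses `as_ended` for the headline panel, whose
final turnover year deliberately stops one year short of the data end;
sensitivity runs with the other policies are one argument away.

## Practice covariates

`build_profiles()` assembles one row per practice: mean registered patients
(size), case-mix and deprivation scores relative to the regional mean,
ownership (public/private) with its subtype (investor chain, GP partnership,
local chain, GP-owned), location class (city/commuting/town/rural) and
workload — registered patients divided by the regular workforce size,
averaged over the practice's defined months. Months without a workforce are
skipped, never divided by.

Continuous covariates are coded into **terciles of the distribution of
practice-level averages**: 1 = lowest, 2 = mid, 3 = highest, 0 = missing.
Cut points are rank-based (empirical CDF) at ranks `ceiling(n/3)` and
`ceiling(2n/3)`, with tied values assigned to the lower tercile. This
convention is fixed project-wide because quantile definitions differ across
software; with distinct values the three groups differ in size by at most one.
Workload has no missing category; a practice without a computable workload is
reported rather than coded.

## Association analysis

`fit_turnover_regression()` fits, by OLS, practice-level turnover on the
tercile dummies (reference: lowest tercile), location dummies (reference:
city) and a private-ownership indicator (reference: public), in three
specifications: full, excluding the private dummy, and excluding the workload
dummies. Standard errors are heteroskedasticity-robust with **HC1**
small-sample scaling, matching the convention of the common econometric
packages, and p-values use the t distribution with *n − k* degrees of
freedom. Missing-category dummies are estimated when present but flagged as
auxiliary. Bivariate summaries (`bivariate_summary()`) use adjacent-value
boxplot statistics: whiskers at the most extreme observations inside
$p25 - 1.5\,(p75-p25)$ and $p75 + 1.5\,(p75-p25)$, computed with R's default
type-7 quantiles. `balanced_panel_filter()` restricts to practices observed
in every year for the balanced-panel sensitivity analysis.

## The synthetic registry

Real care registries of this kind are confidential, so the package ships a
generator (`generate_registry()`) whose defaults emulate the panel the
analysis is designed for: about 160 practices over 2010–2019; 55% public
ownership, with private practices split across investor chains (25%), a
national GP partnership (6%), local chains (4%) and GP-owned practices (10%);
location shares near 49/11/17/22% for city/commuting/town/rural (normalised
to sum to one); registered patients drawn around mean 8,665 (sd 3,802);
case-mix and deprivation scores around 1 (sd 0.11 and 0.36); and a small
yearly probability of openings (0.09) and closures (0.07) yielding an
unbalanced panel with closure months after which no events are emitted.

Staffing is modelled as slots. Each practice holds `1 + Poisson(mean - 1)`
permanent slots (default mean 5.3) plus temporary slots sized so that the
*regular workforce* contains the configured temporary share (default 0.20).
Each slot is occupied by a succession of physicians with immediate
replacement. Permanent, freelance and registrar spells end by a memoryless
monthly exit hazard (defaults 0.0134, 0.25 and 1/60 — about 15% per year for
permanents); fixed-term and foundation contracts end deterministically at
expiry (geometric contract lengths with mean 4 months, and fixed 6-month
placements, respectively). `temp_contract_probs` states the target
*workforce-month composition* of temporary staff, so new-occupant draws are
inverse-duration weighted.

Three design choices deserve emphasis:

* **Wind-down months.** A physician quitting a hazard-driven spell has a final
  month with only 1–5 consultation days, below every workforce threshold.
  This makes the process seen by a workforce member exactly geometric: given
  membership in month *m*, the spell ends within *h* months with probability
  $1-(1-q)^h$, the closed form the recovery tests check. Employment end dates
  are administrative (last day of the wind-down month), which makes the
  January-workforce measure agree with the consultation-based measure in
  expectation on the same process.

* **Per-practice RNG substreams.** One root seed spawns one seed per practice,
  so enlarging `n_practices` leaves existing practices bit-identical — stable
  fixtures for regression tests. As a consequence, the hazard ground truth
  uses *theoretical* terciles of the N(1, sd) score distributions
  (`generate_covariate_panel()`), not empirical ones; the analysis-side
  empirical coding misclassifies only an O(n^{-1/2}) sliver of practices at
  the cut points.

* **Consultation days.** Physicians draw a per-day consulting intensity (0.92,
  0.78 or 0.50 with weights 0.20/0.45/0.35) and consult on a binomial number
  of the month's 22 working days, placed uniformly without replacement. The
  mixture straddles the 10/15/20-day thresholds: mean rosters shrink from
  roughly six physicians at 10 days to below two at 20 days. Visits per
  consultation day are `4 + Binomial(6, 0.5)`, giving the 6–8 interquartile
  range used as a realism check; visit volumes play no role in the rates,
  which count heads.

Newly opened practices pass through a ramp-up period (default 3 months) of
sub-threshold activity, which is what produces practice-years with no regular
workforce and exercises the imputation rule. Long permanent spells may contain
one consultation-free leave (default probability 0.05, at most 270 days), which
the gap rule absorbs by construction.

What the generator does **not** emulate: physicians moving between practices
or returning to a previous practice (the return fraction is 0 by
construction, consistent with the small observed return shares in data of this
kind), seasonal consultation patterns, patient-level visit assignment, and
the construction of case-mix or deprivation scores from microdata — scores
are drawn directly. Passing tests therefore validate the measurement
arithmetic and the estimators, not these behavioural margins of real data.

## Validation design and problem sizes

The test suite checks, among other things:

* exact equivalence of `build_spells()` / `build_workforce()` /
  `monthly_turnover()` with brute-force oracles on hundreds of random small
  event sets;
* recovery of a known permanent exit hazard (q = 0.0134) by both the
  consultation-based and the January-workforce measure, on 100 practices over
  8 years, within three Monte-Carlo standard errors of $100(1-(1-q)^{12})$;
* the mixture identity: a 20% short-contract workforce on top of ~15%/year
  permanents produces overall annual turnover near 32%;
* HC1 robust covariance against the explicit sandwich formula (to 1e-8 on a
  fixed 12-row dataset) and ±2-robust-SE coverage of known coefficients over
  200 replications of a 500-practice panel. The nominal coverage of a ±2-SE
  interval is 95.45%, a hair above the 95% floor being asserted, so the
  per-coefficient assertions carry an explicit two-binomial-SE Monte-Carlo
  allowance while the pooled coverage is asserted at 95% outright;
* recovery of a known deprivation effect on the exit hazard (+0.01 per
  tercile step) by the full pipeline at 500 practices, within two robust SEs
  of the analytic truth.

Simulation sizes (100–500 practices, 6–8 years) are chosen so the whole suite
runs in about two minutes while keeping Monte-Carlo error well inside the
asserted tolerances.

## A worked run

```{r}
library(gpturnover)

cfg <- registry_config(seed = 1)           # study-scale defaults
panel <- panel_definition(2010, 2019, final_turnover_year = 2018)
run <- run_pipeline(config = cfg, panel = panel, censor_policy = "as_ended")
run
run$fits$full
```

## Known limitations

Heads are counted, not full-time equivalents; a physician can belong to two
practices' workforces in the same month; the gap rule cannot distinguish a
long leave from an exit-and-return within the gap length; and the censoring
policies bracket, but cannot resolve, the status of spells ending near the
data end. The regression is descriptive: no causal interpretation, clustering
or model selection is attempted.
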