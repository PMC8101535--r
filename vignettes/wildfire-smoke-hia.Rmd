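---
title: "Estimating mortality attributable to wildfire smoke PM2.5"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mortality attributable to wildfire smoke PM2.5}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokehia)
```

## The problem

Wildfire smoke episodes can raise daily fine particulate matter (PM2.5)
concentrations across an entire state by an order of magnitude for a week
or two. `smokehia` estimates the excess mortality attributable to such an
episode at the county level, starting from regulatory monitor readings,
and quantifies what interventions (staying indoors, portable air
cleaners) could have avoided.

The package follows the standard attributable-fraction design of
environmental burden-of-disease calculators. For each county $i$ and
episode day $k$:

$$\mathrm{AF}_{ik} = 1 - e^{-\beta\,\Delta c_{ik}}
\qquad\text{or}\qquad
\mathrm{AF}_{ik} = \frac{\mathrm{OR} - 1}{\mathrm{OR}}\,\mathbf{1}[\text{smoke day}],$$

$$\Delta Y_{ik} = \mathrm{AF}_{ik} \times \frac{Y_{0,i}}{365} \times \mathrm{Pop}_i,$$

where $\Delta c_{ik}$ is the county-day increase in PM2.5 over the
matched baseline window, $\beta$ is the log-linear coefficient of a
concentration-response function (CRF) for total PM2.5, OR is an odds
ratio of mortality on wildfire smoke days (daily PM2.5 above
20.4 µg/m³, strictly), $Y_{0,i}$ is the county's annual cause-specific
mortality rate and $\mathrm{Pop}_i$ its exposed population. Daily excess
deaths are summed over the episode days and then over counties.

The two attribution conventions deliberately bracket the answer: the CRF
route scales with the (very large) concentration increase and likely
overestimates, because people shelter indoors during smoke episodes; the
smoke-day OR route ignores concentration magnitude beyond the threshold
and likely underestimates, because it was estimated in much milder smoke.

## Exposure construction

Monitor readings are averaged arithmetically within each county-day.
Counties without any regulatory monitor receive the unweighted mean of
their adjacent counties' same-day monitored values; imputed values never
propagate to other counties. Episode days are paired with baseline days
by day index — identical calendar dates one year apart under the default
windows — rather than by weekday, because the baseline is a matched
calendar window, not a weekday-matched control series.

Negative county-day changes ($\Delta c < 0$) are retained in the
exposure table but floored at zero inside acute (and chronic)
attribution: the target quantity is the burden of *increased* PM2.5, and
unfloored negatives would manufacture negative deaths. The flooring is an
attribution policy, not an exposure fact, which is why it is applied at
that stage rather than in `compute_deltas()`.

Nephelometer recalibration (optional, `correct_neph = TRUE`) divides
nephelometer readings above 20 µg/m³ by 1.207, reflecting a consistent
20.7% overestimate of smoke-plume concentrations relative to
gravimetric reference instruments. The correction is applied per reading,
before county averaging, because the bias is instrument-level; a test
pins the pipeline to that ordering. Only the strict primary smoke-day
rule (PM2.5 > 20.4 µg/m³) is implemented; the secondary criteria used
by the OR source study for the 9.0–20.4 µg/m³ band are not published in
a reproducible form, so `compute_deltas()` instead accepts a
user-supplied `smoke_classifier` function.

## Response functions and intervals

`beta_from_percent()` converts a "percent excess per 10 µg/m³" CRF with
the log-linear form $\beta = \ln(1 + p/100)/10$, consistent with the
exponential attributable fraction; a linear conversion ($p/1000$) is
available for sensitivity. The default response-function set
(`default_response_functions()`) is: acute all-cause CRF 0.50%
(95% CI 0.00, 1.01) per 10 µg/m³; smoke-day ORs 1.02 (1.00, 1.05)
all-cause and 1.09 (1.00, 1.18) respiratory; chronic annual CRFs 5.60%
(3.50, 7.80) all-cause and 12.90% (9.50, 16.40) cardiorespiratory.

Intervals propagate response-function uncertainty only: the whole burden
computation is re-run at the CI bounds. Because the acute CRF's lower
bound is 0.00% and both ORs' lower bounds are 1.00, every acute burden
interval is floored at exactly 0 deaths — a structural feature, not a
rounding artifact — and a property test asserts it exactly.

## Chronic annualization

The chronic route spreads the episode's floored daily increases over the
year, $\Delta c^{\mathrm{ann}}_i = \sum_k \max(\Delta c_{ik}, 0)/365$,
applies an annual-average CRF, and multiplies by the *annual* rate (no
/365). A constant 97.1 µg/m³ increase over 13 days gives an annual
increment of 3.46 µg/m³. Chronic estimates assume the cohort-derived
annual CRF applies to a one-year increment, a strong but conventional
extrapolation.

## Intervention scenarios

`apply_reduction()` scales the whole episode concentration by $1-f$, not
just its increment: interventions act on what people breathe. The
concentration change and the smoke-day flag are recomputed from the
scaled values, so large reductions de-classify smoke days. This makes
CRF-route avoided mortality continuous and monotone in $f$ while the
OR route is a step function whose jumps sit exactly at
$f^* = 1 - 20.4/c_{ik}$ — both properties are tested. Reduction levels
10/40/70/80% correspond approximately to measured indoor infiltration
factors: windows open (0.92), windows closed (0.56), DIY box fan with a
MERV 13 filter (0.3), and a HEPA portable air cleaner (0.19). Baseline
concentrations are left unreduced; the scenarios model action during the
episode only.

Poverty-targeted scenarios apply the reduction to the population below
the poverty level only; both the factual and counterfactual runs then use
the poverty population as Pop, since the untreated remainder cancels in
the difference. `pac_program_cost()` prices one HEPA air cleaner per
poverty household (population / 2.55 persons per household, rounded to
the nearest integer, at $150 per unit).

## Monte Carlo exposure uncertainty

A county mean from a handful of monitors carries within-county spatial
sampling error. `estimate_rsd()` measures it as the relative standard
deviation (sample SD / mean) of each multi-monitor county-day; the pooled
average RSD is assigned to county-days that cannot estimate their own.
`draw_exposures()` then redraws every episode county-day from a
log-normal with the observed mean and that RSD (5,000 draws and seed 123
by default; baseline concentrations stay fixed), and `mc_hia()` re-runs
the acute attribution per draw.

The log-normal is parameterized by method of moments from (mean $m$,
RSD $r$): $\sigma^2 = \ln(1+r^2)$, $\mu = \ln m - \sigma^2/2$, which
matches the right-skew of daily PM2.5 and makes the configured mean and
RSD exactly recoverable (tested within 1% at $10^5$ draws). The reported
central estimate is the mean over draws at the central response value.
The combined 95% interval takes the 2.5th percentile of draw totals at
the response function's lower CI bound and the 97.5th percentile at its
upper bound. That combination rule is a convention of this package: it
keeps the zero floor produced by null response lower bounds while
letting exposure spread widen the upper tail, the two qualitative
features such combined intervals should have. With RSD → 0 the Monte
Carlo collapses to the deterministic estimate (tested at RSD $10^{-6}$,
tolerance 0.1%), and intervals widen monotonically in RSD.

## The synthetic study generator

No monitor, census or mortality-rate data ship with the package;
`generate_study()` builds a synthetic state with the statistical
structure the analysis assumes: 39 counties on a ring adjacency with 0–8
monitors each (at least one unmonitored and one multi-monitor county, so
imputation and RSD estimation are always exercised), a 13-day episode,
baseline county-day true means around 6.0 µg/m³ (SD 4.6, truncated
above 0 by redraw), county-level episode increments around 97.1 µg/m³
with cross-county SD 28.5 (truncated at 0 by redraw — concentrations are
physical, and redraw avoids a point mass at zero), and log-normal monitor
readings around each true mean.

Defaults chosen where no published value exists, fixed once:

* `within_county_rsd = 0.25` — within-county spatial RSD of daily
  concentrations; published work reports only that an average RSD from
  multi-monitor counties was used, not its magnitude. 25% is a
  plausible spatial spread for county-scale smoke gradients.
* County populations are drawn log-uniformly on 2,200–2,250,000, giving
  the right-skewed size distribution real county populations have (a few
  metro counties, many small rural ones).
* Poverty fractions uniform on 7–20%; annual mortality rates uniform on
  0.6–1.2% (all-cause), 0.05–0.12% (respiratory), 0.2–0.45%
  (cardiorespiratory) per person-year — magnitudes typical of US county
  vital statistics.

The generator records every true county-day mean and the statewide
burden they imply (computed by direct arithmetic, independent of the
pipeline code) as a ground-truth sidecar; an end-to-end test feeds the
true means through the pipeline and requires agreement to a relative
error of 1e-9.

What the generator does **not** emulate: meteorology and plume
transport, monitor siting bias, day-to-day autocorrelation, and
spatial correlation between neighboring counties' exposures. Passing
tests therefore certify the arithmetic and the statistical machinery,
not the realism of any particular exposure surface; results on real
monitor data inherit whatever structure that data has.

## Numerical conventions

* Smoke-day classification is strictly greater-than 20.4 µg/m³; a
  county-day at exactly the threshold is not a smoke day.
* `pac_program_cost()` rounds households to the nearest integer before
  costing.
* Per-capita rankings break ties by ascending county id, so orderings
  are total and reproducible.
* All generation and simulation is seeded (defaults echo seed 123);
  `run_all()` writes a provenance record (config hash, seeds, versions)
  sufficient to regenerate every output byte-for-byte.
* Problem sizes in the test suite are scaled down (10-county states,
  500-draw Monte Carlo) because the properties under test — conservation,
  monotonicity, collapse, recovery — are size-invariant; the acceptance
  script runs the full 39-county, 5,000-draw design.

## Worked example

```{r example, eval = FALSE}
library(smokehia)
study <- generate_study(synth_config())
fit <- smoke_hia(study)
fit
scenario_table(fit$deltas, study$counties,
               default_response_functions())
pac_program_cost(sum(study$counties$poverty_population))
```

## Known limitations

County-mean exposure ignores within-county population weighting; rates
are not age-standardized; no lag structure or mortality displacement is
modeled; the cardiovascular smoke-day OR is excluded (reported
non-significant in its source); and the OR and CRF routes are alternative
conventions, not independent estimates — their spread is an uncertainty
statement, not a CI.
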