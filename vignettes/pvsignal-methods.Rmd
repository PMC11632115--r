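---
title: "Disproportionality signal detection with pvsignal: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection with pvsignal: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect case reports linking drugs to adverse
events (AEs), coded as MedDRA preferred terms (PTs). Because there is no
denominator of exposed patients, safety signals are sought by
*disproportionality*: is a given (drug, event) pair reported more often
than the rest of the database would predict? `pvsignal` implements the
standard workflow for one target drug — here illustrated throughout with
mogamulizumab, an anti-CCR4 monoclonal antibody used in T-cell
lymphoma — from raw quarterly extracts to ranked signal tables, cohort
description and time-to-onset analysis.

The counting unit everywhere is the *report–PT pair*: one deduplicated
report contributes at most once to a given drug–PT cell, however often the
PT is listed. At system-organ-class (SOC) level a report with two PTs in
the same SOC contributes two pairs, so SOC counts are sums of their member
PT counts.

## From raw tables to analysis pairs

FAERS quarters arrive as five `"$"`-delimited ASCII files (demographics,
drugs, reactions, outcomes, therapy dates). The format has no quoting
mechanism, so the reader treats `"$"` as a hard delimiter and the writer
refuses fields containing it. Identifiers stay text (leading zeros are
significant); dates stay digit strings (`YYYY`, `YYYYMM`, `YYYYMMDD`)
until arithmetic is needed.

Processing follows the conventional order:

1. **Deduplication.** A case may appear as several versions across
   quarters. For each case id the single most recent candidate survives,
   "most recent" made deterministic as the lexicographic maximum of
   (receipt date, case version, primary id). The operation is idempotent
   and order-invariant.
2. **Suspect-drug selection.** A report enters the cohort when a drug row
   with role *primary suspect* (PS; optionally also SS) carries the target
   drug after name standardization — case-folding, punctuation stripping
   and removal of a trailing biologic suffix token (e.g. `-kpkc`), then
   exact lookup in a user-supplied synonym table. Unmatched names are
   flagged, never guessed.
3. **Minimum report count.** Target-drug PTs reported by fewer than 3
   distinct reports are removed before statistics (the threshold is a
   parameter; background counts are never filtered). The boundary is
   inclusive: exactly 3 reports are retained.
4. **SOC mapping.** Each PT maps to exactly one primary SOC via a
   two-column table; unmapped PTs are dropped or kept flagged, and counted
   either way.

## The four disproportionality statistics

Every term is summarized against the database background by a 2×2 table —
`a` target-drug pairs with the term, `b` without, `c` background pairs
with the term, `d` the remainder, `N = a+b+c+d` — and four statistics are
computed.

**Reporting odds ratio.** $ROR = ad/bc$ with the Wald interval
$\exp(\ln ROR \pm z\sqrt{1/a+1/b+1/c+1/d})$, $z = 1.96$. Signal when
$a \ge 3$ and the lower bound exceeds 1.

**Proportional reporting ratio.** $PRR = \frac{a/(a+b)}{c/(c+d)}$ with
$\exp(\ln PRR \pm z\sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)})$, plus the 2×2
chi-squared statistic, by default with the Yates continuity correction
$N(|ad-bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]$ floored at zero (the
uncorrected Pearson form is a switch away). Signal when $a \ge 3$,
$PRR \ge 2$ and $\chi^2 \ge 4$, boundaries inclusive.

Zero cells leave a statistic undefined and flagged rather than imputed;
no Haldane–Anscombe 0.5 correction is applied by default, so estimates
are never silently manufactured for empty cells.

**BCPNN information component.** The Bayesian confidence propagation
neural network scores $IC = \log_2 \frac{p_{xy}}{p_x p_y}$ under
independent Beta posteriors for the joint and marginal reporting
probabilities (marginal priors Beta(1,1); joint prior calibrated so its
expectation is the product of the marginal expectations). The closed-form
posterior expectation and variance give $IC$ and its standard deviation;
$IC_{025} = IC - 2\,\mathrm{sd}$ flags a signal when positive. The closed
form is the classical log-of-posterior-means approximation: it differs
from the exact posterior mean of $IC$ by roughly
$\frac{1}{2\ln 2}\left(\frac{1}{a+1} - \frac{1}{a+b+1} - \frac{1}{a+c+1}\right)$,
and its $\log_2\frac{N+\alpha}{N+\gamma}$ prior-calibration term decays
like the reciprocal of the expected count — both negligible at the cell
counts where IC is interpreted (hundredths of a bit once $a$ and the
expected count are in the tens).
The tests verify the value against a 10⁶-draw Monte-Carlo posterior.

**MGPS empirical Bayes.** The multi-item gamma Poisson shrinker models
the observed count of each pair as Poisson with mean $\lambda E$, where
$E = (a+b)(a+c)/N$ is the count expected under independence, and the rate
ratio $\lambda$ follows a two-component gamma mixture prior
$w\,\mathrm{Ga}(\alpha_1,\beta_1) + (1-w)\,\mathrm{Ga}(\alpha_2,\beta_2)$
(shape/rate). Marginally each count is then a mixture of negative
binomials; the five hyperparameters are fitted by maximizing the summed
marginal log-likelihood over the **full drug×term grid, including zero
cells** — restricting to observed pairs would truncate the likelihood and
bias the prior upward (a defect we hit and corrected during development).
The posterior for a pair is again a gamma mixture, yielding

* $EBGM = 2^{E[\log_2 \lambda \mid a]}$, the empirical-Bayes geometric
  mean, via the digamma closed form per component (this geometric-mean
  definition matches standard FAERS tooling; the posterior arithmetic
  mean is larger), and
* $EBGM_{05}$, the 5th posterior percentile, by bracketed root-finding on
  the mixture CDF between the two component quantiles, polished with one
  Newton step — the CDF at the returned quantile is 0.05 to within 1e-8.

Signal when $EBGM_{05} > 2$. Shrinkage toward the prior is the point:
rare events with unstable raw ratios are pulled toward the database
norm, which is why MGPS is trusted for small counts.

### Optimization details

The prior fit runs in unconstrained space (log for the four positive
hyperparameters, logit for the weight), Nelder-Mead followed by a BFGS
polish, relative tolerance 1e-10, deterministic given the data and the
starting point (the classical DuMouchel values
$\alpha_1=0.2, \beta_1=0.1, \alpha_2=2, \beta_2=4, w=1/3$). Mixture
log-densities use log-sum-exp. When the data are genuinely homogeneous
the maximum-likelihood prior degenerates toward a spike — a correct
optimum, not a failure; the scorer handles arbitrarily concentrated
priors. No stratification or "squashing" of the pair grid is applied, so
fitting cost grows with the full drug×term grid; this is comfortable at
the problem sizes the package targets (thousands of pairs) but a
large-scale deployment over the whole of FAERS would want squashing.

### Joint classification

`significant_any` is the OR and `significant_all` the AND of the four
per-algorithm flags (undefined statistics never flag). Published analyses
report both: "any" mirrors screening tables at SOC level, "all" the
high-confidence PT lists. Ranking removes user-listed terms (e.g.
manifestations of the treated disease itself — an explicit exclusion
list, not a hardcoded ontology), sorts by ROR or count with deterministic
tie-breaks (larger count, then term name), and truncates to a top-k.

## Cohort summary and time to onset

The cohort table reports counts and percentages by receipt year, reporter
occupation, country and outcome. Year/reporter/country use all reports as
denominator. Outcomes use one *most severe* outcome per report (death >
life-threatening > hospitalization > disability > congenital anomaly >
required intervention > other) over the subset of reports carrying any
outcome: published outcome tables have denominators smaller than the
cohort, and most-severe-per-report over outcome-classified reports is the
convention that reproduces them. Percentages round half-up at 2 decimals.

Time to onset is the day count from the earliest full (8-digit) therapy
start date of the target drug to the report's event date. Partial or
missing dates, impossible calendar dates and negative intervals are
excluded and counted by reason. Summaries use `quantile(type = 6)` —
inclusive linear interpolation, under which the quartiles of a small
sample are attainable data values (the convention is a parameter, since
published IQRs rarely state one). The interval distribution bins days
right-inclusively at edges 7/30/60 by default, mirroring the usual
first-week / first-month / second-month / beyond narrative, with the
edges exposed as a parameter.

## The synthetic FAERS generator

Real FAERS extracts are large and MedDRA is licensed, so validation runs
on `simulate_faers()`, which emulates the structural features the
pipeline must survive:

* multi-table reports keyed by a primary id, with case ids and versions;
  a configurable fraction re-emitted as later case versions (duplicates)
  with a ground-truth resolution map;
* a target drug written under brand/generic/suffixed name variants,
  exercising standardization; one primary-suspect drug per report plus
  concomitant rows;
* event draws with popularity following a power law (exponent 1.5), so
  rare events — the regime MGPS exists for — are represented; planted
  (drug, event, λ) multipliers tilt the draw weights, and an optional
  gamma-mixture prior can drive all multipliers for prior-recovery
  experiments;
* demographic mixes (year, reporter, country, outcome presence and type)
  defaulting to the composition of a published mogamulizumab reporting
  cohort: receipt years 2018–2023, ~95% healthcare-professional
  reporters, countries led by the United States, Japan and France, ~86%
  of reports outcome-classified;
* log-normal onset gaps with median $e^{\mu} = 21$ days and
  $\sigma = 2.6$ — chosen once as a compromise reproducing the asymmetric
  interquartile range (about 2–107 days) such cohorts show; a
  configurable fraction of therapy start dates degraded to `YYYYMM` and
  of event dates placed before therapy start, for exclusion testing;
* `target_share = 0.05`: the target drug's share of reports. This is a
  deliberate scaled-down compromise — in the real database a single drug
  is a far smaller fraction, but at test problem sizes a smaller share
  would starve the cohort; 0.05 keeps the independence margins (and hence
  $E$) realistically uncontaminated by the target itself. An early draft
  used 0.3, which let the target drug distort its own expected counts —
  visible as attenuated rate ratios — and was corrected before the study
  conditions were frozen.

Same seed, same corpus, byte for byte. Ground truth (per-report suspect
drug and onset gap, duplicate map, planted multipliers) is returned
separately and never embedded in the FAERS-format files.

What the generator does *not* emulate: free-text narrative noise,
misspelled PT vocabulary, indication/dose tables, reporting-rate secular
trends, and correlated event co-occurrence beyond shared popularity.
Passing the synthetic end-to-end tests therefore demonstrates that the
machinery is correct under the stated generative model, not that any
particular real-world signal is genuine.

## Problem sizes and runtime choices

The shipped tests and the reproduction script use corpora of 300–8,000
reports, 150–200 events and 25 drugs, a 50,000-pair prior-recovery set
and 10⁶ Monte-Carlo draws; each was chosen as the smallest size at which
the checked property is stable across seeds. The end-to-end
planted-signal experiment plants λ=10 multipliers on events popular
enough to accrue ~25–200 target reports — a fair power claim; planting on
an event with an expected count of a handful of reports is below any
detection threshold the joint four-algorithm rule claims, by design.

## Known limitations

* Disproportionality quantifies reporting imbalance, not risk: no
  causal or incidence interpretation survives the missing denominator.
* No stratified or regression-adjusted variants (age/sex adjustment,
  Norén-style IC intervals) are implemented.
* The MGPS fit has no squashing, so whole-database scale would need it.
* The BCPNN closed form is the classical approximation; its IC025 uses
  the two-standard-deviation normal bound, which differs in the second
  decimal from credible-interval variants at very small counts.
* Case deduplication is key-based (case id), not probabilistic record
  linkage across different case ids.

## A worked run

```{r}
planted <- data.frame(drug = "mogamulizumab",
                      event = sprintf("Synthetic reaction %03d", c(5, 12, 25)),
                      lambda = 10)
cfg <- sim_config(seed = 1, n_reports = 3000, planted_signals = planted)
sim <- simulate_faers(cfg)
run <- run_pipeline(pipeline_config(
  tables = sim$tables, target_drug = "mogamulizumab",
  synonyms = sim$synonyms, pt_soc_map = sim$pt_soc_map))
run
summary(run$signal_pt, top_k = 5)
```
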