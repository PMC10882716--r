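---
title: "Methods: disproportionality analysis of spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality analysis of spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rorscan)
```

## The problem and the model

Spontaneous reporting databases such as FAERS accumulate voluntary reports
of suspected adverse drug reactions. Each *case* may be submitted several
times (versions), each report names one or more drugs with a role code
(primary suspect, secondary suspect, concomitant, interacting), and each
reaction is coded as a MedDRA preferred term (PT) that rolls up to a system
organ class (SOC). There is no denominator of exposed patients, so neither
incidence nor causal risk is estimable. What is estimable is
*disproportionate reporting*: whether reports naming a target drug list a
given event more often than the rest of the database does.

`rorscan` operationalizes the standard case/non-case design. Over a
de-duplicated report universe, for a drug set $D$ and event set $E$:

* $a$ = reports in $D$ listing at least one PT of $E$;
* $b$ = reports in $D$ listing none;
* $c$, $d$ = the same counts over the comparator (all other reports).

The reporting odds ratio and its Wald interval are

$$\mathrm{ROR} = \frac{ad}{bc}, \qquad
\mathrm{CI}_{95} = \exp\!\Big(\ln \mathrm{ROR} \pm z\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\Big),$$

with $z = 1.96$ by default. A pair is flagged a **signal** when $a \ge 5$
and the lower bound exceeds 1. The count floor is the only multiplicity
control applied — a deliberate mirror of common pharmacovigilance practice,
documented here as a known limitation: with ~50–90 PTs scanned, roughly
2.5% of true-null PTs will exceed the bound by chance (the test suite
verifies this rate empirically).

Counting is strictly per report: a report listing two PTs of a grouped
event category contributes one to $a$, which is what makes $a+b$ equal the
drug set's total report count. Zero cells make the estimate
`not_computable` rather than corrected; a Haldane–Anscombe $+0.5$ option
exists behind a flag (off by default) because the $a \ge 5$ rule already
excludes the tables where the correction would matter.

### Choice of comparator

"All other drugs in the database" is read literally: when a single regimen
is scanned, reports of the other regimens in the same class sit in the
comparator. `comparator = "class_exclusive"` removes the whole class from
the comparator as a sensitivity analysis. The default matches the
whole-database background convention; the alternative is strictly for
robustness checks.

## De-duplication

Two rules, applied within CASEID: keep the most recent FDA receipt date;
on ties keep the numerically larger PRIMARYID. Two open points the rules do
not settle were decided as follows:

* **Partial receipt dates** compare by their known prefix, and a
  day-precision date beats a month-precision date with the same prefix.
  Rationale: more precise is more recent knowledge. This is configurable in
  principle by pre-editing `fda_dt`; in practice FAERS receipt dates are
  complete, and the rule exists to keep dirty fixtures deterministic.
* **Non-numeric primaryids** (possible in fixtures, not in FAERS) fall
  back to lexicographic comparison.

The operation is idempotent, order-invariant and conserving (one kept
report per usable caseid); reports lacking a caseid are quarantined and
reported, never silently retained. These three properties are tested as
invariants.

## Cohort extraction

Drug matching is deliberately blunt: names are upper-cased,
punctuation-stripped, whitespace-squished, and lexicon entries must match
as whole words in either the verbatim `drugname` or the active-ingredient
field (`prod_ai`). No stemming, no edit distance — the lexicon enumerates
generic and brand names exactly, so "OZEMPIC 0.5 MG PEN" matches and
"NOZEMPICON" does not. Matching both fields (the source tables do not say
which was used) is the default and configurable via `match_fields`.

Only primary-suspect (PS) roles qualify a report for the cohort. PT→SOC
mapping is single-assignment via a user-supplied table (the MedDRA
dictionary itself is licensed and is not shipped; the packaged map in
`synth_soc_map()` is synthetic). PTs absent from the map are counted as
unmapped, never dropped. A report naming two regimens as primary suspect
counts once overall and once per regimen, so per-regimen rows may sum to
more than the overall row — the convention implied by per-drug
characterization tables in this literature.

## Descriptive characterization

Percentages are computed against the stratum case count and rounded
half-up to two decimals (the convention that reproduces published table
arithmetic exactly; base R's banker's rounding does not). Every
categorical block carries an explicit Unknown level so counts always sum
to the stratum size. Ages are converted to years from FAERS unit codes
(decades ×10, months /12, weeks /52, days /365.25, hours /8766) before
quantiles. A report with several outcome codes is assigned its single most
serious one (DE > LT > HO > DS > CA > RI > OT; none → Unknown), which is
what makes the outcome block sum exactly to the case count, as published
outcome tables do. Quantiles use linear interpolation between order
statistics (`stats::quantile` type 7) — an interpolating rule is provably
what produced fractional published IQR bounds such as 145.4 days, though
the exact type is not recoverable; the type is a parameter.

Indications are grouped by keyword (diabetes / weight control / blood
glucose abnormal / others / unknown) from the INDI rows linked to the
matched drug's ordinal, and reporter countries map to continents through a
small packaged lookup.

## Time to onset

Onset is the day difference between the *earliest day-precision* therapy
start among THER rows linked to a lexicon-matched PS drug ("initiation"
means first exposure) and the single DEMO event date. Three exclusion
rules, each a status rather than an exception: non-positive intervals
(`excluded_nonpositive`), start after event (`excluded_invalid_order`),
and missing or sub-day-precision dates on either side
(`excluded_missing`). Every cohort report lands in exactly one class.

Bins are right-closed on integer days — (0,30], (30,60], …, (360,∞) — so
the first bin is exactly days 1–30 and "within the initial 30 days" is the
first bin's share. (Printed bin labels in this literature overlap at their
edges; right-closed integer bins are the reading consistent with a
published 48.58% first-bin share at 734/1,511.) Regimens with fewer than
`min_n = 2` included records are marked insufficient and their quantiles
withheld, mirroring how sparse regimens are reported.

No single canonical test exists for comparing onset distributions in this
literature, so two are reported and neither is privileged: Kruskal–Wallis
globally with pairwise two-sided Mann–Whitney tests (Holm-adjusted) —
appropriate for a skewed duration summarized by median/IQR — and a
log-rank test over the cumulative curves (all onsets treated as events),
matching how the curves are displayed. The Mann–Whitney p-values are
verified in the tests against a brute-force rank-sum permutation oracle at
10,000 permutations, and the global test's type-I error against 1,000
null replicates.

## The synthetic generator

`synth_config()` defines the study conditions; `generate_faers()` realizes
them and returns exact ground truth (surviving version per case, cohort
membership, realized 2×2 cells per planted association, every
pre-censoring onset with its expected status). Defaults are a scaled-down
spontaneous-report universe chosen once:

* 50,000 cases, 2% of them target-drug reports. The real universe is ~330×
  larger with a ~1.1% drug share; shrinking the universe while slightly
  raising the drug share keeps expected co-report counts in the regime
  where the $a \ge 5$ rule operates, without changing the estimand.
* Regimen mix proportional to the six regimens' published all-AE report
  counts; planted class-level log-RORs equal to the eight published signal
  effect sizes (1.28–3.77), so recovery tests run at realistic strengths.
* Events are independent per-PT Bernoulli draws; on drug reports the
  planted PTs get a log-odds shift, which makes the *true* report-level
  odds ratio exactly $e^{\theta}$ — the property the coverage tests rely
  on. A report drawing no PT receives one fallback PT so every report has
  a reaction.
* Onsets are log-normal per regimen (heavy right tail; a published median
  of 31 days against an upper quartile of 145 is strongly right-skewed),
  with exenatide's median planted well above the others.
* Dirty-data rates: 10% duplicate versions (half with tied receipt dates
  to force the primaryid tie-break), 35%/45% missing event/start dates,
  10%/5% month-/year-truncated dates, 2% inverted date order, 2% same-day
  events. These echo the heavy date missingness visible in published
  usable-onset counts (~18% of cases).

What the generator does **not** emulate: correlated PTs within a report,
drug–drug interaction structure, reporting-rate drift over calendar time,
country-specific coding habits, and free-text name misspellings. Passing
recovery tests therefore demonstrates correctness of the pipeline's
counting and arithmetic under clean generative assumptions — not
robustness to every real-world pathology of FAERS data.

Determinism is part of the contract: identical configurations produce
byte-identical file bundles, and the duplicate-planting helper records
which version must survive, giving the de-duplication tests an exact
oracle.

## Numerical and degenerate-input choices

* Rounding: half-up at two decimals for percentages, with an epsilon guard
  against binary representation artifacts.
* Date parsing never raises; impossible calendar dates, zero sentinels and
  garbled strings become precision `none`.
* `compute_ror` requires all cells positive (unless Haldane is enabled);
  reciprocity (swapping event columns inverts the ROR and mirrors the CI)
  and exact unity under proportional tables are tested identities.
* Empty quantile inputs yield absent results, not zeros; an empty report
  universe is a hard error for contingency building.
* Test problem sizes (universes of 1,200–6,000 cases, 10–30 generator
  seeds, 1,200–1,500 simulated tables, 10,000 permutations) were chosen as
  the smallest sizes at which the binomial/Monte-Carlo tolerances used in
  the assertions are decisive.

## Interfaces

All stage outputs are delimited text plus a JSON manifest with row counts,
an attrition log (raw → de-duplicated → cohort → target-SOC cases) and a
configuration hash, so any artifact is re-derivable from the manifest and
config. `exec/rorscan` wraps `run_pipeline()` for shell use. Plotting
(`plot_onset_curves()`) is optional and requires ggplot2.

## Limitations

Beyond the generator's simplifications: no probabilistic cross-caseid
duplicate detection, no Bayesian disproportionality (BCPNN, EBGM), no
Weibull onset modelling, no spelling-tolerant drug matching, and no
multiplicity adjustment of the signal screen beyond the count floor. The
method detects reporting associations; it neither shows causality nor
quantifies risk.
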