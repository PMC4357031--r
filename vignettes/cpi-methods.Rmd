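---
title: "The Community Priority Index: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Community Priority Index: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpindex)
```

## The problem

Community-based organizations routinely have to choose a small number of
issues to act on from a long candidate list. Voting and consensus-building
techniques (nominal groups, Delphi panels, focus groups) elicit the list
and the opinions, but they do not by themselves produce a quantitative,
comparable measure that balances how much an issue *matters* against how
*actionable* it is. The Community Priority Index fills that gap: each
stakeholder scores each issue on a k-point Likert scale against several
decision criteria — importance and changeability by default — and the CPI
aggregates the panel's scores into one number per issue.

## Model and assumptions

Let $x_{iqc} \in \{1, \dots, k\}$ be stakeholder $i$'s score for issue $q$
on criterion $c$, with abstentions recorded as missing. The package
computes:

$$\bar{x}^{*}_{qc} \;=\; \frac{\sum_{i \in R_{qc}} x_{iqc}}{|R_{qc}|},
\qquad
\mathrm{CPI}_q \;=\; \prod_{c=1}^{n_c} \bar{x}^{*}_{qc},$$

where $R_{qc}$ is the set of respondents for that issue and criterion.
Dividing by the respondent count rather than the panel size is a modelling
commitment, not a convenience: stakeholders abstain for legitimate reasons
and forcing responses (or letting abstentions deflate a mean) would distort
the panel's judgment. `criterion_mean()` therefore errors — rather than
guessing — when an issue has *no* usable score on a criterion.

The product form treats criteria symmetrically and rewards issues that are
simultaneously strong on all of them: an issue rated maximally important
but minimally changeable gets the same CPI as one minimally important but
maximally changeable. No criterion weighting is offered; with equal
weights, the product is the natural conjunction.

Setting every score to its minimum or maximum gives the theoretical bounds
$[1, k^{n_c}]$ (`cpi_bounds()`), which anchor the min–max standardization

$$\mathrm{sCPI}_q = \frac{\mathrm{CPI}_q - 1}{k^{n_c} - 1} \in [0, 1].$$

Standardization is strictly increasing, so it never changes a ranking; its
value is comparability across scales (a 3-point and a 5-point study map to
the same interval) and across populations.

## Uncertainty: the percentile bootstrap

Stakeholder panels are small — often fewer than 30 people — so a normal
approximation to the sampling distribution of a product of means is not
trustworthy. `bootstrap_ci()` instead resamples the issue's stakeholder
rows with replacement at the observed roster size, recomputes the CPI per
replicate, and reports the 2.5th and 97.5th percentiles of the replicate
distribution. The interval has a substantive reading: its width is the
scope of disagreement among stakeholders, and a priority whose interval
lower bound clears the high-priority cut-off is one the panel agrees on,
not merely one with a high point estimate.

Design choices that the bootstrap definition leaves open, and how this
package resolves them:

* **Resampling unit.** Whole stakeholder rows are resampled jointly across
  criteria (default), preserving the within-stakeholder correlation
  between importance and changeability scores. Independent per-criterion
  resampling is available (`resampling = "independent"`) for sensitivity
  analysis; it assumes criteria are uncorrelated within a rater, which is
  rarely plausible.
* **Replicate count.** Default $B = 10{,}000$; configurable.
* **Percentile convention.** Nearest-rank order statistics (ranks
  $\lceil 0.025B \rceil$ and $\lceil 0.975B \rceil$). On the small discrete
  resampling distributions of small panels, interpolated quantiles
  manufacture values the statistic cannot take; the order-statistic
  convention keeps endpoints inside the support. Interpolation is available
  by option.
* **Missing scores** travel through resampling as missing and are excluded
  from replicate means, mirroring the observed-data rule at replicate
  level. A replicate in which some criterion draws only missing values has
  no defined CPI; such replicates are discarded and redrawn, with a
  `max_redraws` guard against pathologically sparse items and a count of
  discards reported.
* **Reproducibility.** Each item draws from its own RNG substream derived
  deterministically from the run seed and the item id, so the interval for
  an item does not depend on how many items precede it, and a fixed seed
  reproduces results bit for bit. Global RNG state is saved and restored.

### The exhaustive oracle

For a roster of $n \le 6$ stakeholders, `exact_resample_distribution()`
enumerates all $n^n$ equally likely ordered resamples and returns the exact
distribution the Monte-Carlo bootstrap approximates;
`exact_percentiles()` applies the same nearest-rank convention to it. This
is test infrastructure promoted to a first-class function: the package's
own test suite checks that Monte-Carlo intervals at large $B$ coincide with
the enumerated truth, and the function is equally useful to a user who
wants exact intervals for a very small panel.

## Validation, classification and reporting

`validate_likert()` coerces every score outside $\{1, \dots, k\}$ —
including 0 and non-integers — to missing, logging each replacement. The
scale's domain is taken to be $1..k$ because the bounds derivation and the
standardization both require it; a 0 on the form is treated as an invalid
mark, not a lower anchor. Validation never drops records, and an item left
without usable scores is flagged and later skipped with a log entry rather
than silently vanishing from the report.

Priority classes use cut-offs on the standardized scale, by default
$< 0.3$ low, $> 0.7$ high, the closed band $[0.3, 0.7]$ intermediate. The
boundary values are assigned to the middle band because the conventional
phrasing of the bands ("0.3–0.7 intermediate") includes its endpoints; the
cut-offs themselves are admittedly arbitrary conventions and are
configurable. By default classification is applied to the *reported*
(2-decimal) standardized score so that a printed table is always
self-consistent — a printed 0.70 is never labelled high. Full-precision
classification is a flag.

Reports (`build_report()`) are stratified by target population, ranked in
descending standardized CPI within stratum with ties broken by item id,
and carry their full configuration in metadata so any report can be
regenerated from its inputs. The ranking key is the standardized CPI,
which is equivalent to ranking on the raw CPI since the map is strictly
increasing. Rendered numbers are rounded half away from zero at two
decimals (`round_half_up()`); base R's round-half-even would render some
scores one cent differently from the usual presentation of priority
tables. Full precision is retained internally and in JSON output.

## The synthetic generator

`generate_panel()` draws each stakeholder × item × criterion score
independently from an item-specific categorical distribution over $1..k$,
then masks it as missing with an item-specific abstention probability. The
scenario carries its own truth (true criterion means, true CPI), so
recovery and coverage tests compare estimates against known values.
`consensus_scenario_pair()` constructs matched scenarios with identical
means and different dispersion by mixing a base distribution with the
maximum-variance two-point distribution of the same mean — the device used
to check that weaker consensus widens intervals.

What the generator deliberately does not emulate: correlation between
criteria within a stakeholder (available only through the bootstrap's
joint resampling of real rows), rater effects (systematically lenient or
harsh stakeholders), herding or social dynamics in the panel, and
informative (non-random) abstention. Passing tests therefore demonstrate
correctness of the computational pipeline under independent random rating,
not robustness to panel sociology.

## Test problem sizes and numerical tolerances

The suite validates the pipeline at sizes chosen to make each property
sharp: brute-force CPI comparisons on panels of up to 4 stakeholders and 3
items; bootstrap-versus-enumeration checks at $B = 100{,}000$ on rosters
of 2–4 (where the exact CDF is far enough from the 2.5%/97.5% cuts that
the Monte-Carlo order statistic is determined with overwhelming
probability); interval coverage of the true CPI over 500 simulated panels
of 30 stakeholders at $B = 2{,}000$, required to land in $[0.90, 0.99]$ —
the percentile bootstrap is approximate at such sample sizes, and a tight
band around 0.95 would be a false promise; and consensus-width comparisons
averaged over 40 matched panels per scenario. Law-of-large-numbers checks
on the generator use 2,000 stakeholders with tolerances set from binomial
standard errors.

## Limitations

* The CPI is a decision aid, not a decision rule: cut-offs are
  conventions, and the index deliberately ignores cost, feasibility
  ordering and ethical weighting, which remain human judgments.
* Percentile bootstrap intervals undercover somewhat in very small panels;
  for rosters of 6 or fewer, prefer the exact enumeration.
* Equal criterion weighting is built in; a weighted-product extension
  would change the bounds and the standardization and is out of scope.
* The file format is the plain CSV rating dialect; spreadsheets and survey
  platforms must export to it.
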