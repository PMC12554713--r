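---
title: "Disproportionality signal detection for spontaneous adverse event reports"
author: "pvsignal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous adverse event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect voluntarily submitted reports linking drugs
to suspected adverse reactions. They are large, uncontrolled, duplicated and
under-reported, and support no direct estimate of incidence. What they do
support is *disproportionality analysis*: asking whether a drug–event pair
is reported more often than the rest of the database would predict. pvsignal
implements that workflow end to end for FAERS-format data, with the
motivating use case of screening twelve antiepileptic drugs (carbamazepine,
ethosuximide, phenytoin, valproic acid, gabapentin, lamotrigine,
levetiracetam, oxcarbazepine, topiramate, zonisamide, eslicarbazepine,
lacosamide) for osteopenia, a reduced-bone-density event relevant to
long-term anticonvulsant therapy.

A signal here is a statistical alert, not a causal claim: reporting odds are
distorted by notoriety, channeling, and co-medication, so every positive
pair is a hypothesis for pharmacoepidemiological follow-up.

## Data model and ETL

FAERS ships quarterly `$`-delimited ASCII tables: DEMO (one row per report
version, keyed by PRIMARYID within a case keyed by CASEID), DRUG (one row
per drug mention with a role code), REAC (one MedDRA preferred term, PT, per
row), OUTC (outcome codes), plus THER/INDI which are parsed and carried but
not consumed by any analysis here. The ETL follows the standard
FDA-recommended conventions:

* **Deduplication.** A case may be reported repeatedly (follow-up versions,
  multiple reporters). Within each CASEID the version with the latest FDA
  receipt date survives; ties are broken by the higher PRIMARYID. A dated
  report always beats an undated one — reports with unparseable `FDA_DT` are
  ordered as minus infinity. This choice (how to order missing dates) is not
  dictated by any convention we know of; it is declared here rather than
  inferred.
* **Primary suspect restriction.** Each drug mention carries a role code —
  PS (primary suspect), SS (secondary suspect), C (concomitant), I
  (interaction). A case is attributed to a drug only when that drug is a
  primary suspect, the conservative attribution used throughout.
* **Name normalization.** Reported drug names are free text. Names are
  uppercased, trailing dosage/form/salt tokens are stripped against a
  configurable stop-list, and the result is looked up exactly in an editable
  synonym dictionary (generic spellings, salts, and common brands, e.g.
  Dilantin, Depakote, Neurontin, Lamictal, Keppra, Trileptal, Topamax,
  Zonegran, Aptiom, Vimpat, Tegretol, Zarontin). There is deliberately no
  fuzzy matching by default: silent mis-assignment is worse for a screening
  system than a counted non-match. The bundled dictionary is a fixture, not
  a claim about any particular study's search strings.
* **Event hierarchy.** PTs map through a MedDRA-like four-level hierarchy
  (PT → HLT → HLGT → SOC). MedDRA itself is licensed and not shipped; the
  package bundles a small mock hierarchy covering the terms its generator
  and tests use, and accepts a full user-supplied hierarchy in the same
  `pt,hlt,hlgt,soc` CSV format. Unmapped PTs route to an `UNMAPPED`
  sentinel and are counted, never dropped.
* **Ages** arrive with unit codes (DEC, YR, MON, WK, DY, HR) and are
  converted to years (weeks divide by 52.1775, days by 365.25, hours by
  8766). An age with a missing or unknown unit is treated as missing rather
  than assumed to be years — mis-assuming units would silently mis-stratify
  the age subgroup analysis.

The target event set defaults to the single PT `OSTEOPENIA`. Published
analyses of this question sometimes blur osteopenia and osteoporosis at the
PT level, so the set is configurable; a broader bundled set adds
`OSTEOPOROSIS` and `BONE DENSITY DECREASED` for sensitivity analyses.

## The four statistics

For one drug $D$ and one event set $Y$ within an analysis universe of $n$
deduplicated cases, the 2×2 table is

|              | event $Y$ | other events |
|--------------|-----------|--------------|
| $D$ is PS    | $a$       | $b$          |
| other drugs  | $c$       | $d$          |

with expected count $E = (a+b)(a+c)/n$ under independence. The four
screening statistics are the conventional ones:

* **ROR** $= ad/bc$, with the Wald 95% interval
  $\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$. If any cell is
  zero, 0.5 is added to all four cells for this computation
  (Haldane–Anscombe). We apply the correction to both the point estimate and
  the interval — an uncorrected point estimate would be 0 or infinite and
  unusable — and the correction fires only when a zero cell occurs.
* **PRR** $= \frac{a/(a+b)}{c/(c+d)}$, accompanied by the Yates-corrected
  $\chi^2 = n(|ad-bc|-n/2)^2 / [(a+b)(c+d)(a+c)(b+d)]$, floored at 0 when
  $|ad-bc| \le n/2$. A zero margin makes PRR undefined; undefined statistics
  are flagged and can never contribute a positive call.
* **IC** $= \log_2 \frac{a+0.5}{E+0.5}$, the shrunken information component
  of the BCPNN tradition, with the standard credibility-bound approximation
  $\mathrm{IC}_{025} = \mathrm{IC} - 3.3(a+0.5)^{-1/2} - 2(a+0.5)^{-3/2}$.
* **EBGM**, DuMouchel's multi-item gamma-Poisson shrinker, described below.

The hypothesis test is the two-sided Fisher exact test (robust at the very
small counts this screening routinely produces, e.g. $a = 2$), adjusted by
Bonferroni with family size $m$ defaulting to the number of drug–event
hypotheses with a defined p-value in the run (12 for the default screen);
$m$ is configurable. The Yates $\chi^2$ is retained as the PRR companion
statistic rather than as the p-value source.

**Positivity.** A pair must first have at least `min_cases = 3` co-reports.
It is then a signal if *any* of: ROR CI lower bound > 1; PRR ≥ 2 with
$\chi^2$ ≥ 4; IC$_{025}$ > 0; EBGM05 > 2. The any-of-four rule maximizes
sensitivity, which is the usual screening posture; a stricter all-of-four
mode is available (`rule: "all"` in `thresholds.yaml`), since consensus
positivity is sometimes preferred when presenting a short list of drugs.
All thresholds live in one editable YAML file.

## The empirical Bayes shrinker

The MGPS model treats each cell of the full drug × PT grid as
$O \sim \mathrm{Poisson}(\lambda E)$ with the relative reporting rate
$\lambda$ drawn from a five-parameter mixture prior
$w\,\Gamma(\alpha_1,\beta_1) + (1-w)\,\Gamma(\alpha_2,\beta_2)$
(shape/rate). The marginal likelihood of a cell is then a two-component
negative-binomial mixture, available in closed form, so the prior is fitted
by bounded quasi-Newton maximum likelihood (L-BFGS-B on log/logit-scale
parameters, shapes and rates bounded to $[10^{-4}, 10^4]$, with an analytic
gradient) rather than EM. Because this likelihood is known to be bimodal, a
small fixed multi-start grid is run from the classic initialization
$(w, \alpha_1, \beta_1, \alpha_2, \beta_2) = (1/3, 0.2, 0.1, 2, 4)$, and the
returned prior never has lower log-likelihood than the init (ascent is
enforced; non-convergence returns the best point found, flagged, never
silently).

The posterior for a cell is again a two-gamma mixture,
$\Gamma(\alpha_k + O, \beta_k + E)$ with posterior component weight $Q$, and

$$\mathrm{EBGM} = \exp\!\big(Q\,[\psi(\alpha_1+O) - \ln(\beta_1+E)] +
(1-Q)\,[\psi(\alpha_2+O) - \ln(\beta_2+E)]\big),$$

the posterior geometric mean of $\lambda$. EBGM05 is the posterior 5th
percentile, found by bisection on the mixture CDF bracketed by the two
component quantiles, to $10^{-10}$ relative precision.

Two deliberate choices: (i) the expected counts are taken from the row and
column case-count margins of the drug × PT grid of the chosen universe, so
the cell of a target pair carries exactly the 2×2 table's $a$ and
$(a+b)(a+c)/n$ and the shrinkage borrows strength from the whole reporting
background; (ii) no count "squashing" is applied — the grids here are
desk-scale — though the fitting function accepts any cell vector, so a
squashing wrapper is trivial to add. Stratified analyses refit the prior
inside each stratum rather than pooling stratum-specific expectations; this
matches re-running the whole method per stratum, the simplest defensible
reading of a subgroup re-analysis. The fitted prior is serialized into every
run report for auditability.

A behavior worth knowing about: on backgrounds with little true
overdispersion (such as this package's own null simulations, where almost
every cell has $\lambda = 1$ exactly), the ML prior legitimately collapses
toward a point mass near 1 and EBGM shrinks even genuinely elevated cells
hard toward 1. That is correct empirical-Bayes behavior, not a defect — on
such data the ROR/IC routes carry the detection, and on real FAERS-scale
backgrounds, which are strongly overdispersed, the prior is wider and EBGM
regains its usual sensitivity.

## Subgroups and descriptives

Sex strata are F and M; age strata split at 60 years (younger < 60 ≤ older),
the cutoff used for analysis. The descriptive tables use the conventional
display bins (<18, 18–64.9, 65–85, >85) — display bins and the analysis
cutoff are different objects and are kept separate on purpose. Cases with
unknown sex or age stay in the overall analysis but are excluded from the
corresponding stratified dimension, with counts logged. Strata where a drug
has no co-reports keep their row with undefined statistics (the analogue of
a dash in a published subgroup table). Outcome codes are case-level sets: a
case reporting both hospitalization and death counts once under each code,
a convention the descriptives document rather than hide.

## The synthetic-data generator

Real FAERS extracts cannot be redistributed, so the package carries a
seeded generator whose defaults *are* the study conditions of the motivating
screen, and which gives every statistic a known ground truth:

* 12 study drugs share 40% of reports, split proportionally to their
  published report volumes in a 2005–2025 antiepileptic extract (gabapentin
  largest at ~26% of the study share, eslicarbazepine smallest); the
  remaining 60% goes to a 20-drug background pool. The 40% study share is a
  package choice — the true FAERS-wide share of these drugs is not printed
  anywhere we could use — made once so that background cells dominate the
  shrinkage grid, as they do in reality.
* Sex marginals 50.0 / 33.0 / 16.9% (F/M/unknown, normalized from their
  printed rounding), age drawn uniformly within the display bins at
  9.8 / 38.3 / 12.4 / 1.4% among knowns with 38.2% of ages missing, and
  outcome marginals matching the same descriptive distribution with ~34% of
  cases carrying no outcome code.
* Each report draws 1–3 drug rows (the first is PS; extras are
  concomitant/secondary/interacting) and 1–5 PT draws (decreasing
  probabilities 0.35, 0.30, 0.20, 0.10, 0.05 — most spontaneous reports
  carry few reaction terms); the per-draw PT distribution is the event
  marginal, scaled by any injected (drug, PT) multiplier — optionally
  restricted to a sex or age stratum — and renormalized. Reactions are the
  deduplicated set of draws. The osteopenia marginal defaults to
  $8 \times 10^{-4}$ per draw, matching the observed order of magnitude
  (181 osteopenia cases among ~207k antiepileptic reports).
* With probability `duplicate_rate` (default 0.05) a case emits an extra
  earlier-dated version with a lower PRIMARYID, exercising the
  deduplication path; `expected_table()` returns the closed-form expected
  2×2 proportions implied by the model, the oracle for calibration tests.

Events depend only on the PS drug — concomitant drugs do not modulate PTs.
That is the simplest generative model under which every statistic has an
analytically known truth. Consequences worth stating: the generator does
*not* emulate misspelled drug names, notoriety waves, co-reporting
correlations between PTs, or reporting trends over time, so passing
calibration and power tests here demonstrates correctness of the machinery
under a clean model, not robustness to those real-data pathologies.

## Numerical and degenerate-input choices

* Marginal likelihoods are computed in log space (no underflow for counts up
  to $10^6$); a non-finite cell likelihood is a hard error naming the cell.
* `fisher.test` provides the exact p-value; the suite cross-checks it
  against full hypergeometric enumeration for all tables with $n \le 40$.
* Zero cells: the 0.5 correction applies only to the ROR; the IC's +0.5
  shrinkage terms are part of its definition, not a correction.
* Tables below `min_cases` are reported with all statistics but can never be
  called positive; undefined statistics count as negative, never as errors.
* Empty analysis universes are hard errors; empty strata yield flagged rows.
* All outputs are timestamp-free, so identical input and configuration give
  byte-identical files; the run report records the config hash, universe,
  thresholds, Bonferroni family size and fitted prior.

## Problem sizes used in validation

The suite validates the statistics against independent oracles on ~1,600
randomized tables; fits the shrinker on 5,000 cells simulated from a known
prior; runs 200 null replicates of 20,000 reports for familywise error
calibration; and 20 replicates of 50,000 reports for injected-signal power
(threefold multiplier) and stratum-pattern recovery. These sizes were chosen
so that every stochastic check has enough replicates for its binomial
tolerance while the whole suite stays comfortably runnable on a laptop. The
acceptance script (`scripts/acceptance.R`) re-runs scaled versions of the
same studies from scratch.

## Known limitations

* Disproportionality is association screening: no causal inference, no
  incidence estimation, and comparator-universe choice (all ingested reports
  vs study drugs only) materially changes the background odds — which is why
  the universe is a first-class, logged parameter.
* Pre-2012 LAERS layouts are out of scope; the reader handles the post-2012
  quarterly ASCII dialect (with `gndr_cod` accepted as a `sex` alias).
* The bundled event hierarchy is a mock standing in for licensed MedDRA;
  SOC-level summaries on real data require the user's own MedDRA copy in
  the same CSV format, and the synthetic-name fixtures are labelled as such.
* MedDRA SMQ logic and fuzzy drug-name matching are intentionally absent;
  stratified-expectation MGPS (Mantel–Haenszel pooling) is not implemented —
  subgrouping re-runs the full method per stratum instead.
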