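---
title: "Methods: pedigree model, guideline rule engine and evaluation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree model, guideline rule engine and evaluation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famrisk)
```

famrisk models a family-history assessment for colorectal cancer (CRC):
a structured pedigree of the proband's blood relatives, a guideline-style
rule engine that maps the pedigree to one of four lifetime-risk categories,
two equivalent data-entry modes, and the statistical pipeline used to
compare such interfaces in a two-arm usability study. This vignette records
the model, its assumptions, and every design decision that was genuinely
open.

## The pedigree model

Twelve roles are recognised: mother, father, the four grandparents (unique
per pedigree) and six group roles — maternal and paternal aunts/uncles,
their children, the proband's siblings and children — distinguished by a
0-based `member_index`. Two classifications are pure functions of the role
and therefore can never be stored inconsistently:

* **Family side.** Mother's side (mother, maternal grandparents, maternal
  aunts/uncles and their children), father's side (symmetric), and "your
  side" (siblings and children). The assessment pools a parent's siblings'
  children with that parent's side; genealogically they are the proband's
  cousins, and the role names say so (`*_aunt_uncle_child`) even though
  such tools often label them nieces and nephews.
* **Degree.** First-degree relatives are mother, father, siblings and
  children; everyone else is second-degree. Note this is the assessment's
  operational grouping: cousins are pooled with the SDRs of their side.

Only blood relatives appear; spouses and in-laws are assumed excluded, as
is usual for heritable-risk assessment. A relative's history carries the
affected flag, an integer age at diagnosis (years, valid in (0, 120],
allowed only when affected), and three boolean signals: multiple colorectal
polyps, other Lynch-spectrum cancers, and multiple primary CRCs. The flags
may be set on an unaffected relative (a polyposis carrier without CRC);
this is the one deliberate asymmetry in the validation rules.

Validation returns violations as data rather than raising, so an intake
front-end can display them. Group sizes are capped at 7 per pooled group
(each parental side pools aunts/uncles with their children; siblings and
children are separate groups) — the calibration that makes the
questionnaire flow's page bounds come out right (below).

## The rule engine

The engine evaluates six rules and returns the highest-ranking category
with a complete trigger trace, sorted by rule identifier; the trace is
empty exactly when the category is *average*. Defaults: primary age cutoff
55 y, high-risk cutoff 50 y, Amsterdam-style cluster of ≥ 3 relatives over
≥ 2 generations, high-risk cluster of ≥ 2.

Decisions worth recording:

* **The guideline rules are reconstructions.** The deployed assessment this
  package models followed the New Zealand Guidelines Group familial-CRC
  criteria, but the exact category boundaries are not public in a form the
  package could quote; the defaults encode the standard criteria family
  (one older-onset FDR → slight; early-onset FDR or two FDR → moderate;
  same-side clusters, polyposis or Lynch-spectrum signals → potentially
  high). Every parameter, rule switch and recommendation text is
  configurable, so a programme can substitute its exact local rules.
* **Age comparisons are strict** (`< 55`, `< 50`), matching "diagnosed
  before age 55" phrasing; a diagnosis at exactly 55 therefore counts as
  older-onset.
* **Unknown ages satisfy no age comparison.** An affected FDR with unknown
  age neither triggers R1 (≥ 55) nor R2a (< 55) on its own, but still
  counts toward the count-based rules (R2b, clusters). This is the
  conservative reading; the alternative (treating unknown as early onset)
  would over-refer.
* **"Your side" counts toward both parental sides** in the cluster rules:
  siblings and children are blood relatives of both lineages, and omitting
  them would let a genuine same-lineage cluster split across the proband's
  generation and be downgraded.
* **R1 is guarded** ("and no higher rule fires") so that the trace never
  contains a lower-rank rule that the category contradicts; precedence is
  by rank with the rule-id ordering only deciding the trace order.

Monotonicity — adding an affected relative can never lower the category —
holds by construction (every rule predicate is monotone in the affected
set) and is property-tested; the engine is also checked rule-by-rule
against an independently coded brute-force evaluator on 10,000 random
pedigrees.

## The two intake modes

The questionnaire flow presents one question per page under a family-side
heading. The base sequence is 6 screening pages (named relatives), 4
group-count pages, and a terminal confirm page: 11 pages for an
all-negative history. Each affirmative screening answer and each counted
group member inserts one detail page, so the maximum traversal is
11 + 6 + 4×7 = 45 pages. The 11/45 bounds are the published behaviour of
the tool being modelled; the page inventory that attains them (6 + 4 + 1
base pages, cap 7 per pooled group, one detail page per affected relative,
relationship asked on the detail page for the side groups) is this
package's calibration — the unique simple one consistent with those
bounds. Introduction pages are not counted: the counter counts pages to
fill in. The confirm page allows a restart, which clears the answers but
keeps counting presented pages (the reported bounds therefore apply to
single-pass traversals).

The diagram intake accepts the whole form at once, with reset-plus-confirm
semantics, and funnels through the same relative constructor, so
`diagram_intake()` and `flow_to_pedigree()` agree pedigree-for-pedigree
and `render_summary()` output is byte-identical across modes — both are
property-tested. Both modes record affected relatives only (the detail
questions ask about the cancer), matching the modelled questionnaire;
personal-history-only entries are constructible through the API.

## The evaluation statistics

`analyze_study()` reproduces the two-arm evaluation procedure:

1. **Efficiency.** Per-arm mean/SD of task time; Shapiro–Wilk per arm; a
   pooled-variance two-sided t-test (Welch by flag) and a Mann–Whitney U
   test are both computed, and the normality gate — reject at α = 0.05 in
   either arm, with arm sizes below 50 — selects which one is the primary
   result, mirroring the modelled analysis (which reported both).
2. **Satisfaction.** Items flagged as reverse-anchored are recoded
   `x → 8 − x`; Little's MCAR test runs when any item is missing; a single
   completed dataset is produced by EM conditional-mean (regression)
   imputation; totals are summed per participant; Cronbach's alpha is
   computed on the completed items; then the same gated comparison.

Decisions:

* **Instrument polarity.** The 17 CSUQ-style items are anchored
  1 = strongly agree … 7 = strongly disagree on positively worded
  statements, so raw agreement scores low. The default instrument flags
  all 17 items for recoding, which is the only reading under which
  published-scale totals around 101–109 (of a maximum 119) are possible.
  A "maximum of 8×17 = 136" sometimes quoted for such scales is
  inconsistent with a 1..7 response range; the package uses 17..119.
* **Little's MCAR test** estimates the grand mean and covariance by
  maximum-likelihood EM over missingness patterns (initialisation:
  available-case means and diagonal variances; convergence when no
  parameter moves by more than 1e-6; cap 500 iterations), then sums
  `n_j (ȳ_j − μ̂_j)' Σ̂_j⁻¹ (ȳ_j − μ̂_j)` over patterns, with
  df = Σ p_j − p. A complete matrix yields no test (statistic 0, df 0,
  `applicable = FALSE`); a singular pattern covariance is reported as a
  numerical error naming the pattern. The implementation is checked
  against an independently coded row-by-row EM on toy matrices, and its
  null rejection rate is simulation-checked at the nominal 5 % on
  multivariate-normal data.
* **Imputation is deterministic** (conditional means under the EM
  estimates, observed cells untouched): the procedure calls for a single
  completed dataset, and determinism makes the whole pipeline reproducible
  without auxiliary seeds.
* **Mann–Whitney** uses exact enumeration of U over all assignments of the
  observed (possibly tied) values when both arms have ≤ 8 observations —
  standard exact routines decline ties, and Likert data are nothing but
  ties — and otherwise the SPSS-style tie-corrected normal approximation
  without continuity correction. Exactness is verified against a pairwise
  counting enumeration oracle for all arm sizes up to 6, and the
  approximation against `wilcox.test` on tie-free data.
* **Degenerate inputs** error early with stage labels: constant samples
  for the t-test, n < 3 for normality, zero total variance for alpha,
  all-tied samples for the approximate U test.

## The synthetic generators

The pedigree generator draws, per role, affection (per-role probability),
an age at diagnosis from a normal truncated to 25–95 y (default mean 65,
SD 12 — typical sporadic CRC onset), history flags conditional on
affection, and pooled group sizes on 0..7 (default heavily weighted to
small families). It exists so every property of the model can be tested on
arbitrarily many pedigrees without any data download; its defaults are not
calibrated to any population's epidemiology.

The study generator reproduces the modelled study's conditions: 90
participants; arm assignment by permuting a pool of 45 + 45 labels (the
prepared-label randomisation); exact — not in-expectation — demographic
marginals (age bands 8, 9, 9, 29, 21, 9, 5 from under-18 to over-64;
41 male; internet-use counts 11, 2, 7, 70 from least to most frequent,
taking the printed frequency table over the rounded percentage quoted
alongside it); gaussian task times per arm (89.2 ± 7.05 s and
80.89 ± 5.19 s — reported as SDs and used as SDs, though values this small
for skewed task times may well have been standard errors in the source);
satisfaction totals per arm (101.12 ± 11.9 and 108.79 ± 9.08 on the
recoded scale); and exactly 21 participants with 1–3 missing items under
an MCAR mechanism.

Satisfaction items come from a one-factor model: a participant factor
(loading 0.55) plus item residuals whose variance is solved per arm from
the configured total SD, discretized by rounding and clamping to 1..7.
Because clamping biases the mean near the scale ceiling, the latent item
mean is calibrated by root-finding so that the *discretized* expectation
equals the configured arm mean divided by 17 — the arm means are therefore
recovered unbiasedly, which is what the acceptance checks measure. Two
consequences are accepted rather than corrected: discretization attenuates
the total SD and the inter-item correlations, so Cronbach's alpha on the
default configuration lands near 0.83–0.87 rather than exactly at the 0.9
the loading targets; and the clamped items are distinctly non-normal, so
Little's chi-square approximation is mildly anti-conservative on the
17-item default fixture (rejection near 10 % at nominal 5 % in our
simulations) even though the missingness mechanism is genuinely MCAR and
the test holds its size on normal data. An optional `skew` parameter
(default off) makes the participant factor lognormal-shaped, since the
modelled satisfaction distributions were described as skewed.

What passing tests show — and do not show. The generators emulate the
study's design margins and distributional headline numbers, not real
response behaviour: no response styles, no item-content structure, no
correlation between demographics and outcomes, no informative missingness.
Pipeline correctness on these fixtures demonstrates the statistics are
computed as specified, not that the original study's p-values (which
depend on the unavailable raw data) are recovered; those are deliberately
out of scope, replaced by the oracle-equivalence and invariance suites.

## Problem sizes and numerical settings

The shipped test suite runs the rule-engine oracle equivalence on 10,000
generated pedigrees, mode-equivalence and monotonicity on 50–120, MCAR
size at 200 replicates of an 80 × 3 matrix, type-I error of the group
tests at 1,000 replicates of 45 + 45, and generator-moment convergence at
n = 4,500 — sizes chosen so the whole suite completes in about a minute
while keeping Monte-Carlo error well inside the asserted bands. EM
tolerance is 1e-6 (500-iteration cap) in the pipeline and 1e-10 in the
slow test oracle.

## Known limitations

* The default rule set is a documented reconstruction, not a certified
  transcription of any national guideline; the engine is not a clinical
  device and gives no quantitative risk percentages or penetrance-model
  output.
* The pedigree model has no general graph semantics (no half-siblings,
  consanguinity, or genotypes), and the tab-separated dialect is only
  superficially PED-like.
* Little's test inherits its chi-square asymptotics; on small samples with
  many variables (the 17-item, 90-row default is already borderline) and
  on heavily discretized data its size is approximate, as quantified
  above.
* The flow counts pages, not seconds; timing behaviour of a real interface
  is outside the model.
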