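# famrisk

Family-history assessment and risk stratification for colorectal cancer
(CRC).

Most colorectal cancers arise sporadically, but the number of affected
first- and second-degree relatives and their ages at diagnosis are among the
strongest determinants of an individual's lifetime risk, and in many health
systems they alone decide entry into an endoscopic surveillance programme.
Collecting that family history accurately — from the general public, not
from clinicians — and turning it into a guideline category is the problem
this package addresses. It is aimed at health-informatics researchers and
screening-programme developers who need an auditable, configurable,
scriptable version of such an assessment tool together with the statistics
used to evaluate its interfaces.

## What the package implements

**Pedigree model.** Twelve blood-relative roles around the proband, grouped
into three family sides — mother's side, father's side, and "your side"
(the proband's siblings and children) — and classified into first-degree
relatives (FDR: mother, father, siblings, children) and second-degree
relatives (SDR: grandparents, aunts/uncles and, following the assessment's
pooling, their children). Pedigrees validate structurally, count affected
members under composable filters, and round-trip through a JSON schema and
a tab-separated format.

**Risk engine.** A rule table maps a pedigree to one of four ordered
lifetime-risk categories with a full trigger trace:

| rule | category | condition (defaults) |
|------|----------|----------------------|
| R1 | slightly increased | exactly one affected FDR diagnosed at ≥ 55 y |
| R2a | moderately increased | any affected FDR diagnosed < 55 y |
| R2b | moderately increased | ≥ 2 affected FDR |
| R3a | potentially high | same-side cluster of ≥ 3 affected FDR/SDR spanning ≥ 2 generations, ≥ 1 diagnosed < 50 y |
| R3b | potentially high | same-side cluster of ≥ 2 affected with early onset, multiple primary CRC, or other Lynch-spectrum cancer |
| R3c | potentially high | multiple colorectal polyps in any relative |

No rule firing means average lifetime risk. Every threshold, rule switch
and recommendation text is configurable (`rule_table()`,
`load_rule_table()`); the defaults reconstruct the standard familial-CRC
guideline criteria and are documented as reconstructions.

**Two intake modes.** A sequential questionnaire flow (one question per
page, 11 pages for an empty history up to 45 for a maximal one) and a
single-form diagram intake produce identical pedigrees and byte-identical
summary reports.

**Usability statistics.** The evaluation pipeline for comparing the two
interfaces: negative-item recoding of the 17-item CSUQ satisfaction scale,
Little's MCAR test (EM-estimated mean and covariance), deterministic
single imputation by conditional means, Cronbach's alpha, per-group M/SD,
and a pooled t-test with a Shapiro–Wilk normality gate falling back to a
tie-corrected Mann–Whitney U test (exact enumeration for small groups).

**Synthetic generators.** Seeded generators for random pedigrees and for
usability-study datasets whose demographic marginals (90 participants,
45 per arm, seven age bands, 41 male, 21 participants with missing items)
are matched exactly, with gaussian task times and one-factor Likert items
per arm.

## Worked example

```r
library(famrisk)

ped <- pedigree(
  relative("mother",               affected = TRUE, age_dx = 52),
  relative("maternal_grandmother", affected = TRUE, age_dx = 49),
  relative("maternal_aunt_uncle",  affected = TRUE, age_dx = 47)
)
print(render_summary(ped))
```

```
Family history summary
======================
- mother: bowel cancer diagnosed at age 52
- maternal_grandmother: bowel cancer diagnosed at age 49
- maternal_aunt_uncle#0: bowel cancer diagnosed at age 47

Risk category: potentially high risk
Recommendation: Your family history suggests a potentially high lifetime risk. A referral to a genetic service for assessment (including possible Lynch-syndrome or polyposis testing) and an individual surveillance plan is recommended; please see your general practitioner promptly.
Please discuss this result with your general practitioner.
```

Three affected relatives on the mother's side, two generations, earliest
diagnosis at 47: the Amsterdam-style cluster rule (R3a) fires, so the
pedigree lands in the highest category and the report recommends a genetic
referral. A lone mother diagnosed at 60 would instead trigger R1 and
"slightly increased risk".

The same assessment is scriptable from the shell:

```sh
exec/famrisk assess inst/extdata/example_pedigree.tsv --format json
exec/famrisk analyze inst/extdata/synthetic_study_small.csv --json
```

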