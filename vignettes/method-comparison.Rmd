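---
title: "Comparing breast-cancer biomarker calls across IHC, image analysis and RT-qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing breast-cancer biomarker calls across IHC, image analysis and RT-qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brcaConcord)
```

## The problem

ER, PR, HER2 and Ki67 status determine systemic therapy in breast cancer,
yet each can be measured through channels with very different error
profiles: routine IHC read under time pressure ("eyeballing"), blinded
manual re-evaluation with formal nucleus counting, semi-automated digital
image analysis of the scanned slide, and RT-qPCR quantification of the
corresponding transcripts (ESR1, PGR, ERBB2, MKI67) from the same FFPE
block. `brcaConcord` implements the full comparison pipeline: quantify,
classify, measure agreement, resolve HER2, subtype, and quantify subtype
redistribution — plus a generator of synthetic paired cohorts that makes
every stage testable against known truth.

## Relative-units quantification

Each gene's replicate Cq values are reduced to a median after discarding
undetermined replicates (`NA`) and values beyond the 40-cycle detection
limit; a target with no valid replicate raises a quantification failure
rather than imputing (an undetected transcript in otherwise amplifiable
material is a data problem the analyst must see). A single surviving
replicate triggers a warning. Reference (housekeeping) genes are combined
by the arithmetic mean of their per-gene median Cqs by default; the
aggregation is configurable and recorded in the output provenance, since
assay documentation rarely pins it down.

The doubly normalized log2 expression is

$$\Delta\Delta Cq = (\bar{Cq}_{ref} - Cq_{g})_{sample} -
  (\bar{Cq}_{ref} - Cq_{g})_{control},$$

and relative units are $RU = \Delta\Delta Cq - c_g$ with $c_g$ the
marker-specific cutoff constant on the log2 scale. Two conventions need
stating because assay sheets are often ambiguous:

* **Sign.** We orient the contrast as reference − target, so that a lower
  target Cq (more transcript) gives a *higher* RU and positive RU means
  expression above the clinical cutoff. Written the other way around
  (target − reference), the same formula yields negative values for high
  expression while still being described as "positive = above cutoff";
  we resolve that internal contradiction in favour of the stated
  interpretation, which also matches how the classification thresholds
  are laid out (Positive at the top of the RU scale).
* **Cutoffs.** The $c_g$ are instrument calibration constants, not
  universal values; they must be supplied in configuration (default 0,
  meaning the ddCq scale is already centered). The synthetic generator
  sets known nonzero cutoffs so round-trip tests are closed.

Two invariants worth knowing: RU is strictly decreasing in the target Cq
with everything else fixed, and adding a constant to *every* Cq of both
runs leaves RU unchanged (so plate-wide shifts cancel). Quantifying the
calibrator against itself gives $RU = -c_g$ exactly.

## Classification

All category intervals are left-closed: a value exactly at a printed
"≥ x" breakpoint belongs to the upper category.

| Scale | ESR1 / ER | PGR / PR | ERBB2 / HER2 | MKI67 / Ki67 |
|---|---|---|---|---|
| RU | <0 Neg; [0,1.1) Low Pos; ≥1.1 High Pos | <0 Neg; [0,0.5) Low Pos; ≥0.5 High Pos | <−0.7 Neg; [−0.7,0) Equivocal; ≥0 Pos | <0 Low; ≥0 High |
| IHC | <1% Neg; [1,50)% Low Pos; ≥50% High Pos | <1% Neg; [1,20)% Low Pos; ≥20% High Pos | 0/1+ Neg; 2+ Equivocal; 3+ Pos | <20% Low; ≥20% High |

The ERBB2 equivocal zone spans 0.7 RU to the left of the cutoff: a value
there is never called Negative, mirroring the 2+ IHC score. HER2 2+ cases
reflex to dual-probe FISH, classified by the 2013 ASCO/CAP dual-probe
rules (HER2/CEP17 ratio ≥ 2.0, or <2.0 with ≥ 6.0 mean copies/cell,
amplified; <2.0 with copies in [4, 6) equivocal; otherwise negative). The
guideline edition is version-tagged in the result; later editions dropped
the ISH equivocal category and are out of scope here. A 2+ without FISH
resolves to the flagged state `Equivocal-unresolved` — absence of reflex
testing is a reportable state, not an error.

Ki67 additionally gets a tripartite zoning with lower and upper cutoffs at
9% and 30%: below 9 unequivocally Low, above 30 unequivocally High, and an
Intermediate band in between where scoring disagreement concentrates. We
take the Intermediate band as closed on both ends, `[9, 30]`, so that the
Low/High zones are strictly "unequivocal"; the alternative half-open
readings move only the measure-zero boundary cases. IHC percentages are
accepted as continuous values (image analysis reports fractions of a
percent) and are never rounded before thresholding.

## Agreement statistics

Differences are defined as first-listed method minus second (ORI − REV,
ORI − DIA); the median difference, median absolute difference and the
sample SD of the absolute differences summarize systematic and random
disagreement. The intraclass correlation is the one-way random-effects
estimator ICC(1,1),

$$\widehat{ICC} = \frac{MS_B - MS_W}{MS_B + (k-1) MS_W},$$

the sample version of between-case variance over total variance, treating
the k methods as exchangeable replicate measurements of the same case.
Negative estimates are reported as-is with a flag (clamping to zero hides
real incompatibility); a matrix with no variance at all returns `NA`
flagged `zero-variance`. Two-way models (method as a fixed or random
factor) are deliberately out of scope. Pearson's r complements the ICC
for cross-scale comparisons (percent vs RU), where only monotone
association, not absolute agreement, is meaningful.

Bland–Altman analysis reports per-case mean and difference, flagging cases
whose absolute difference strictly exceeds 10 percentage points —
"differed by *more than* 10%" is a strict inequality, so a difference of
exactly 10 is not flagged. Categorical discordance rates are count/n with
the percentage rounded half-up to one decimal: reproducing printed pairs
such as 30/96 → 31.3% requires half-up, not banker's rounding, and
`roundHalfUp()` is exported because R's `round()` would give 31.2. Where
re-assessments overlap, the union of discordant cases follows
inclusion–exclusion over inclusive per-method totals, $|A|+|B|-|A\cap B|$.
A two-proportion chi-square utility (`compareRates()`) backs "higher in
zone X" claims; no multiple-testing correction is applied because only a
handful of planned comparisons arise.

## Surrogate subtyping

The 2013 St. Gallen surrogate definitions map the four markers to five
subtypes. Luminal A-like requires HER2-negative, ER-positive, Ki67 Low
*and* PR High Positive (the ≥20% / ≥0.5 RU criterion); the PR criterion is
config-switchable (`require_pr_high = FALSE`) since earlier panel
editions split A/B on Ki67 alone. The Ki67 and PR thresholds are bound to
the classification registry — one source of truth. The RT-qPCR path uses
the RU categories throughout: ESR1/PGR positivity at RU ≥ 0, MKI67 High at
RU ≥ 0, and ERBB2 Positive at RU ≥ 0, with the equivocal zone mapping
below the cutoff (an RU-equivocal tumor is not called HER2-driven on RNA
evidence alone, and is never silently merged with the IHC/FISH status).

Two states are handled explicitly rather than left to fall through:
unresolved HER2 raises an error directing the caller to `resolveHER2()`,
and ER-negative/PR-positive tumors — a rare constellation the surrogate
tables do not address — are treated as hormone-receptor positive, land in
the Luminal B-like branch of their HER2 arm, and carry a `flagged`
attribute so downstream users can audit them. Redistribution between
methods is a full subtype cross-tabulation plus per-subtype switch rates,
$100 \cdot (\text{cases leaving } S) / (\text{cases originally } S)$.

## The synthetic cohort

`simConfig()` defaults describe a ~96-case surgical cohort enriched for
diagnostic difficulty:

* **ER**: two-component mixture — a small negative cluster (weight 10/96,
  uniform below 1%) and a broad, strongly positive Beta(4, 1.2) component
  on the percent scale. The bimodality is what makes ER concordance easy.
* **PR**: same structure, heavier negative mass (18/96) and a flatter
  positive component Beta(1.6, 1.2) — the "more heterogeneous" hormone
  receptor.
* **Ki67**: lognormal with median 16% and log-sd 0.8, right-skewed and
  centered near the 20% decision cutoff, which is exactly why Ki67
  classification is fragile (about 40% of cases land High).
* **HER2**: trimodal latent state with weights 66/13/17 of 96 for
  negative/equivocal/positive; equivocal cases draw a latent RU inside
  (−0.7, 0) and always receive FISH inputs, a configurable fraction of
  them borderline (close to the ratio-2 / 4-and-6-copy boundaries but on
  the truth-consistent side). Latent-equivocal truth resolves negative or
  positive with probability 0.7/0.3.
* **Observer model**: per-method Gaussian noise on the percent scale
  (ORI 6, REV 4, DIA 4 points), clipped to [0, 100]. The ORI read is
  additionally snapped to a 5% grid, mimicking quick eyeballing versus
  formal counting; the snap is part of the observer-imprecision model and
  is disabled when the ORI noise is zero, so the zero-noise limit is
  exact. HER2 ordinal scores misgrade into an adjacent category with
  probability 0.06 (ORI) / 0.03 (REV); there is no DIA HER2 read, since
  validated membrane-staining algorithms are not assumed, and the DIA
  subtyping path borrows the REV-resolved HER2 status.
* **Cq link**: latent log2 expression is the latent RU plus the known raw
  cutoff (ESR1 1.0, PGR 0.5, ERBB2 2.0, MKI67 1.5), mapped through
  monotone piecewise-linear anchors that make the percent and RU category
  systems agree exactly on latent values (1% ↔ 0 RU and 50% ↔ 1.1 RU for
  ER, and so on). Cq = intercept − latent + N(0, 0.15) per replicate,
  3 replicates, two reference genes (B2M, CALM2), and one positive-control
  run with latent 0 throughout.

These weights echo the printed category composition of a real diagnostic
cohort (10/86 ER, 18/78 PR, 58/38 Ki67) without claiming to estimate its
distributions; they are illustrative study conditions, fixed once.
Randomness uses one seed with per-case substreams derived arithmetically,
so enlarging a cohort never reshuffles earlier cases.

What the generator does *not* emulate: spatial heterogeneity and hot-spot
structure beyond a noise term, inter-block sampling effects (the RNA and
the slides come from the "same" latent tumor), pre-analytical failures,
correlated observer bias across markers, and FISH-equivocal results (the
generator always plants resolvable FISH so truth labels stay derivable;
user-supplied data may still contain FISH-equivocal values and the
classifier handles them). Passing tests therefore demonstrate the
pipeline's arithmetic and logic under controlled noise — not that any
real cohort's discordance rates will match.

## Numerical conventions and edge cases

* Interval classification uses `findInterval(..., left.open = FALSE)`:
  breakpoints belong to the upper category, matching "≥" semantics.
* Percentages live on the 0–100 scale everywhere; RU tables are written
  to CSV at 3 decimals, JSON metrics at full precision.
* Zero within-case variance makes the ICC exactly 1 when between-case
  variance exists, `NA` (flagged) when nothing varies; Pearson returns a
  flagged `NA` on zero variance instead of propagating `NaN`.
* The per-case Bland–Altman flag, the discordance counts and the union
  arithmetic are integer-exact; only the final percentage is rounded, and
  the raw value is always returned alongside.
* In the zero-noise limit the full pipeline reproduces the generator's
  truth labels exactly — provided the cohort contains no latent
  HER2-equivocal cases, because an RU-equivocal tumor whose FISH truth is
  positive is a *designed* cross-platform discordance (RNA below cutoff,
  FISH amplified), not noise. The end-to-end concordance test uses an
  equivocal-free configuration for precisely this reason.

## Problem sizes in the test-suite and acceptance runs

Unit and property tests run on cohorts of 4–400 cases; variance-component
and RU recovery use one 2000-case cohort (ICC tolerance 0.02 against
$\sigma^2_b/(\sigma^2_b+\sigma^2_w)$; RU mean absolute error bounded at
0.3 and worst case 1.0, both derived from propagating the 0.15-cycle
replicate noise through medians, reference averaging and the shared
calibrator draw). The planted-effect check upgrades REV Ki67 by +6 points
on 400 cases — large enough that zone concentration and low→high flow
dominance are stable, small enough to keep the plant realistic.

## Limitations

The package compares methods; it does not validate them clinically. No
outcome or survival modelling is included, IHC/FISH wet-lab quality is
out of scope, the FISH rules are the 2013 edition by design, and the
simulation's agreement statistics should not be read as estimates of any
real cohort's values. Two-way ICC models, Cohen's kappa and regression-
based method comparison (Passing–Bablok, Deming) are intentionally
absent.
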