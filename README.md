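# brcaConcord

Breast-cancer biomarker testing rests on four determinations — estrogen
receptor (ER), progesterone receptor (PR), HER2 and the proliferation marker
Ki67 — that steer endocrine therapy, anti-HER2 therapy and chemotherapy
decisions. The same tumor can be scored by routine immunohistochemistry
(ORI), by blinded manual re-evaluation of the slides (REV), by digital image
analysis (DIA), or quantified at the mRNA level by RT-qPCR, and the four
channels do not always agree. `brcaConcord` is an R package for pathologists
and biostatisticians running such method-comparison studies: it quantifies
RT-qPCR panels into clinically interpretable relative units, classifies every
channel's measurements into guideline categories, computes the paired-method
agreement statistics, resolves HER2 by reflex FISH, derives St. Gallen
surrogate molecular subtypes, and ships a synthetic paired-cohort generator
so the whole pipeline is testable end to end without patient data.

## The core quantities

**Relative units (RU).** For each target gene *g* (ESR1, PGR, ERBB2, MKI67),
with median Cq over valid replicates and a combined reference Cq (mean of
the reference-gene medians), expression is doubly normalized against a
positive-control run and centered on the marker-specific cutoff *c\_g*:

    ΔΔCq = (Cq_ref − Cq_g)_sample − (Cq_ref − Cq_g)_control
    RU    = ΔΔCq − c_g

The sign is oriented so lower target Cq (more transcript) gives higher RU,
and RU = 0 is the clinical decision boundary: RU ≥ 0 means expression above
the cutoff. Categories use left-closed intervals, e.g. ERBB2 is Negative
below −0.7 RU, Equivocal in [−0.7, 0), Positive from 0 — the equivocal zone
mirrors the 2+ IHC score and triggers reflex dual-probe FISH
(2013 ASCO/CAP rules: ratio ≥ 2 or ≥ 6 copies/cell amplified).

**Agreement.** For two aligned score vectors the package reports the median
difference, median absolute difference and SD of the absolute differences;
the one-way random-effects intraclass correlation
ICC = (MSB − MSW) / (MSB + (k−1)·MSW), i.e. between-case variance over total
variance; Pearson's r; and Bland–Altman differences with flagging of cases
differing by more than 10 percentage points. Discordance percentages are
reported rounded half-up to one decimal (30/96 → 31.3).

**Subtyping.** ER/PR/HER2/Ki67 categories combine into the surrogate
subtypes Luminal A-like, Luminal B-like (HER2−/HER2+), HER2-positive
(non-luminal) and Triple-negative; redistribution tables quantify how many
cases switch subtype when the assessment method changes.

## Worked example

```r
library(brcaConcord)
res <- runPipeline(simConfig(n_cases = 96, seed = 1))

res$agreement[res$agreement$pair == "ORI-REV",
              c("marker", "n", "median_abs_delta", "icc", "rate_over_threshold")]
#>  marker  n median_abs_delta   icc rate_over_threshold
#>      ER 96             4.53 0.957                15.6
#>      PR 96             3.23 0.979                10.4
#>    Ki67 96             4.56 0.916                20.8
```

Routine and re-evaluated reads of the same 96 simulated tumors agree to an
ICC of 0.92–0.98, but 10–21% of cases still differ by more than 10
percentage points. Scoring disagreement concentrates where the biology is
borderline — the intermediate Ki67 band between the 9% and 30% cutoffs:

```r
res$ki67_zones[, c("zone", "n", "n_discordant", "rate")]
#>          zone  n n_discordant rate
#>           Low 13            3 23.1
#>  Intermediate 59           19 32.2
#>          High 24            2  8.3
```

Those Ki67 flips matter clinically because they move luminal tumors across
the A/B boundary; with RNA data replacing IHC, 3 of 27 Luminal A-like cases
(11.1%) switch subtype:

```r
res$redistribution$RTqPCR$switch_rates[1:3, ]
#>                 subtype n_ref n_switched rate
#>          Luminal A-like    27          3 11.1
#>  Luminal B-like (HER2-)    47          9 19.1
#>  Luminal B-like (HER2+)    22          3 13.6
```

The RU table carries full provenance, and classification is one call:

```r
head(subset(res$ru_table, gene_id == "ERBB2"), 3)[, c("sample_id", "ddcq", "ru")]
#>  sample_id    ddcq      ru
#>   case_001  1.0842 -0.9158
#>   case_002 -0.1632 -2.1632
#>   case_003  1.3604 -0.6396
classifyRU("ERBB2", c(-1.2, -0.3, 0.4))
#> [1] "Negative"  "Equivocal" "Positive"
```

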