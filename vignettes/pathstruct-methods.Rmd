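---
title: "Extracting and standardising colorectal pathology reports with confidence"
author: "pathstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and standardising colorectal pathology reports with confidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathstruct)
```

## The problem

Colorectal cancer resections are reported against a fixed national
dataset — the Royal College of Pathologists (RCPath) proforma — yet a
large share of reports, and essentially all legacy reports, are free
text. Recovering the proforma fields (specimen type, tumour type and
site, maximum diameter, pT/pN/pM stage, grade, node counts, resection
status) from that text is required for registries, audit and survival
modelling, and doing it by hand does not scale.

`pathstruct` implements a two-stage large-language-model extraction
pipeline for this task, together with everything needed to *trust* it:
a per-field confidence score, per-field probability calibration, an
evaluation battery, and survival utilities to verify that the extracted
fields carry the prognostic signal they should. Because hosted model
APIs are neither reproducible nor always available, the package also
ships a synthetic report generator and a fully seeded simulated backend,
so the entire pipeline — prompts, voting, validation, confidence,
calibration, evaluation, prognosis — runs and is tested offline.

## The two-stage pipeline

For each query field $q$ the **Extractor** agent sends two differently
phrased prompts (identical semantics) and collects $N_E = 20$ replies in
total, ten per variant. Replies are parsed from JSON, normalised into
the field's controlled vocabulary (so `"T4A"`, `"pT4a"` and `"t4a"`
pool into one bucket), and aggregated by majority vote. The Extractor
consistency

$$\mathrm{EConfidence} = \frac{\#\{\text{replies equal to the modal value}\}}{N_E}$$

uses the *requested* count as denominator, so malformed replies depress
confidence rather than being silently retried: malformed output is
itself evidence of model uncertainty.

The **Validator** agent then receives the report and the Extractor's
value and returns $N_{Va} = 10$ JSON replies with three labels:
`Correctness` (correct/incorrect), `Confidence` (an integer 0–100) and
`Corrected` (its own best value). Each label is aggregated by the same
modal rule; the per-label consistencies become
$\mathrm{VCorrect}$, $\mathrm{VConfidence}$ and $\mathrm{VCorrection}$,
and $\mathrm{V\%Correct}$ is the fraction of replies asserting the
extraction is correct. If the majority judges the extraction incorrect
($\mathrm{V\%Correct} < 0.5$, strict), the modal `Corrected` value
replaces it; an exact split keeps the Extractor's value.

The raw confidence of the final value is the plain average

$$C_q = \frac{\mathrm{EConfidence} + \mathrm{VCorrect} +
\mathrm{VConfidence} + \mathrm{VCorrection} +
\mathrm{V\%Correct}}{5} \times 100 .$$

No single term is reliable on its own — sampled replies can be
consistent while wrong — so the score averages consistency across two
differently framed tasks plus the cross-agent agreement rate.

### Tie handling

Ties are resolved deterministically and conservatively, and always
flagged in the output:

* among tied modal values, the field's not-available sentinel wins — a
  tie is itself evidence of insufficient information;
* among tied non-NA values, the lexicographically smallest canonical
  value (radix order, locale-independent) wins;
* on the Validator side, `Correctness` ties resolve to *incorrect* and
  `Confidence` ties to the lower bucket (both conservative), while
  `Corrected` ties follow the Extractor rule.

Self-reported `Confidence` values are bucketed to the nearest multiple
of 5 before modal voting, so 89 vs 90 does not artificially break
unanimity; the width is configurable.

## Vocabulary, granularity, missingness

The controlled vocabulary ships as a versioned JSON document
(`inst/extdata/schema/colorectal_rcpath.json`), one object per field,
so other tumour streams can be dropped in without code changes. TNM
fields carry both granularities (broad pT4 and specific pT4a/pT4b);
`to_broad()` collapses sub-stages for broad-level evaluation. Bare
"T4"/"pT4" normalises to the broad pT4, never silently to a sub-stage.
Each field has its proforma-specific not-available sentinel (`NA`,
`pTX`, `pNX`, `pMX`, `RX`); a report-level helper treats all of them as
missing. The proforma prints no explicit NA option for specimen type,
but the prompts instruct the model it may always answer "Not
Available", so the schema includes the sentinel there too. Numeric
fields are integer millimetres (diameter, 0–160) or counts (nodes,
0–116 / 0–50); centimetre quotes are converted (×10) during
normalisation and out-of-range values are rejected as invalid rather
than clamped.

`check_report_consistency()` applies three cross-field sanity rules:
metastatic nodes cannot exceed examined nodes; the pN status must match
the metastatic count under the standard bins (0 → pN0, 1–3 → pN1, ≥4 →
pN2); and pM1 disease contradicts a complete (R0) resection, since R0
asserts no residual disease anywhere.

## Calibration

Sampled-reply consistency is systematically overconfident, so raw
$C_q$ is rescaled per field with Platt's two-coefficient sigmoid
$P(\text{correct} \mid c) = 1/(1 + e^{A_q c + B_q})$, fitted by
maximum likelihood against 0/1 correctness labels with Platt's smoothed
targets $t_+ = (N_+ + 1)/(N_+ + 2)$, $t_- = 1/(N_- + 2)$. The negative
log-likelihood is convex in $(A_q, B_q)$; the package runs BFGS
followed by Newton polishing to a gradient norm below $10^{-8}$ (at
most 200 iterations). Fields whose validation labels contain a single
class refuse to fit (with an explicit error suggesting identity
scaling); a pooled fit over all fields is available for small
validation sets but off by default. Calibration is rank-preserving, so
AUROC is identical before and after — calibration changes the meaning
of the score, not the ordering.

## The synthetic study system

`generate_case()` produces one report with known ground truth:
internally consistent field values (metastatic ≤ examined, pN derived
from the metastatic count), rendered in one of three styles (narrative,
semi-tabular, terse) with alias surface forms ("T4A", sizes in cm,
"poorly differentiated") at a configurable rate, and per-field
missingness (default 0.15) that removes the statement from the text and
sets the truth to the sentinel. `generate_cohort()` adds survival:
exponential event times whose log-hazard is linear in the ordinal pT,
pN, pM codes (defaults 0.5/0.6/0.9 per step — a strong but plausible
stage effect chosen once), with independent exponential censoring
(default rate 0.01 against a baseline hazard of 0.0005, giving roughly
a quarter censoring). The exponential form keeps closed-form sanity
checks available.

`simulated_backend()` stands in for the hosted model. Its central
design choice is that **extraction errors are report-level, not
reply-level**: for each (report, field) the simulated model either
"knows" the answer — every reply states the truth, in varying surface
forms — or consistently errs, with wrong replies massing on a
deterministic preferred alternative at the configured `concentration`
(numeric fields get geometric near-miss perturbations). A model that
misreads a report misreads it consistently; modelling errors per reply
would let 20-fold majority voting erase them, which matches neither
observed LLM behaviour nor the study conditions where per-field
accuracy is a controlled parameter. Under this design a single reply
*and* the majority-voted extraction are correct with probability
`accuracy`. The Validator judges the true correctness of the extracted
value with probability `validator_informativeness` per reply, corrects
to the truth when it rightly detects an error, and self-reports a
confidence drawn from a clipped Gaussian centred at
$50 + 45 \cdot \text{informativeness}$ with SD `self_report_noise`.

What the generator does *not* emulate: OCR noise, handwriting,
non-English fragments, multi-tumour specimens, free-text ambiguity that
is hard even for humans. Passing tests therefore show that the
aggregation, confidence, calibration and evaluation machinery is
correct under controlled error processes — not that any particular
hosted model achieves any particular accuracy on real reports.

## Evaluation choices

Scoring is exact string/integer match after normalisation, at broad or
specific granularity (both sides collapsed with `to_broad()` for
broad). A not-available extraction matching a not-available truth
counts as correct by default (`na_matches` switch). Cohen's kappa uses
marginal-product chance agreement and returns 1 by convention when both
raters are constant and equal; AUROC is the midrank Mann–Whitney
statistic; the abstention curve rejects strictly below threshold so the
curve starts at full-coverage accuracy, and an all-rejected point
carries `NA`, never a fabricated number. Numeric matching is exact by
default with an optional ±mm tolerance for diameter only.

The confidence-quality analyses (AUROC of $C_q$ against correctness,
abstention curves) are run with the correction stage disabled
(`correction_threshold = 0`), so they measure the confidence score
itself. With the simulated Validator — whose judgement is conditioned
on actual correctness — leaving correction on would repair almost every
extraction error and leave no negative class to flag; the real study
system has no such oracle, so this isolation keeps the in-silico
measurement meaningful.

## Survival utilities

Kaplan–Meier curves and the two-group log-rank test delegate to the
`survival` package. The concordance index is computed in-package
because its pair policy is part of the contract: permissible pairs are
those whose earlier time is an event (Harrell), plus time-tied pairs
with both events; concordance means the shorter survival has the higher
risk score; score ties count 0.5; time-tied event pairs count 0.5 when
the scores differ and 1 when the scores tie as well. A brute-force
pair-enumeration oracle in the test suite pins this definition, and
`survival::concordance` cross-checks it on tie-free data.

The learned survival ranking model used in the original prognostic
analysis is a separate method and is deliberately not re-implemented;
in its place `linear_risk_score()` computes a transparent weighted sum
of ordinal stage codes (sub-stages inherit their broad stage's code;
missing values take the cohort median code), which is all the
stratification and concordance utilities need. `tnm_weights()` supplies
equal unit weights on pT/pN/pM — a plain "stage sum". The
simulation-recovery analyses instead score with the cohort's generating
coefficients (0.5/0.6/0.9 per stage step), since a recovery property
should use the true model's linear predictor, and average over five
cohort seeds. Median-split
stratification sends scores at or below the median to the low-risk
group; with odd cohorts the low group gets the extra member.

## Problem sizes and reproducibility

The packaged study protocol uses: 20 Extractor + 10 Validator replies
per field; accuracy-recovery cohorts of 200 reports across all 11
fields at reply accuracies 0.6 / 0.8 / 0.95; confidence-quality
cohorts of 300 reports over four fields with heterogeneous accuracy
(two fields at 0.6, two at 0.9), five seeds per responder profile;
prognosis cohorts of n = 300 (stage-driven hazards) and n = 500 (null
hazards). Every stochastic component — generation, backend replies,
sub-sampling — derives its stream from a single user seed through a
deterministic sub-seed function, so full runs are byte-reproducible;
structured-report output omits timestamps by default for the same
reason.

## Known limitations

* Prompt wording follows the five-component structure (role, task,
  format constraints, examples, uncertainty handling) but is this
  package's own; no claim is made that it is optimal for any particular
  hosted model.
* The live backend is a transport-injection shell; rate limits,
  billing and retries beyond a bounded count are out of scope.
* The schema covers the RCPath colorectal dataset only; other tumour
  streams require a new schema document (the format is designed for
  that, the prompts' per-field content likewise).
* Calibration quality depends on the validation set: per-field fits
  need both correct and incorrect examples, which very accurate fields
  may not provide — hence the pooled-fit fallback.
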