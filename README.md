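# pathstruct

Standardisation of free-text colorectal pathology reports with per-field
confidence estimation, in R.

Pathology reports carry the fields that drive cancer registries, audit
and survival analysis — specimen type, tumour type and site, maximum
diameter, pT/pN/pM stage, histologic grade, node counts, resection
status — but in legacy and multi-centre material those fields live in
unstructured prose. `pathstruct` implements a two-stage
large-language-model pipeline that extracts each field, validates it,
and emits a structured report conforming to the UK Royal College of
Pathologists (RCPath) colorectal dataset, in both human-readable
proforma text and lossless JSON.

## The method

For each query field *q*:

1. **Extractor** — two differently phrased prompts collect
   *N<sub>E</sub>* = 20 model replies; replies are parsed, normalised
   into the field's controlled vocabulary (so "T4A", "pT4a", "t4a" pool
   together) and majority-voted. EConfidence is the modal vote share
   over all requested replies.
2. **Validator** — a second agent judges the extracted value with
   *N<sub>Va</sub>* = 10 replies, each carrying three labels
   (`Correctness`, `Confidence` 0–100, `Corrected`); per-label modal
   consistencies give VCorrect, VConfidence, VCorrection, and
   V%Correct is the fraction of replies confirming the extraction. A
   majority "incorrect" verdict substitutes the modal corrected value.
3. **Confidence** — the raw score is

   C<sub>q</sub> = (EConfidence + VCorrect + VConfidence + VCorrection + V%Correct) / 5 × 100,

   rescaled per field by Platt's sigmoid 1/(1 + exp(A<sub>q</sub>·c + B<sub>q</sub>))
   fitted against manual-validation correctness labels.

The package also provides the full evaluation battery (accuracy,
Cohen's kappa at broad and specific TNM granularity, AUROC of
confidence against correctness, abstention curves), survival utilities
(Kaplan–Meier, log-rank, Harrell's c-index, an ordinal linear risk
score with median-split stratification), and — because hosted model
APIs are neither reproducible nor free — a synthetic report generator
plus a fully seeded simulated backend so every stage runs offline.

## Worked example

```r
library(pathstruct)

case <- generate_case(42)                    # synthetic report + ground truth
backend <- simulated_backend(responder_profile(accuracy = 0.95), list(case))
rep <- extract_report(case$report_text, backend = backend,
                      seed = 7, report_id = case$report_id)
print(rep)
```

```
Standardised colorectal cancer report: case_42
Specimen type: Abdominoperineal excision (confidence 67)
Tumour type: Mucinous adenocarcinoma (confidence 68)
Tumour site: NA (confidence 79)
Maximum diameter: 59 mm (confidence 88)
Local invasion: pT4a (confidence 79)
Histologic grade: Low (confidence 78)
Examined nodes: NA (confidence 84)
Metastatic nodes: 6 (confidence 79)
Lymph node status: pN2a (confidence 88)
Distant metastatic disease: pMX (confidence 80)
Resection: R0 (confidence 78)
```

Each line is one RCPath field with its final value and the raw
confidence (0–100). `Tumour site: NA` and `Examined nodes: NA` are the
field-specific not-available sentinels: this synthetic report genuinely
omits those statements, and the pipeline reports missingness rather
than guessing. At reply accuracy 0.95 every extracted value here equals
the generator's ground truth (`case$true_values`); scoring it with
`score_extractions()` gives accuracy 1.0. The confidences sit in the
high 60s–80s rather than at 100 because the simulated validator's
self-reported confidence is noisy — exactly the overconfidence-vs-noise
trade-off that Platt calibration (`fit_platt()`, `apply_platt()`) turns
into honest probabilities given a validation table.

`write_report_json(rep)` serialises the report losslessly (vote counts,
all five confidence terms, tie flags); `read_report_json()` restores it
identically. A command-line wrapper over the same functions lives at
`inst/cli/pathstruct.R` with subcommands `simulate`, `extract`,
`evaluate`, `calibrate`.

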