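# fuzzyslim

Quantifies the probability of medication errors in hospital work processes
with a fuzzy extension of the Success Likelihood Index Methodology (SLIM).
It is aimed at patient-safety researchers and occupational health and
safety practitioners who need a transparent, auditable human reliability
analysis for medication handling — from expert-panel weighting of the
conditions that shape performance, down to a per-subtask error probability.

## The method

Human error probability (HEP) in a subtask is modelled as a log-linear
function of a Success Likelihood Index (SLI):

```
SLI     = Σ_i W_i · R_i          (ratings R_i ∈ [1, 9]; 9 = best situation)
log₁₀ HEP = a · SLI + b          (a, b solved from the HEP bounds)
```

With the default anchors — HEP = 1 at SLI = 1 and HEP = 10⁻⁴ at SLI = 9 —
the calibration is `a = -0.5`, `b = 0.5`. The performance shaping factors
(PSFs) are three categories (personal, job, organization), each a bundle
of concrete factors such as workload, fatigue or patient safety climate
(17 in the bundled taxonomy). Weights come from two fuzzy group-decision
procedures:

* **Category weights** — the panel's linguistic importance judgments are
  fused by the similarity aggregation method (pairwise opinion similarity
  → relative agreement → consensus coefficients `CC_u = β·W(E_u) +
  (1-β)·RA_u` → fuzzy weighted aggregate) and defuzzified with the
  Chen–Hwang max-min scores.
* **Factor weights** — Chang's extent-analysis fuzzy AHP over pairwise
  comparison matrices on a five-term linguistic ratio scale: fuzzy
  synthetic extents, degrees of possibility, min-normalised weight
  vector.

The package ships an emergency-department case study (task analysis of 5
tasks / 31 subtasks with its full rating sheet and published weights),
seeded synthetic generators for every input, and a CLI. See the methods
vignette (`vignettes/fuzzy-slim-methodology.Rmd`) for the model's
assumptions, defaults and limitations.

## Worked example

```r
library(fuzzyslim)

res <- reproduce_case_study()   # bundled fixtures, published weights
res[res$subtask_id %in% c("1.1", "2.4", "3.1"), ]
#>  subtask   R_P   R_J   R_O    SLI      HEP
#>      1.1 5.814 4.490 3.593 4.6835 0.014400
#>      2.4 5.928 3.925 3.033 4.3698 0.020660
#>      3.1 6.498 4.888 4.687 5.4095 0.006241
attr(res, "max_hep_subtasks")   # "2.4"
attr(res, "min_hep_subtasks")   # "3.1" "3.2"
```

Each row is one subtask of the emergency-department medication process:
its three category ratings (`R_P`, `R_J`, `R_O`), the weighted index
`SLI = 0.367·R_P + 0.311·R_J + 0.321·R_O`, and the resulting error
probability. Subtask 2.4 — transcribing medication orders from the patient
records file into the Kardex — is the most error-prone step (HEP ≈ 2.1%),
while receiving medications from the drugstore (3.1/3.2) is the safest
(HEP ≈ 0.6%). `render_report(res)` prints the full ranking;
`psf_weights()`, `ahp_weights()` and `assess()` run the same pipeline on
your own panel files (see `?fslim_cli` for the command-line interface,
wrapped by `inst/cli/fuzzyslim.R`).

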