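---
title: "Quantifying medication error probability with fuzzy SLIM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying medication error probability with fuzzy SLIM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyslim)
```

## The model

fuzzyslim estimates the probability of a medication error in each step of a
hospital work process with the Success Likelihood Index Methodology (SLIM).
The premise of SLIM is that human error probability in a subtask is driven
by a small set of performance shaping factors (PSFs). Each subtask receives
a rating $R_i \in [1, 9]$ per PSF (1 = worst conceivable situation, 9 =
best), which are combined into a Success Likelihood Index

$$\mathrm{SLI} = \sum_i W_i R_i,$$

and the index maps to a human error probability (HEP) log-linearly:

$$\log_{10} \mathrm{HEP} = a\,\mathrm{SLI} + b.$$

The constants $a, b$ are fixed by anchoring the worst situation
($\mathrm{SLI} = 1$) to a maximum credible error probability and the best
($\mathrm{SLI} = 9$) to a minimum. The defaults, `hep_max = 1` and
`hep_min = 1e-4`, give $a = -0.5$, $b = 0.5$; `slim_calibration()` solves
the two-point system for any other anchors. Base-10 logarithms are part of
the calibration's definition — the bundled case-study table is only
reproduced with $a = -0.5$ in base 10, which the test suite cross-checks.

The PSFs here are three categories — personal, job and organization-related
factors — each decomposed into concrete factors (subPSFs): 17 in total in
the bundled taxonomy (`load_taxonomy("default")`). The weights enter at two
levels:

* **category weights** $W_i$ in the SLI come from a fuzzy group-decision
  process over an expert panel (the `psf_weights()` pipeline);
* **factor weights** inside each category come from Chang's extent-analysis
  fuzzy AHP over pairwise comparison matrices (`ahp_weights()`), and turn
  factor-level ratings into a category rating via
  $R = \sum_i r_i w_i$ (`category_rating()`).

All elicitation arithmetic runs on triangular or trapezoidal fuzzy numbers
(`fuzzy_number()`), which capture the vagueness of linguistic answers like
"high importance" without forcing experts to produce crisp numbers.

## Panel consensus (similarity aggregation method)

For each judged item the panel's linguistic opinions are converted to fuzzy
numbers by a linguistic scale and fused in five steps:

1. pairwise agreement $S_{uv} = 1 - \frac{1}{J}\sum_i |a_i - b_i|$ between
   each two experts' opinions (`fz_similarity()`);
2. each expert's average agreement with the rest of the panel,
   $AA_u = \frac{1}{m-1}\sum_{v \ne u} S_{uv}$;
3. relative agreement $RA_u = AA_u / \sum_v AA_v$;
4. consensus coefficients $CC_u = \beta W(E_u) + (1-\beta) RA_u$, blending
   agreement with the expert's importance weight $W(E_u)$;
5. fuzzy aggregation $\tilde R_{AG} = \sum_u CC_u \tilde R_u$ and
   defuzzification to a crisp total score.

The blend factor $\beta \in [0,1]$ defaults to 0.4; $\beta = 0$ treats all
experts as equally important and is exposed both in the API and the CLI.
Expert importance weights are derived from profile attributes (years of
experience, education, relevancy of specialty). No canonical scoring
formula exists for these attributes, so the package uses a documented
additive ordinal score (experience binned at 5/10/20 years, education
diploma→phd scoring 1–4, relevancy low/medium/high scoring 1–3) normalised
across the panel, with a `"uniform"` preset and fully customisable level
tables. The defuzzified totals are normalised exactly (full precision) into
weights summing to 1.

Two details deserve emphasis:

* **Elicitation scale.** The seven-term triangular scale on $[0, 1]$
  returned by `fmagdm_scale()` is a package default chosen to be symmetric
  and uniformly spaced, *not* a reproduction of any published membership
  functions; studies with their own scale should load it via
  `linguistic_scale()`/`load_scale()`.
* **Published category weights.** The bundled case study uses the
  published weights $(0.367, 0.311, 0.321)$ verbatim
  (`published_category_weights()`). The raw panel judgments behind them
  were never released, so these weights are a fixture validated only for
  normalisation invariants; they sum to 0.999 because they were normalised
  *then* rounded to three decimals. They are used unnormalised because the
  case-study table is only reproducible with the printed values; the
  recompute path (`psf_weights()`) keeps full precision instead.

## Defuzzification (Chen–Hwang max-min scores)

A fuzzy total opinion on $[0,1]$ becomes crisp via the max-min reference
sets: the right score $\mu_R = \sup_x \min(\mu(x), x)$, the left score
$\mu_L = \sup_x \min(\mu(x), 1-x)$, and the total
$\mu_T = (\mu_R + 1 - \mu_L)/2$. For piecewise-linear numbers both suprema
have closed forms on the outer legs (for a triangular $(a,b,c)$:
$\mu_R = c/(1+c-b)$, $\mu_L = (1-a)/(1+b-a)$); degenerate vertical legs
reduce continuously (e.g. $\mu_R = c$ when $b = c$), implemented as the
limit value. The scores are defined only on the unit universe, so a wider
scale is affinely rescaled onto $[0,1]$ first; because defuzzified scores
are used solely for relative weighting, the rescaling constant cancels
under normalisation. The test suite checks the closed forms against a
dense-grid brute-force evaluation of the defining suprema (10,001-point
grid with two levels of local refinement — valid because the objective is
a min of quasi-concave piecewise-linear functions, hence unimodal) on
1,000 random numbers at an absolute tolerance of $10^{-4}$.

## Factor weighting (Chang extent analysis)

Within each category, factors are compared pairwise on a five-term ratio
scale (`ahp_scale()`: "Equal importance" $(1,1,1)$ up to "Very much more
importance" $(2.5,3,3.5)$). For a judgment matrix $\tilde M$:

1. synthetic extents $S_i = \sum_j \tilde M_{ij} \otimes
   (\sum_{kl} \tilde M_{kl})^{-1}$, with the inverse taken as reversed
   reciprocals;
2. possibility degrees $V(S_i \ge S_k)$: 1 when $m_i \ge m_k$, 0 when the
   supports are disjoint with $S_k$ entirely to the right, otherwise the
   intersection height of $S_i$'s falling leg with $S_k$'s rising leg,
   $(l_k - u_i)\,/\,((m_i - u_i) - (m_k - l_k))$;
3. raw scores $W'_i = \min_{k \ne i} V(S_i \ge S_k)$, normalised to sum
   to 1.

Three design points were genuinely open:

* **Zero-possibility case.** Some presentations of the method omit the
  disjoint-support case; without it the intersection-height formula
  produces out-of-range values, so the package includes $V = 0$ explicitly
  (the standard form of the method). The formula's semantics are anchored
  to "height of the intersection", which the tests validate against a
  geometric sup/min oracle rather than any particular typography.
* **Degenerate legs.** When both relevant legs are vertical and the modes
  are distinct, the supports are necessarily disjoint and the 0/1 branches
  apply; a vanishing denominator is additionally guarded to return 0.
* **Panel aggregation.** How multiple experts' matrices are pooled is not
  part of the method's core. The default pools first: a cell-wise weighted
  arithmetic mean followed by a reciprocity repair (each upper-triangle
  cell is blended with the reversed reciprocal of its mirror's mean by a
  pointwise geometric mean, and the mirror is set to the exact reciprocal),
  which keeps matrices valid and reduces to the identity for one expert or
  identical panels. `ahp_weights(mode = "per_expert")` instead derives one
  weight vector per expert and averages.

A known limitation of extent analysis is that a criterion whose extent is
wholly dominated receives weight exactly 0, erasing rank information among
dominated criteria. The recovery experiments below therefore measure
ranking *concordance* — no pair strictly ordered opposite to the ground
truth, ties permitted where the method truncates to zero — rather than
exact permutation equality, which the zero-truncation makes unattainable
for larger criterion sets.

## Synthetic data

`synthetic_spec()` and the `gen_*()` generators emulate the whole
elicitation with known ground truth: panels with random profile attributes,
linguistic opinions snapped to the scale term nearest each item's true
importance, pairwise matrices snapped (on the log scale) to the comparison
term nearest each true weight ratio, and category-level rating sheets drawn
from per-category normal profiles clipped to $[1, 9]$ (defaults matched to
the magnitude of the bundled case-study ratings: personal ≈ 6.2 ± 0.25,
job ≈ 4.2 ± 0.45, organization ≈ 4.1 ± 0.55). Judgment noise is modelled as
a one-step drift along the scale with probability `opinion_noise`
(default 0.1) — the same code path a careless questionnaire answer takes.
Ground-truth weight vectors from `gen_true_weights()` have consecutive
sorted ratios uniform in $[1.3, 1.8]$, i.e. neighbouring criteria are far
enough apart for the five-term scale (whose finest non-trivial step is
ratio 1.5) to resolve them, as real panels are only asked to compare
criteria they can tell apart. All randomness flows from one master seed
through fixed per-generator substreams, so runs are bit-reproducible.

What the generators deliberately do *not* model: systematic expert bias,
correlated opinions, within-subtask correlation of ratings, and any
calibration to the real panel (whose data are unpublished). Passing
recovery tests therefore demonstrate the pipeline's internal consistency —
inputs expressible in the elicitation vocabulary are mapped back to
weights that respect the generating ranking — not field validity of the
elicitation itself.

## Problem sizes and numerical choices

The default test run uses 1,000 random instances for each closed-form vs
grid-oracle comparison (absolute tolerance $10^{-4}$), 200 seeded
synthetic panels of 4–6 criteria and 10 experts at 10% noise for ranking
recovery (threshold 95% concordance), and 10,000 randomized trials for
HEP monotonicity. Validity tolerances are tight where arithmetic is exact
(reciprocity $10^{-9}$, weight normalisation $10^{-9}$, calibration
round-trip $10^{-12}$) and loose only where printed precision forces it
(per-category taxonomy weight sums within $10^{-3}$, since three-decimal
printed weights legitimately sum to 0.999).

## Known limitations

* The SLI is additive: interactions between factors (e.g. workload
  amplifying fatigue) are outside the model class.
* Extent-analysis weights can be exactly 0 for dominated factors; where
  full rankings among weak factors matter, a different fuzzy-AHP variant
  would be needed (not implemented here).
* The bundled case-study table carries printed-precision artefacts: the
  published category weights sum to 0.999, and exact recomputation from
  the printed category ratings reproduces most but not all HEP entries to
  half a unit in their last printed digit (the regression test reports
  the discrepant rows). The package computes at full precision and treats
  the printed values as the fixture they are.
* HEP point estimates only; no uncertainty intervals, and no
  consequence/risk scoring — the method quantifies error probability, not
  harm.
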