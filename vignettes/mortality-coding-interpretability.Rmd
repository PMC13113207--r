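---
title: "Interpreting automated underlying-cause-of-death coding: calibration, difficulty and attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting automated underlying-cause-of-death coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mortality statistics rest on the *underlying cause of death* (UCOD): the
disease or injury that initiated the chain of events leading to death,
selected from the conditions stated on a death certificate according to WHO
rules over the ICD-10 classification. Classifiers that select the UCOD from
coded certificates can reach very high accuracy, yet coding agencies will
not act on a black box. This package implements the interpretability layer
such a classifier needs before anyone trusts it:

* **confidence calibration** — does a reported confidence of 0.9 mean the
  prediction is right 90% of the time? (expected / maximum calibration
  error, reliability diagrams, post-hoc temperature scaling);
* **instance difficulty** — which certificates does the model find hard,
  and do rare or never-seen codes surface as out-of-distribution-like?
  (Variance of Gradients across training checkpoints);
* **word attribution** — which words of the certificate text drove a
  prediction? (Integrated Gradients with word-level aggregation);
* **stratified reporting** — accuracy and confidence by ICD-10 chapter and
  category, frequency tables and coverage.

Real multiple-cause mortality files are restricted, so the package ships a
synthetic world: an ICD-10-like codebook, certificates with a rule-derived
ground truth, a reverse-coding step that renders each certificate as the
sentence a text classifier consumes, and a small differentiable classifier
with checkpoint capture. Every analysis runs end to end on a laptop.

```{r, eval = FALSE}
library(mortexplain)
res <- run_pipeline(pipeline_config(seed = 1), "run1")
res$calibration$before   # ECE/MCE before temperature scaling
res$vog$frequency$table  # difficulty by code frequency band
```

## The synthetic certificate world

`build_codebook()` draws an ontology of ICD-10-style codes (letter, two
digits, optional one-digit subdivision), allocated to the 22 chapters in
proportion to the chapter mix of stated conditions observed in published US
multiple-cause data (2014–2017), with the administrative chapters XXI/XXII
at zero. Each code carries a unique synthetic title assembled from
chapter-specific clinical phrase pools, plus the flags the selection rules
need: external cause (chapter XX), injury (XIX), ill-defined (XVIII),
selectable. A `title_collision` switch deliberately gives two codes one
title, reproducing a real failure mode of reverse coding: two distinct
categories that collapse to the same sentence are indistinguishable to any
text model.

`generate_certificates()` samples 1–15 stated conditions per certificate
(1 + Poisson with a default mean of 3 conditions, matching the ~2.9
conditions per record implied by published chapter counts) over 1–4 Part 1
lines plus an optional Part 2; per-code frequencies follow a Zipf law
within each chapter (`imbalance_exponent`, default 1). Two co-occurrence
rules keep the rule engine realistic: an external cause is usually
accompanied by an injury, and an injury always has its external
circumstance stated — which is why injuries never end up as the ground
truth, mirroring the empty injury row of chapter-level accuracy tables.

The ground truth is a deliberately *simplified* WHO cascade
(`select_true_ucod()`): external-cause precedence, then a backwards walk
from the originating condition (the last code of the last used Part 1
line) skipping ill-defined, injury and non-selectable codes, then an
originating-condition fallback. The full WHO modification tables (recoding
into combination categories, linkage rules) are out of scope; the package
documents this divergence rather than pretending to implement them. One
consequence: real-world examples whose published UCOD reflects a
modification rule (e.g. a first-line infarction) will not match this
engine's answer, and that is intentional — the synthetic ground truth must
be unambiguous and recomputable.

Part 2 serialisation ("; with (<title>)") is an interface decision of this
package: published sentence examples never show contributing conditions,
so the format is isolated in one function and exercised by tests.

`split_dataset()` stratifies by the true UCOD with exact global split
sizes (classes of fewer than three members are effectively random, with a
warning). The out-of-distribution holdout removes certificates stating
chosen codes from the training split only, diverting them to the test
split: those codes then have zero training occurrences but remain
observable. The pipeline picks the rarest stated non-external codes for
this. Codes that double as frequent labels are a poor choice — removing
them leaves never-trained classes on which the model is confidently wrong,
which is a different pathology from the "unseen stated condition" the
analysis targets (the emulated setting stratifies labels, so OOD means
unseen inputs, not unseen classes).

## The classifier and what it can and cannot learn

The stand-in model is an embedding table, mean pooling over non-padding
tokens, an optional `tanh` hidden layer and an affine map to class logits,
trained with Adam under a fixed seed (`train_with_checkpoints()`), with
`K` snapshots at evenly spaced epochs. Defaults for the pipeline are
`d = 32`, `hidden = 256`, 40 epochs, `K = 5`.

Two properties of this architecture matter for interpreting every result:

* **Closed-form gradients.** The gradient of any class output with respect
  to a token embedding is the pooled gradient divided by the token count;
  for the linear head it is exactly `W2[, p] / L`. All gradient machinery
  is therefore testable against finite differences and hand algebra.
* **Order blindness.** Mean pooling sees a bag of words, but the selection
  rules depend on condition *order*. Multi-condition certificates whose
  bags are identical under reordering are irreducibly ambiguous, which
  caps held-out accuracy around 0.5–0.6 under the default generator. On
  well-separated data (single-condition certificates) the same model
  reaches accuracy 1.0, which is what the training smoke benchmark
  asserts. The full-scale system this emulates is a transformer with
  positional information and accuracy 0.99; the toy model deliberately
  trades that for analysability, and the calibration / difficulty /
  attribution machinery is architecture-agnostic.

The `hidden = 256` default makes the model mildly overparameterized. That
is a considered choice: checkpoint-to-checkpoint gradient variance only
carries an out-of-distribution signal when the function can drift at
inputs the training data do not anchor, and a minimal-capacity model has
no slack to drift. Forty epochs put the first checkpoint past initial
convergence, so the captured variance reflects post-fit dynamics rather
than the initial descent.

## Calibration

`bin_predictions()` uses M equal-width half-open bins `((m-1)/M, m/M]`
(default M = 10; the emulated study never states its bin count), per-bin
accuracy and mean confidence, and `calibration_errors()` reports on the
percent scale: ECE as the count-weighted mean absolute accuracy-confidence
gap, MCE as the worst gap over non-empty bins. Empty bins contribute
nothing to ECE and are excluded from the MCE maximum — a stated policy
where the literature is silent. Argmax ties break toward the lowest class
index.

`fit_temperature()` minimises held-out negative log-likelihood of
`softmax(z / T)` by bounded scalar search on `[0.05, 20]` (tolerance
1e-4), the standard single-parameter post-hoc method; an ECE-minimising
objective is available behind a flag. If the objective keeps improving
into a bound — e.g. an all-correct validation set, whose likelihood grows
without limit as T shrinks — the boundary temperature is returned with
`bound_hit = TRUE` and a warning. Scaling never changes the predicted
label (a monotone transform per row).

On synthetic prediction sets with labels drawn at a known temperature
T\*, the fitted temperature recovers T\* within a few percent at
n = 50,000, and applying it strictly lowers ECE whenever T\* ≠ 1. MCE may
move either way — with most predictions piled into the top bin, the
sparsely populated bins that MCE keys on are noisy, and the full-scale
study itself observed MCE worsening under scaling. The package records
the MCE direction but does not assert it.

## Variance of Gradients

`instance_vog()` scores one record: for each checkpoint, the gradient of
the class-`p` output with respect to every non-padding token embedding;
then the population variance (denominator K) of each (token, component)
cell across checkpoints; then the mean over cells. `p` is the true label
when analysing labelled data (the predicted label otherwise — both are
defensible and the choice is a flag). A `mode = "final"` variant
(variance across the final snapshot's gradient components) is provided
purely for sensitivity analysis.

**Which activation to differentiate** is the one place this package
departs from the obvious reading. The method description ("the final
activation layer") admits both the pre-softmax logit and the post-softmax
probability. For this architecture the logit gradient under mean pooling
carries a mechanical `1/L²` factor — short certificates get inflated
scores — and its across-checkpoint variance is dominated by weight growth
proportional to class frequency. Both effects *invert* the expected
difficulty pattern. The post-softmax gradient carries the `p(1-p)`
confidence damping: records the model is always sure about contribute
almost nothing, records it is uncertain about at some checkpoints
dominate. With the softmax layer (the default, `layer = "softmax"`), the
package reproduces the documented qualitative pattern: certificates
stating never-seen codes have the highest mean normalised score and mean
difficulty declines as the minimum training occurrence of stated codes
rises. `token_gradients()` keeps the logit contract (and its closed form)
and exposes both layers.

Normalisation follows the stated two-step scheme in the one order that
makes both steps meaningful: centre each record on its class mean
(`class_norm_vog`, handling class imbalance), then z-score the centred
values globally and clip to [-1, 1] for the reported `global_norm_vog`.
The unclipped z-score is retained (`global_z`): clipping is a display
convention, and the OOD flag quantile is computed on the unclipped score
because clipping piles the extreme tail at exactly 1.

`rank_and_flag()` flags a record as OOD-like if it states a code with
zero training occurrences or its score exceeds the `flag_quantile`
(default 0.95). `vog_frequency_analysis()` assigns each record the
minimum training occurrence among its stated codes and reports per-band
means; the full-scale bands (0, 1–2, up to >20,000) are the package
default, and the pipeline substitutes powers-of-ten-style bands capped at
the observed maximum when training counts never reach the full-scale
ranges — a scale adaptation, not a tuning knob. A log2-binned trend
replaces the LOESS curve of the original figure (binned means are
dependency-free and monotone-comparable).

At desk scale the qualitative claims are assessed pooled over five seeded
replicates, with band comparisons allowed two pooled standard errors of
slack: individual toy-scale runs are noisy, and the claim under test is a
direction, not a magnitude. The class-level correlation between mean
difficulty and mean stated-condition count comes out weakly positive
(roughly 0–0.15 across seeds), consistent in direction with the weak
values reported at full scale; the magnitude is data-dependent and not
asserted.

## Integrated Gradients

`integrated_gradients()` attributes the pre-softmax logit of a target
class (saturation-free, the common practice for attribution even though
the difficulty score differentiates the softmax) along the straight-line
path from a baseline to the embedded input, by Gauss–Legendre quadrature
(default 50 nodes; left Riemann available). The baseline is the padding
embedding — pinned to the zero vector during training, so the "empty
certificate" reference — repeated to input length. For the linear head
the attribution is exact at any step count; for the nonlinear model the
completeness gap `|Σ attributions − (F(x) − F(baseline))|` falls below
1e-3 by 128 steps and is non-increasing in the step count on trained
models (the quadrature error of a smooth one-dimensional integrand).

Token scalars are component sums (sign preserved), summed per word via
the tokenizer's word map; hyphenated chunks stay one word across tokens.
Display values rescale by the record's maximum absolute word attribution
— a per-record normalisation for the red/white/green rendering only; all
statistics use raw attributions. The report
(`render_saliency_report()`) writes an HTML page and a numeric TSV twin
with true and predicted codes, titles, word importances and the summed
attribution score, for a balanced sample of correct and failed
predictions. On certificates whose UCOD is an external cause, the
external-cause words carry the top positive attribution in the majority
of correctly classified cases — the attribution concentrates on the
rule-decisive condition.

## Stratified reporting

`map_code_to_chapter()` is a total function on valid codes over the
hard-coded 2016 chapter boundaries. `chapter_accuracy_table()` counts
every stated condition (input frequency) and every true UCOD (target
frequency) by chapter and reports accuracy only for chapters that occur
as targets (`NA` otherwise). Both percent columns use one denominator
each — total stated conditions and total certificates — and sum to 100;
published tables of this kind mix denominators, which this package does
not reproduce. `top_k_frequency_table()` ranks codes with 3-decimal
percents and cumulative coverage; given a published table with printed
percentages it uses them verbatim, which is how the 36% / 31.2% top-10
coverage figures are recomputed. `confidence_group_stats()` gives
five-number confidence summaries (linear-interpolation quantiles, stated
in the output metadata), error rates and training counts per chapter or
class; on imbalanced synthetic data, classes under ~15 training samples
show visibly higher error, the low-sample band the full-scale analysis
flags for manual review.

## Numerical and design notes

* All randomness is seeded and the generator restores the caller's RNG
  state; pipelines are idempotent per seed (identical manifests).
* Confidence 0 (impossible for a softmax maximum) would fall to bin 1;
  bin assignment uses `ceiling(conf * M)` with a 1e-12 guard against
  floating-point edge effects at bin boundaries.
* The temperature search is Brent's method via `optimize()`; degenerate
  (monotone) objectives are detected by comparing the interior optimum
  against both bounds.
* Zero global SD of the centred difficulty scores (all records identical)
  is an error, not a silent zero.
* The problem sizes used by the shipped checks — 5,000 certificates over
  a 60-code ontology for the pipeline, 2,000 certificates per seed for
  the difficulty replicates, 50,000 synthetic predictions for temperature
  recovery — were chosen as the smallest sizes at which the directional
  claims are stable across seeds.

## Limitations

The synthetic world reproduces the statistical shape of coded mortality
data (long-tailed code use, chapter imbalance, 1–15 conditions, held-out
codes) but not its content: titles are synthetic phrases, the rule engine
is a four-rule cascade, and the classifier is order-blind. Passing tests
therefore demonstrate that the interpretability machinery is correct and
that its qualitative behaviours emerge under controlled conditions — not
that any particular clinical deployment is calibrated or that its
difficult cases are the same ones a coder would flag. The difficulty
score's OOD signal at this scale is a pooled, directional effect with
seed-level noise; magnitudes do not transfer. Nothing here implements the
full WHO selection/modification tables, ICD-11, or COVID-era special
codes.
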