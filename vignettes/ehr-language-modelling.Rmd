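---
title: "Modelling longitudinal EHRs as token sequences: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal EHRs as token sequences: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling idea

`ehrseq` treats a patient's electronic health record as a sentence in a small
clinical language. A record is a time-ordered series of visits; each visit
carries diagnoses (ICD-10, grouped to their 3-character stem), procedures
(CPT-4), medications (RxNorm) and laboratory results (LOINC codes with
continuous values). The package linearizes a record as

```
SEX, AGE | V1, SEP | t, V2, SEP | t, V3, SEP | ...
```

where the demographics prefix holds a sex token and a 5-year age-bucket token
(age at first visit), each visit block opens with a visit-type token and may
close with a discharge-type token, and every visit except the first is
preceded by a relative-time token encoding the gap since the previous visit:
`T0` within the same quarter (at most 91 days), `T1` more than 3 but within 6
months (92-182 days), `T2` more than 6 months but within a year (183-365),
`T3` more than a year (366+). `SEP` terminates every visit block, which is
what lets greedy generation discover the end of a visit.

A decoder-only transformer is fitted to the resulting token corpus with the
standard next-token objective: the mean negative log-likelihood of each token
given its prefix under causal masking. Every downstream capability — visit
forecasting, zero-shot diagnostic prediction, embeddings for a linear probe,
attention attribution — is read off this single fitted model
(`ehr_lm()`), which is the package's central object.

## Tokenization choices

**Code grouping and mapping.** Diagnosis codes are grouped to the at-most-3
characters before the decimal point (`E11.9` becomes `E11`), after an
optional user-supplied source-to-target code mapping (e.g. an ICD-9 to
ICD-10 General Equivalence Mapping extract) has been applied. No terminology
content ships with the package; `read_code_mapping()` accepts any two-column
delimited table and unknown codes map to themselves.

**Rare-code filter.** Codes carried by fewer than 0.1% of patients are
removed. "Carried by" is counted per patient, not per occurrence, making the
filter robust to repeat billing of chronic conditions; a code at exactly the
threshold is retained (strictly-below removal). The filter is applied after
mapping and grouping.

**Lab discretization.** Each laboratory code's continuous values are reduced
to ten decile tokens of its empirical CDF, fitted on the training split
only. We use the left-continuous inverse of the eCDF (the sorted training
value at index `ceil(k*n/10)`, computed in exact integer arithmetic so that
the fitted boundaries are reproducible to the bit). A value's bin is the
number of boundaries strictly below it, clipped to 0..9, so out-of-range
values at inference fall into the extreme bins rather than minting unseen
tokens. Labs with fewer than 10 training values are excluded; all-identical
values give degenerate bins with a warning. Each (lab, decile) pair is one
vocabulary entry.

**Intra-visit order.** Events within a visit often share one timestamp, so a
canonical order is imposed: timestamp, then domain (diagnosis, procedure,
medication, lab), then code. This is an artificial order chosen for
deterministic, reproducible training; it is also why the package never
claims to learn true intra-visit sequencing.

**Truncation.** Sequences are cut to a 512-token context window by dropping
whole oldest visit blocks; the demographics prefix is always kept and the
retained suffix's first visit loses its time token, so truncated sequences
remain grammatical. Visits are never split (the pathological case of a
single visit longer than the window is truncated with a warning; it does not
arise at realistic visit sizes).

## The model and its defaults

The transformer is written in base R (BLAS matrix algebra, hand-derived
backpropagation verified against finite differences in the test suite, Adam
optimizer). Defaults are a desk-scale configuration chosen to train on one
CPU in minutes and scale up if asked: 2 layers, 2 heads, 128 hidden units
(64 in the package's own end-to-end evaluations), GELU feed-forward (the
sigmoid approximation `x * sigmoid(1.702 x)`), pre-norm residual blocks,
learned positional embeddings, untied output head. Training uses Adam at a
fixed learning rate (default 3e-3), a 90/10 patient-level train/validation
split, and early stopping on validation loss with the best-validation
weights restored. PAD targets are excluded from the loss; the loss is
averaged per token. All randomness (initialization, the split, shuffling,
dropout) derives from one integer seed, and two identically seeded runs are
bit-identical.

Greedy decoding resolves exact probability ties by ascending token id, a
platform-independent rule that also fixes the top-N candidate ordering.
Incremental generation uses a key-value cache whose logits agree with the
full forward pass to machine precision (asserted in tests).

## The synthetic cohort: what it emulates, and what it does not

There is no public cohort at the scale of the private hospital data this
methodology targets, so the package ships a generator
(`simulate_ehr_cohort()`) whose defaults are the study conditions used by
the test suite and the acceptance script:

* 2,000 patients; visit counts 1 + NegBin(size 4, mu 11), capped at 30;
* inter-visit gaps from a four-range mixture (55/20/15/10% over 1-91,
  92-182, 183-365, 366-730 days) so all four time tokens occur;
* four domains with frequency-skewed per-visit background rates (40
  diagnosis stems, 30 medications, 20 procedures, 8 labs);
* log-normal lab values per code (skewed positive values are typical for
  labs and deliberately stress the decile discretization);
* chronic codes that, once present, are re-billed at subsequent visits
  (obesity, hypertension, diabetes, chronic kidney disease in the default
  pools);
* injected conditional structure as precursor rules: each rule fires at
  most once per patient, so the realized frequency of "target follows
  precursor" is directly interpretable as the configured conditional
  probability (the generator inserts a visit when no existing visit falls
  in the lag window — the diagnosis event itself constitutes a contact).

The default cohort wires the rules into a cascade,
obesity (E66) -> type-2 diabetes (E11) with p = 0.9 at 120-360 days,
then E11 -> chronic kidney disease (N18) with p = 0.8 at 1-89 days. The
chaining is essential to the censored-window evaluation being a meaningful
test: the protocol cuts a positive patient's history 91 days (3 months)
before the first target occurrence, and since the immediate precursor fires
at a lag shorter than the window, every trace of it is inside the censored
region. A single-link rule would therefore leave the positive arm's visible
history carrying *no* signal, and no evaluator — however good — could beat
chance. The chronic, recurring early marker is what real prodromes look
like and is what the model can legitimately learn to use.

What the generator does **not** emulate: billing semantics, care-seeking
behaviour, code co-missingness, multi-day inpatient episodes, measurement
panels ordered together, demographic confounding, or any real disease
dynamics beyond the injected cascade. Passing the recovery tests therefore
shows the pipeline is correct and the model can extract planted conditional
structure at desk scale; it says nothing about clinical performance on real
records.

## The two evaluation protocols

**Visit-level forecasting.** For each sequence with at least two visits,
visits 1..k are the input and visit k+1 is generated greedily until SEP (cap
64 tokens); generated and true visits are compared as de-duplicated sets,
with precision = |intersection| / |generated| and recall = |intersection| /
|truth|, micro-averaged over all compared visits. An empty generation scores
precision 0 by convention. Only event-domain tokens enter the comparison by
default; structural tokens (time, visit type, discharge, SEP) are excluded,
since including them inflates both metrics with grammar that is trivially
predictable (`include_structural = TRUE` restores them).

**Censored-window zero-shot diagnosis.** Positives are patients whose first
target occurrence leaves at least one visit strictly before
(first target date − window); the input ends there, so the gap to the true
first occurrence is exactly the prediction window (3 months = 91 days,
6 months = 182 days, matching the time-token boundaries). Negatives — which
the original protocol leaves undefined — are patients who never carry the
target, censored at a seeded random visit boundary with at least one visit
of history and a full window of recorded follow-up; this guarantees label
correctness and reproducibility. Every positive input is re-scanned for the
target token at evaluation time (censoring soundness is asserted, not
assumed).

Each patient's history is rolled forward along the greedy path. Elapsed
time inside the window is accumulated from generated time tokens at their
range midpoints (T0 45, T1 137, T2 274, T3 548 days) — the only time signal
the token stream carries; the midpoint is the minimal-assumption estimator.
Generation stops when the simulated clock passes the window, after 10
generated visits, or at the context window.

**Candidate checks happen at event-emitting steps.** The protocol asks
whether the target is in the model's top-N at "each step", and the obvious
reading includes structural steps. Implementing that reading showed it to
be degenerate: at deterministic grammar slots (e.g. the visit-type position
after a time token) cross-entropy training only separates the structural
tokens from everything else, leaving the remainder of the softmax ordered
by corpus frequency — so a common chronic target ranks in the top handful
*for every patient*, regardless of history, and TP and FP both saturate
once N reaches 10-20 at desk-scale vocabularies. The package therefore
records the target's candidate rank only at steps whose greedy token is an
event (diagnosis/procedure/medication/lab); structural steps advance the
grammar and the clock. A hit at candidate-set size N is a best in-window
rank at most N; one greedy pass per patient is reused across all N, and the
nesting of candidate sets makes TP@N and FP@N non-decreasing in N by
construction. Chapter-range targets (e.g. C00-D49) hit when any member
token enters the candidate set.

## The supervised comparator

The frozen backbone supplies mean-pooled final-layer hidden states as
sequence embeddings; a single linear head with input dropout (0.1) is
trained with the logistic loss, Adam at learning rate 1e-4, and class
balancing via weighted sampling (minibatches drawn with inverse
class-frequency probabilities). The backbone cannot change — only the
embedding matrix enters the head — and byte-identity of the serialized
backbone across head training is asserted anyway. Sensitivity is reported
at a matched false-positive rate: the smallest threshold whose FP% is at
most the target (predicted positive means score strictly above threshold),
which never overstates sensitivity at the stated specificity; with fully
tied scores the only such threshold may sit above every score, reported as
TP% 0 with a note.

## Interpretability

"Attention" attribution uses the causal self-attention of the final layer
from the predicting position, averaged over heads (a decoder-only model has
no encoder-decoder cross-attention; the final layer is the conventional
choice and the head average avoids privileging one head). At a step whose
top-1 forecast is the target, the top-15 attended input positions are
reported, ties broken by earlier position; per-cohort aggregation counts a
code once per patient and max-normalizes frequencies so the most frequent
code scores exactly 1, with ties at the cutoff rank all included and
flagged. Code embeddings for 2-D projection are the input-embedding rows
("embeddings for each code" is context-free phrasing), labelled with the 14
ICD-10 chapter ranges; the projection itself (e.g. UMAP) is delegated to
whatever tool the user prefers — the package only writes the labelled
matrix.

## Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` run the full pipeline at the
generator's default scale: 2,000 patients (about 190k corpus tokens), a
2-layer, 2-head, 64-hidden model trained up to 12-20 epochs with early
stopping, evaluation cohorts of roughly 500 positives and 1,450 negatives.
These sizes were chosen so a complete run finishes on one CPU in minutes
while leaving the planted-signal margins far from the decision boundaries.

Numerical details that matter for reproducibility: decile boundaries use
exact integer indexing (no floating-point quantile fuzz); greedy and top-N
ties break by ascending token id; layer norm uses epsilon 1e-5; the
softmax subtracts row maxima; probability vectors are asserted to sum to 1
within 1e-5; all stochastic stages consume a single documented seed.

## Known limitations

* The generator's realism limits are listed above; in particular the
  canonical intra-visit order means "next token within a visit" is partly
  an artifact of sorting.
* Calendar quarters are approximated by fixed 91/182/365-day boundaries;
  the simulated clock inside the prediction window is a midpoint estimate,
  so windows are honoured in expectation, not exactly.
* The model is deliberately small; nothing in the code prevents larger
  configurations, but CPU training beyond a few hundred thousand tokens
  per epoch becomes slow.
* Age is encoded once, at the first visit, in 5-year buckets; patients are
  not re-aged over long histories.
* The zero-shot protocol evaluates one target at a time; correlated codes
  in candidate sets are counted for chapter ranges but not otherwise
  analysed.
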