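# ehrseq

Autoregressive next-event modelling of longitudinal electronic health
records, in plain R.

`ehrseq` is for biostatisticians and clinical-informatics researchers who
want to study *EHR-as-language* methodology — tokenizing OMOP-style patient
records, pretraining a small generative model on them, and evaluating
zero-shot diagnostic forecasting — without access to protected health
information and without a deep-learning software stack. Everything runs on
one CPU: the transformer (forward pass, backpropagation, Adam) is
implemented in base R on top of BLAS and is verified against finite
differences in the test suite.

## The model

A patient record is linearized as a token sequence

```
u = (SEX, AGE, V1, [SEP], t2, V2, [SEP], ..., tL, VL, [SEP])
```

where each visit `Vk = (vt, w_k1, ..., w_km, dt)` holds a visit-type token,
the visit's diagnosis / procedure / medication / lab-decile tokens, and an
optional discharge token, and `tk ∈ {T0, T1, T2, T3}` encodes the gap to
the previous visit (within a quarter; 3–6 months; 6–12 months; over a
year). Diagnoses are grouped to their 3-character ICD-10 stem, codes
carried by fewer than 0.1 % of patients are removed, and each lab's
continuous values are discretized into deciles of its training-split
empirical CDF. A decoder-only transformer is fitted by maximizing

```
L(u) = Σ_i log P(w_i | w_{i-1}, ..., w_0)
```

with causal masking. The fitted model is then used three ways:

* **visit-level forecasting** — generate visit k+1 greedily from visits
  1..k and score the predicted event set by precision and recall;
* **zero-shot diagnosis** — cut a patient's history 3 or 6 months before
  the first occurrence of a target code, roll the history forward along
  the greedy path, and call the patient positive if the target enters the
  model's top-N candidates at an event step inside the prediction window
  (reported as TP/FP/TN/FN percentages at N = 1, 5, 10, 20);
* **a frozen linear probe** — mean-pooled embeddings plus a logistic head
  trained with weighted sampling, reporting TP% at a matched FP%, the
  supervised comparator for the zero-shot numbers.

Because real hospital-scale corpora are private, the package ships a
synthetic OMOP cohort generator with injected precursor→target rules of
known conditional probability (a chronic prodrome → disease → complication
cascade by default), giving every pipeline stage a ground truth to recover.

## Worked example

```r
library(ehrseq)

# simulate a 300-patient OMOP-style cohort with a known disease cascade
config <- ehr_cohort_config(n_patients = 300, seed = 42)
sim <- simulate_ehr_cohort(config)
print(sim$ground_truth$rule_summary)

# vocabulary, tokenized corpus, and a small next-event model
vocab <- build_vocabulary(sim$records)
seqs  <- tokenize_cohort(sim$records, vocab)
model <- ehr_lm(seqs, vocab, hidden_dim = 64, max_epochs = 8, seed = 1)
print(model)

# zero-shot censored-window evaluation for the cascade target (N18)
cohort    <- build_diagnostic_cohort(sim$records, vocab, "N18",
                                     window_months = 3, seed = 7)
confusion <- confusion_at_n(model, sim$records, cohort)
print(confusion)
```

which prints (about two minutes on one CPU):

```
  rule precursor target configured_prob n_emitting n_fired realized_frequency
1    1       E66    E11             0.9         87      84          0.9655172
2    2       E11    N18             0.8         93      73          0.7849462

Autoregressive EHR event model (decoder-only transformer)
  2 layers, 2 heads, 64 hidden, vocab 207, context 512
  trained 8 epochs on 270 sequences (best epoch 8, val loss 2.7941 nats/token)

Zero-shot censored-window confusion (target {N18}, 3-month window)
  76 positives, 214 negatives; percentages per arm
     N=1   N=5  N=10  N=20
TP 57.89 90.79 90.79 90.79
FP  7.94  9.81 11.21 13.55
TN 92.06 90.19 88.79 86.45
FN 42.11  9.21  9.21  9.21
```

Reading it: the generator made the precursor→target rules fire at their
configured conditional probabilities (0.97 vs 0.9 and 0.78 vs 0.8, within
binomial noise at these arm sizes). After eight epochs of pretraining, the
model — never told what "N18" means — flags 58 % of true future chronic
kidney disease cases at top-1 three months ahead, at an 8 % false-positive
rate among never-diagnosed patients; widening the candidate set to top-20
raises detection to 91 % while false positives stay below 14 %. TP rises
monotonically in N by construction (candidate sets are nested).

Other entry points: `visit_level_forecast_eval()` (forecast
precision/recall), `extract_embedding()` / `fit_linear_probe()` /
`tp_at_matched_fp()` (the supervised comparator), `attended_tokens()` /
`aggregate_attention()` (which input codes the model looked at),
`export_code_embeddings()` (chapter-labelled embedding matrix for a 2-D
projection), and `write_omop_tables()` / `read_omop_tables()` for the
delimited OMOP table subset. A thin CLI over these functions is in
`inst/cli/ehrseq.R` (subcommands `simulate`, `build-vocab`, `tokenize`,
`train`, `eval-forecast`, `eval-zeroshot`, `finetune`, `interpret`,
`export-embeddings`).

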