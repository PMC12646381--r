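# Shared fixtures: hand-built records, toy grammars, and memoized tiny
# trained models so expensive training runs once per suite.

.fixture_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

# a patient record assembled by hand
make_record <- function(person_id, sex = "F", birth = "1960-01-01", visits) {
  vl <- lapply(visits, function(v) {
    ev <- v$events %||% data.frame(domain = character(0), code = character(0),
                                   value = numeric(0), stringsAsFactors = FALSE)
    list(date = as.Date(v$date), visit_type = v$visit_type %||% "outpatient",
         discharge = v$discharge %||% NA_character_, events = ev)
  })
  structure(list(person_id = person_id, sex = sex, birth_date = as.Date(birth),
                 visits = vl),
            class = "ehr_record")
}

dx_events <- function(codes) {
  data.frame(domain = "diagnosis", code = codes, value = NA_real_,
             stringsAsFactors = FALSE)
}

# small cohort for structural tests
small_cohort <- function(n = 40, seed = 11) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_ehr_cohort(ehr_cohort_config(n_patients = n, seed = seed))
  }
  .fixture_env[[key]]
}

# toy A -> B grammar: filler tokens, then A, then B w.p. p else C
toy_grammar_vocab <- function() {
  ehr_vocabulary(event_tokens = c("DX:AAA", "DX:BBB", "DX:CCC",
                                  sprintf("DX:F%02d", 1:5)),
                 extra_special = "VT:outpatient")
}

toy_grammar_corpus <- function(n, p = 0.9, seed = 1, vocab = toy_grammar_vocab()) {
  idA <- encode_tokens(vocab, "DX:AAA")
  idB <- encode_tokens(vocab, "DX:BBB")
  idC <- encode_tokens(vocab, "DX:CCC")
  filler <- encode_tokens(vocab, sprintf("DX:F%02d", 1:5))
  set.seed(seed)
  replicate(n, {
    f <- sample(filler, 6, replace = TRUE)
    c(f[1:3], idA, if (stats::runif(1) < p) idB else idC, f[4:6])
  }, simplify = FALSE)
}

# tiny model memorizing a deterministic visit grammar:
# [SEX:F AGE:040 VT X SEP T3 VT X SEP T3 VT X SEP]
deterministic_visit_vocab <- function() {
  ehr_vocabulary(event_tokens = "DX:XXX", extra_special = "VT:outpatient")
}

deterministic_visit_model <- function() {
  if (is.null(.fixture_env$det_model)) {
    vocab <- deterministic_visit_vocab()
    toks <- c("SEX:F", "AGE:040", "VT:outpatient", "DX:XXX", "SEP",
              "T3", "VT:outpatient", "DX:XXX", "SEP",
              "T3", "VT:outpatient", "DX:XXX", "SEP")
    ids <- encode_tokens(vocab, toks)
    corpus <- replicate(60, ids, simplify = FALSE)
    .fixture_env$det_model <- ehr_lm(corpus, vocab, n_layers = 1, n_heads = 2,
                                     hidden_dim = 32, context_window = 32,
                                     learning_rate = 5e-3, batch_size = 16,
                                     max_epochs = 30, patience = 30,
                                     val_fraction = 0, seed = 3)
  }
  .fixture_env$det_model
}

# hand-built model whose logits are a constant vector (all weights zero):
# useful for tie-break and attention tests
constant_logit_model <- function(vocab, bout, n_layers = 1, n_heads = 1,
                                 hidden_dim = 8, context_window = 64) {
  cfg <- list(vocab_size = length(vocab$tokens),
              context_window = as.integer(context_window),
              n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
              hidden_dim = as.integer(hidden_dim), dropout = 0, seed = 1L)
  par <- ehrseq:::.lm_init_par(cfg)
  par <- ehrseq:::.tree_map(function(x) x * 0, par)
  for (i in seq_len(cfg$n_layers)) {
    par$layers[[i]]$ln1g <- rep(1, hidden_dim)
    par$layers[[i]]$ln2g <- rep(1, hidden_dim)
  }
  par$lnfg <- rep(1, hidden_dim)
  stopifnot(length(bout) == cfg$vocab_size)
  par$bout <- bout
  ehrseq:::.new_ehr_lm(par, cfg, vocab)
}

expect_no_target_leak <- function(records, cohort, vocab, mapping = NULL) {
  by_id <- stats::setNames(seq_along(records),
                           vapply(records, function(r) as.character(r$person_id),
                                  character(1)))
  for (i in seq_len(nrow(cohort$positives))) {
    rec <- records[[by_id[[as.character(cohort$positives$person_id[i])]]]]
    cen <- censor_record(rec, cohort$positives$censor_date[i])
    if (!length(cen$visits)) next
    s <- tryCatch(build_sequence(cen, vocab, mapping), error = function(e) NULL)
    if (is.null(s)) next
    expect_false(any(s$token_ids %in% cohort$target_token_ids))
  }
  for (i in seq_len(nrow(cohort$negatives))) {
    rec <- records[[by_id[[as.character(cohort$negatives$person_id[i])]]]]
    s <- tryCatch(build_sequence(rec, vocab, mapping), error = function(e) NULL)
    if (is.null(s)) next
    expect_false(any(s$token_ids %in% cohort$target_token_ids))
  }
}
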