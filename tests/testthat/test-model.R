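test_that("analytic gradients match central finite differences", {
  set.seed(4)
  cfg <- list(vocab_size = 11L, context_window = 16L, n_layers = 2L,
              n_heads = 2L, hidden_dim = 8L, dropout = 0, seed = 1L)
  par <- ehrseq:::.lm_init_par(cfg)
  seqs <- list(sample(11, 7, TRUE), sample(11, 5, TRUE))
  ids <- unlist(seqs); lens <- lengths(seqs)
  fwd <- ehrseq:::.lm_forward(par, cfg, ids, lens, want = "cache")
  lg <- ehrseq:::.lm_loss_grad(fwd$logits, ids, lens, 1L)
  gr <- ehrseq:::.lm_backward(par, cfg, ids, lens, fwd, lg$dlogits)
  lossfn <- function(p) {
    f <- ehrseq:::.lm_forward(p, cfg, ids, lens, want = "logits")
    ehrseq:::.lm_loss_grad(f$logits, ids, lens, 1L)$loss
  }
  eps <- 1e-5
  check <- function(get, set, i, ana) {
    p1 <- set(par, replace(get(par), i, get(par)[i] + eps))
    p2 <- set(par, replace(get(par), i, get(par)[i] - eps))
    num <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
    expect_lt(abs(num - ana) / (abs(num) + abs(ana) + 1e-9), 1e-3)
  }
  check(function(p) p$tok, function(p, v) { p$tok <- v; p }, 25L, gr$tok[25])
  check(function(p) p$pos, function(p, v) { p$pos <- v; p }, 10L, gr$pos[10])
  check(function(p) p$Wout, function(p, v) { p$Wout <- v; p }, 40L, gr$Wout[40])
  for (f in c("Wqkv", "Wo", "W1", "W2", "ln1g", "ln2b", "bqkv")) {
    for (li in 1:2) {
      check(function(p) p$layers[[li]][[f]],
            function(p, v) { p$layers[[li]][[f]] <- v; p },
            5L, gr$layers[[li]][[f]][5])
    }
  }
})

test_that("next-token distributions are proper probability vectors", {
  m <- deterministic_visit_model()
  V <- m$config$vocab_size
  set.seed(2)
  for (i in 1:5) {
    prefix <- sample(V, sample(3:10, 1), replace = TRUE)
    p <- next_token_distribution(m, prefix)
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-5)
  }
})

test_that("causal masking: tokens after position k never affect its logits", {
  set.seed(5)
  cfg <- list(vocab_size = 20L, context_window = 32L, n_layers = 2L,
              n_heads = 2L, hidden_dim = 16L, dropout = 0, seed = 1L)
  par <- ehrseq:::.lm_init_par(cfg)
  ids <- sample(20, 12, TRUE)
  ids2 <- ids; ids2[9:12] <- sample(20, 4, TRUE)
  f1 <- ehrseq:::.lm_forward(par, cfg, ids, 12L, want = "logits")
  f2 <- ehrseq:::.lm_forward(par, cfg, ids2, 12L, want = "logits")
  expect_equal(f1$logits[1:8, ], f2$logits[1:8, ], tolerance = 1e-12)
})

test_that("identically seeded trainings are identical", {
  vocab <- toy_grammar_vocab()
  corpus <- toy_grammar_corpus(40, seed = 6)
  fit <- function() ehr_lm(corpus, vocab, n_layers = 1, n_heads = 2,
                           hidden_dim = 16, context_window = 16,
                           batch_size = 16, max_epochs = 2, seed = 9)
  m1 <- fit(); m2 <- fit()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$par, m2$par)
})

test_that("training loss decreases over the first epochs on a learnable corpus", {
  vocab <- toy_grammar_vocab()
  corpus <- toy_grammar_corpus(100, seed = 8)
  m <- ehr_lm(corpus, vocab, n_layers = 1, n_heads = 2, hidden_dim = 16,
              context_window = 16, batch_size = 16, max_epochs = 3,
              val_fraction = 0, patience = 10, seed = 1)
  expect_true(all(diff(m$history$train) < 0))
})

test_that("a single repeated sequence is memorized to near-zero loss", {
  m <- deterministic_visit_model()
  expect_lt(m$history$train[nrow(m$history)], 0.1)
})

test_that("the deterministic grammar is decoded exactly (generator as oracle)", {
  m <- deterministic_visit_model()
  vocab <- m$vocab
  prefix <- encode_tokens(vocab, c("SEX:F", "AGE:040", "VT:outpatient", "DX:XXX", "SEP"))
  p <- next_token_distribution(m, prefix)
  expect_equal(names(which.max(p)), "T3")
  gen <- generate_visit(m, prefix)
  expect_equal(gen$tokens, c("T3", "VT:outpatient", "DX:XXX"))
  expect_false(gen$capped)
})

test_that("top-N candidate sets nest and break ties by ascending id", {
  m <- deterministic_visit_model()
  prefix <- encode_tokens(m$vocab, c("SEX:F", "AGE:040", "VT:outpatient"))
  t1 <- top_n_candidates(m, prefix, 1)
  t5 <- top_n_candidates(m, prefix, 5)
  t10 <- top_n_candidates(m, prefix, 10)
  expect_equal(t5[1], t1)
  expect_equal(t10[1:5], t5)
  p <- next_token_distribution(m, prefix)
  expect_equal(t1, unname(which.max(p)))
  expect_error(top_n_candidates(m, prefix, m$config$vocab_size + 1L), "vocabulary")

  # exact ties: constant-logit model, all logits equal -> ids in ascending order
  vocab <- deterministic_visit_vocab()
  mc <- constant_logit_model(vocab, bout = rep(0, length(vocab$tokens)))
  expect_equal(top_n_candidates(mc, c(3L, 4L), 5), 1:5)
})

test_that("generate_visit stops at SEP, respects the cap, and flags it", {
  vocab <- deterministic_visit_vocab()
  V <- length(vocab$tokens)
  sep <- unname(encode_tokens(vocab, "SEP"))
  # SEP as immediate argmax -> empty generated visit
  b <- rep(0, V); b[sep] <- 5
  m_sep <- constant_logit_model(vocab, b)
  g <- generate_visit(m_sep, c(3L, 4L))
  expect_length(g$token_ids, 0L)
  expect_false(g$capped)
  # pathological non-SEP model -> exactly the cap, flagged
  dx <- unname(encode_tokens(vocab, "DX:XXX"))
  b2 <- rep(0, V); b2[dx] <- 5
  m_loop <- constant_logit_model(vocab, b2)
  g2 <- generate_visit(m_loop, c(3L, 4L), max_visit_tokens = 7L)
  expect_length(g2$token_ids, 7L)
  expect_true(g2$capped)
  expect_true(all(g2$token_ids == dx))
})

test_that("overlong prefixes use the last context_window tokens with a message", {
  vocab <- deterministic_visit_vocab()
  m <- constant_logit_model(vocab, rep(0, length(vocab$tokens)), context_window = 8)
  long_prefix <- rep(3L, 20)
  expect_message(p <- next_token_distribution(m, long_prefix), "context window")
  expect_lt(abs(sum(p) - 1), 1e-5)
})

test_that("corpus token ids outside the vocabulary are rejected with the sequence index", {
  vocab <- deterministic_visit_vocab()
  corpus <- list(c(1L, 2L, 3L), c(2L, 999L))
  expect_error(ehr_lm(corpus, vocab, hidden_dim = 8, n_heads = 1, max_epochs = 1),
               "sequence 2")
})

test_that("checkpoints round-trip and refuse a mismatched vocabulary", {
  m <- deterministic_visit_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f, vocab = m$vocab)
  expect_identical(m2$par, m$par)
  other <- ehr_vocabulary(event_tokens = "DX:OTHER")
  expect_error(load_checkpoint(f, vocab = other), "hash")
})

test_that("model methods print, summarize, plot and expose coefficients", {
  m <- deterministic_visit_model()
  expect_output(print(m), "decoder-only transformer")
  expect_output(print(summary(m)), "parameters")
  emb <- coef(m)
  expect_equal(rownames(emb), m$vocab$tokens)
  expect_equal(ncol(emb), m$config$hidden_dim)
  ll <- logLik(m)
  expect_s3_class(ll, "logLik")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(m); grDevices::dev.off()
  expect_true(file.exists(f))
  # simulate() rolls several visits forward
  prefix <- encode_tokens(m$vocab, c("SEX:F", "AGE:040", "VT:outpatient", "DX:XXX", "SEP"))
  vs <- simulate(m, nsim = 2, prefix = prefix)
  expect_length(vs, 2L)
  expect_equal(vs[[1]]$tokens, c("T3", "VT:outpatient", "DX:XXX"))
})
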