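test_that("forecast set arithmetic matches hand computation", {
  fs <- forecast_scores(list(c("A", "B", "C")), list(c("B", "C", "D")))
  expect_equal(fs$precision, 2 / 3)
  expect_equal(fs$recall, 2 / 3)
  fs2 <- forecast_scores(list(c("A", "B")), list(c("A", "B")))
  expect_equal(fs2$precision, 1)
  expect_equal(fs2$recall, 1)
  fs3 <- forecast_scores(list(character(0)), list(c("A")))
  expect_equal(fs3$precision, 0)   # empty-prediction convention
  expect_equal(fs3$recall, 0)
  # micro-averaging pools counts across visits
  fs4 <- forecast_scores(list(c("A", "B"), c("C")), list(c("A"), c("C", "D")))
  expect_equal(fs4$precision, 2 / 3)
  expect_equal(fs4$recall, 2 / 3)
  # duplicates collapse to sets
  fs5 <- forecast_scores(list(c("A", "A", "B")), list(c("A")))
  expect_equal(fs5$precision, 1 / 2)
})

test_that("visit-level evaluation is perfect on a memorized deterministic grammar", {
  m <- deterministic_visit_model()
  vocab <- m$vocab
  toks <- c("SEX:F", "AGE:040", "VT:outpatient", "DX:XXX", "SEP",
            "T3", "VT:outpatient", "DX:XXX", "SEP",
            "T3", "VT:outpatient", "DX:XXX", "SEP")
  ids <- encode_tokens(vocab, toks)
  s <- structure(list(person_id = 1, token_ids = ids,
                      visit_index = ehrseq:::.visit_index_from_ids(ids, vocab),
                      visit_dates = NULL, n_dropped = 0L),
                 class = "ehr_sequence")
  fs <- visit_level_forecast_eval(m, list(s))
  expect_equal(fs$n_visits, 2L)   # visits 2 and 3 are forecast
  expect_equal(fs$precision, 1)
  expect_equal(fs$recall, 1)
})

test_that("single-visit sequences are skipped with a count", {
  m <- deterministic_visit_model()
  ids <- encode_tokens(m$vocab, c("SEX:F", "AGE:040", "VT:outpatient", "DX:XXX", "SEP"))
  s <- structure(list(person_id = 1, token_ids = ids,
                      visit_index = ehrseq:::.visit_index_from_ids(ids, m$vocab),
                      visit_dates = NULL, n_dropped = 0L),
                 class = "ehr_sequence")
  expect_message(fs <- visit_level_forecast_eval(m, list(s)), "skipped 1")
  expect_equal(fs$n_visits, 0L)
})

test_that("positive-arm censoring ends the window before the first target date", {
  vocab <- ehr_vocabulary(event_tokens = c("DX:E11", "DX:N18"),
                          extra_special = "VT:outpatient")
  d0 <- as.Date("2015-01-01")
  rec <- make_record(1, visits = list(
    list(date = d0, events = dx_events("E11")),
    list(date = d0 + 150, events = dx_events("E11")),
    list(date = d0 + 300, events = dx_events(c("E11", "N18")))))
  coh <- build_diagnostic_cohort(list(rec,
    make_record(2, visits = list(
      list(date = d0, events = dx_events("E11")),
      list(date = d0 + 400, events = dx_events("E11"))))),
    vocab, "N18", window_months = 3, seed = 1)
  expect_equal(nrow(coh$positives), 1L)
  expect_equal(coh$positives$censor_date, d0 + 300 - 91)
  cen <- censor_record(rec, coh$positives$censor_date)
  expect_length(cen$visits, 2L)   # the target visit and anything after are gone
  expect_equal(nrow(coh$negatives), 1L)
})

test_that("patients with all history inside the window are ineligible", {
  vocab <- ehr_vocabulary(event_tokens = c("DX:E11", "DX:N18"),
                          extra_special = "VT:outpatient")
  d0 <- as.Date("2015-01-01")
  recs <- list(
    make_record(1, visits = list(   # only visit is 30 d before target
      list(date = d0, events = dx_events("E11")),
      list(date = d0 + 30, events = dx_events("N18")))),
    make_record(2, visits = list(   # eligible: history 200 d before target
      list(date = d0, events = dx_events("E11")),
      list(date = d0 + 200, events = dx_events("N18")))))
  coh <- build_diagnostic_cohort(recs, vocab, "N18", window_months = 3, seed = 1)
  expect_equal(coh$positives$person_id, 2)
  expect_error(build_diagnostic_cohort(recs[1], vocab, "N18", window_months = 3),
               "empty cohort")
})

test_that("negatives never carry the target and keep a window of follow-up", {
  sim <- small_cohort(n = 120, seed = 17)
  vocab <- build_vocabulary(sim$records)
  coh <- build_diagnostic_cohort(sim$records, vocab, "N18", window_months = 3, seed = 2)
  by_id <- stats::setNames(seq_along(sim$records),
                           vapply(sim$records, function(r) as.character(r$person_id),
                                  character(1)))
  for (i in seq_len(nrow(coh$negatives))) {
    rec <- sim$records[[by_id[[as.character(coh$negatives$person_id[i])]]]]
    codes <- unlist(lapply(rec$visits, function(v)
      normalize_diagnosis_code(c(v$events$code[v$events$domain == "diagnosis"], "ZZZ"))))
    expect_false(any(codes %in% coh$target_codes))
    dates <- do.call(c, lapply(rec$visits, function(v) v$date))
    expect_gte(sum(dates < coh$negatives$censor_date[i]), 1L)
    expect_gte(as.numeric(max(dates) - coh$negatives$censor_date[i]), 91 - 1)
  }
  expect_no_target_leak(sim$records, coh, vocab)
})

test_that("chapter ranges expand to every member diagnosis token", {
  sim <- small_cohort(n = 60, seed = 19)
  vocab <- build_vocabulary(sim$records)
  coh <- build_diagnostic_cohort(sim$records, vocab, "C00-D49", window_months = 6, seed = 3)
  dx <- sub("^DX:", "", vocab$tokens[startsWith(vocab$tokens, "DX:")])
  expect_setequal(coh$target_codes, dx[dx >= "C00" & dx <= "D49"])
  expect_equal(coh$window_days, 182L)
})

test_that("a model that emits the target immediately is positive at N = 1", {
  vocab <- deterministic_visit_vocab()
  V <- length(vocab$tokens)
  dx <- unname(encode_tokens(vocab, "DX:XXX"))
  b <- rep(0, V); b[dx] <- 5
  m <- constant_logit_model(vocab, b)
  res <- predict_within_window(m, c(3L, 4L), target_ids = dx, n = 1,
                               window_days = 91)
  expect_true(res$hit)
  expect_equal(res$first_hit_step, 1L)
  expect_equal(res$best_rank, 1L)
})

test_that("N = vocabulary size is positive at the first event step", {
  vocab <- deterministic_visit_vocab()
  V <- length(vocab$tokens)
  dx <- unname(encode_tokens(vocab, "DX:XXX"))
  b <- rep(0, V); b[dx] <- 5   # greedy emits an event token every step
  m <- constant_logit_model(vocab, b)
  res <- predict_within_window(m, c(3L, 4L), target_ids = 7L, n = V,
                               window_days = 91)
  expect_true(res$hit)
  expect_equal(res$first_hit_step, 1L)
  # the event token is argmax, then ties resolve by ascending id: id 7 ranks 8th
  expect_equal(res$best_rank, 8L)
})

test_that("structural decoding steps are not candidate checks", {
  vocab <- deterministic_visit_vocab()
  V <- length(vocab$tokens)
  sep <- unname(encode_tokens(vocab, "SEP"))
  b <- rep(0, V); b[sep] <- 5   # greedy emits SEP forever: no event steps
  m <- constant_logit_model(vocab, b)
  res <- predict_within_window(m, c(3L, 4L), target_ids = 7L, n = V,
                               window_days = 91)
  expect_false(res$hit)
  expect_true(is.na(res$best_rank))
})

test_that("a model emitting T3 first exhausts a 3-month window with no hit", {
  vocab <- deterministic_visit_vocab()
  V <- length(vocab$tokens)
  t3 <- unname(encode_tokens(vocab, "T3"))
  target <- V  # highest id, so its tie-broken rank stays far beyond N
  b <- rep(0, V); b[t3] <- 5
  m <- constant_logit_model(vocab, b)
  res <- predict_within_window(m, c(3L, 4L), target_ids = target, n = 3,
                               window_days = 91)
  expect_false(res$hit)
  expect_equal(res$n_steps, 1L)         # 548 simulated days at the first step
  expect_gt(res$elapsed_days, 91)
})

test_that("confusion percentages obey the arm identities and nesting in N", {
  sim <- small_cohort(n = 120, seed = 17)
  vocab <- build_vocabulary(sim$records)
  coh <- build_diagnostic_cohort(sim$records, vocab, "N18", window_months = 3, seed = 2)
  set.seed(8)
  m <- constant_logit_model(vocab, stats::rnorm(length(vocab$tokens)),
                            hidden_dim = 16, context_window = 512)
  cf <- confusion_at_n(m, sim$records, coh, Ns = c(1, 5, 10, 20))
  expect_equal(cf$confusion["TP", ] + cf$confusion["FN", ],
               rep(100, 4), ignore_attr = TRUE)
  expect_equal(cf$confusion["FP", ] + cf$confusion["TN", ],
               rep(100, 4), ignore_attr = TRUE)
  expect_true(all(diff(cf$confusion["TP", ]) >= 0))
  expect_true(all(diff(cf$confusion["FP", ]) >= 0))
  expect_true(all(diff(cf$confusion["TN", ]) <= 0))
  # empty arm errors name the arm
  coh2 <- coh
  coh2$negatives <- coh2$negatives[0, ]
  expect_error(confusion_at_n(m, sim$records, coh2), "negative arm")
})
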