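# Two evaluation protocols: (1) visit-level stepwise forecasting with greedy
# decoding, scored by set precision/recall; (2) the censored-window zero-shot
# diagnostic task: history cut 3 or 6 months before the first target
# occurrence, greedy roll-forward, TP/FP/TN/FN at top-N candidate sets.

#' Set precision and recall for predicted versus true visit token sets
#'
#' Low-level metric: per compared visit, precision = |intersection| /
#' |predicted| and recall = |intersection| / |truth| on the de-duplicated
#' token sets; an empty prediction scores precision 0 by convention.
#' Aggregates are micro-averaged: total intersection size over total
#' predicted (respectively true) tokens across all compared visits.
#'
#' @param predicted list of character/integer vectors (one per visit).
#' @param truth list of the corresponding true token vectors.
#' @return an `ehr_forecast_scores` list: `per_visit` data frame,
#'   micro-averaged `precision` and `recall`, and `n_visits`.
#' @export
forecast_scores <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  n <- length(predicted)
  prec <- rec <- numeric(n)
  n_int <- n_pred <- n_true <- integer(n)
  for (i in seq_len(n)) {
    p <- unique(predicted[[i]]); t <- unique(truth[[i]])
    ni <- length(intersect(p, t))
    n_int[i] <- ni; n_pred[i] <- length(p); n_true[i] <- length(t)
    prec[i] <- if (length(p)) ni / length(p) else 0
    rec[i] <- if (length(t)) ni / length(t) else 0
  }
  structure(
    list(per_visit = data.frame(precision = prec, recall = rec,
                                n_intersect = n_int, n_predicted = n_pred,
                                n_truth = n_true),
         precision = if (sum(n_pred)) sum(n_int) / sum(n_pred) else 0,
         recall = if (sum(n_true)) sum(n_int) / sum(n_true) else 0,
         n_visits = n),
    class = "ehr_forecast_scores")
}

#' @export
print.ehr_forecast_scores <- function(x, ...) {
  cat(sprintf("Visit-level forecast: precision %.3f, recall %.3f over %d visits\n",
              x$precision, x$recall, x$n_visits))
  invisible(x)
}

#' Visit-level stepwise forecasting evaluation
#'
#' For every sequence with at least two visits, visits 1..k are used as
#' input to greedily generate visit k+1, for k = 1..L-1; the generated event
#' tokens are compared as a set against the true event tokens of visit k+1.
#' Structural tokens (SEP, time, visit-type, discharge) are excluded from
#' both sets unless `include_structural = TRUE`. Single-visit sequences are
#' skipped and counted.
#'
#' @param model a fitted `ehr_lm`.
#' @param sequences list of `ehr_sequence`.
#' @param include_structural compare visit-type/discharge/time tokens too.
#' @param max_visit_tokens per-visit generation cap.
#' @return an `ehr_forecast_scores` (micro-averaged over all compared
#'   visits) with attribute `n_skipped`.
#' @export
visit_level_forecast_eval <- function(model, sequences, include_structural = FALSE,
                                      max_visit_tokens = 64L) {
  stopifnot(inherits(model, "ehr_lm"))
  vocab <- model$vocab
  predicted <- list(); truth <- list(); skipped <- 0L
  keep_tokens <- function(toks) {
    if (include_structural) toks[toks != "SEP" & !.is_time_token(toks)]
    else toks[.is_event_token(toks)]
  }
  for (s in sequences) {
    vi <- s$visit_index
    n_visits <- max(vi)
    if (n_visits < 2L) { skipped <- skipped + 1L; next }
    for (k in seq_len(n_visits - 1L)) {
      prefix <- s$token_ids[vi <= k]
      gen <- generate_visit(model, prefix, max_visit_tokens)
      true_tokens <- vocab$tokens[s$token_ids[vi == k + 1L]]
      predicted[[length(predicted) + 1L]] <- keep_tokens(gen$tokens)
      truth[[length(truth) + 1L]] <- keep_tokens(true_tokens[true_tokens != "SEP"])
    }
  }
  if (skipped > 0L) message(sprintf("skipped %d single-visit sequence(s)", skipped))
  out <- forecast_scores(predicted, truth)
  attr(out, "n_skipped") <- skipped
  out
}

# expand a target spec ("I50", c("I50","I51"), or a chapter range "C00-D49")
# into normalized 3-character codes present in the vocabulary
.expand_target_codes <- function(vocab, target) {
  dx <- sub("^DX:", "", vocab$tokens[startsWith(vocab$tokens, "DX:")])
  hits <- character(0)
  for (t in target) {
    if (grepl("^[A-Z][0-9A-Z]{2}-[A-Z][0-9A-Z]{2}$", toupper(t))) {
      lim <- strsplit(toupper(t), "-", fixed = TRUE)[[1]]
      hits <- c(hits, dx[dx >= lim[1] & dx <= lim[2]])
    } else {
      hits <- c(hits, normalize_diagnosis_code(t))
    }
  }
  sort(unique(hits))
}

#' Build a censored diagnostic evaluation cohort
#'
#' Positives are patients whose first occurrence of the target code has at
#' least `min_history_visits` visits strictly before the censor date (first
#' target date minus the prediction window); their input history ends at the
#' censor date, so the window between history end and the true first
#' occurrence is exactly the prediction window. Negatives are patients who
#' never carry the target, censored at a seeded random visit boundary
#' leaving at least one visit of history and at least a full window of
#' recorded follow-up. Every positive input is verified target-free.
#'
#' @param records an `ehr_cohort` / list of `ehr_record`.
#' @param vocab an `ehr_vocab` (defines which diagnosis codes exist).
#' @param target a diagnosis code (`"I50"`), vector of codes, or an ICD-10
#'   chapter range (`"C00-D49"`); codes are grouped to 3 characters.
#' @param window_months prediction window, 3 or 6 months (91 / 182 days).
#' @param min_history_visits minimum visits before the censor date.
#' @param seed seed for the negative-arm censor draws.
#' @return an `ehr_cohort_spec`: target codes/token ids, window, and
#'   per-arm data frames (`person_id`, `censor_date`).
#' @export
build_diagnostic_cohort <- function(records, vocab, target, window_months = 3L,
                                    min_history_visits = 1L, seed = 1L) {
  stopifnot(inherits(vocab, "ehr_vocab"))
  window_days <- .window_days(window_months)
  codes <- .expand_target_codes(vocab, target)
  tokens <- paste0("DX:", codes)
  tokens <- tokens[tokens %in% vocab$tokens]
  if (!length(tokens)) {
    stop("no target token present in the vocabulary", call. = FALSE)
  }
  target_codes <- sub("^DX:", "", tokens)
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")

  pos <- list(); neg <- list()
  for (r in records) {
    dates <- do.call(c, lapply(r$visits, function(v) v$date))
    has_target <- vapply(r$visits, function(v) {
      any(v$events$domain == "diagnosis" &
            normalize_diagnosis_code(if (nrow(v$events)) v$events$code else "X") %in% target_codes)
    }, logical(1))
    if (any(has_target)) {
      first_date <- dates[which(has_target)[1]]
      censor <- first_date - window_days
      n_hist <- sum(dates < censor)
      if (n_hist >= min_history_visits) {
        pos[[length(pos) + 1L]] <- data.frame(person_id = r$person_id,
                                              censor_date = censor,
                                              first_target_date = first_date)
      }
    } else {
      n_visits <- length(dates)
      # candidate censor boundaries: after visit j, leaving >= window follow-up
      ok <- which(seq_len(n_visits) >= min_history_visits &
                    as.numeric(dates[n_visits] - dates) >= window_days)
      ok <- ok[ok < n_visits]
      if (length(ok)) {
        j <- ok[sample.int(length(ok), 1L)]
        neg[[length(neg) + 1L]] <- data.frame(person_id = r$person_id,
                                              censor_date = dates[j] + 1L,
                                              first_target_date = as.Date(NA))
      }
    }
  }
  if (!length(pos)) stop("empty cohort: no eligible positives for the target", call. = FALSE)
  spec <- structure(
    list(target = target, target_codes = target_codes,
         target_token_ids = unname(vocab$token_to_id[tokens]),
         window_months = as.integer(window_months), window_days = window_days,
         min_history_visits = as.integer(min_history_visits),
         positives = do.call(rbind, pos),
         negatives = if (length(neg)) do.call(rbind, neg) else
           data.frame(person_id = integer(0), censor_date = as.Date(character(0)),
                      first_target_date = as.Date(character(0)))),
    class = "ehr_cohort_spec")
  spec
}

#' @export
print.ehr_cohort_spec <- function(x, ...) {
  cat(sprintf("Censored diagnostic cohort: target {%s}, window %d months (%d days)\n",
              paste(x$target_codes, collapse = ", "), x$window_months, x$window_days))
  cat(sprintf("  %d positives, %d negatives\n", nrow(x$positives), nrow(x$negatives)))
  invisible(x)
}

#' Censor a patient record at a date
#'
#' Keeps only visits strictly before `censor_date`.
#'
#' @param record an `ehr_record`.
#' @param censor_date a `Date`.
#' @return the censored `ehr_record` (possibly with zero visits).
#' @export
censor_record <- function(record, censor_date) {
  keep <- vapply(record$visits, function(v) v$date < censor_date, logical(1))
  record$visits <- record$visits[keep]
  record
}

#' Roll a censored history forward and test for the target in top-N sets
#'
#' Extends the prefix along the greedy decoding path. At each event-emitting
#' decoding step (one whose greedy token is a diagnosis/medication/procedure/
#' lab code) the rank of the target among next-token candidates is recorded
#' (ties broken by ascending token id); the patient is positive at
#' candidate-set size N if the best rank within the simulated window is
#' <= N. Structural steps — time, visit-type, discharge and SEP tokens —
#' advance the grammar and the simulated clock but are not candidate checks:
#' those slots are deterministic grammar positions whose probability tail
#' reflects corpus frequency rather than patient history. Simulated
#' elapsed time accumulates from generated time tokens, each contributing
#' its range midpoint (T0 45, T1 137, T2 274, T3 548 days); generation stops
#' once the elapsed time exceeds the window, `max_future_visits` visits have
#' been generated, or the context window is exhausted.
#'
#' @param model a fitted `ehr_lm`.
#' @param prefix censored input sequence (ids or `ehr_sequence`), ending at
#'   a visit boundary.
#' @param target_ids integer token ids counting as a hit (any member).
#' @param n candidate-set size N.
#' @param window_days prediction window in days.
#' @param max_future_visits cap on generated visits, default 10.
#' @param max_visit_tokens cap on tokens per generated visit, default 64.
#' @return list with `hit` (logical), `first_hit_step` (NA if no hit),
#'   `best_rank` (smallest target rank over in-window steps), `n_steps`,
#'   and `elapsed_days` at stopping time.
#' @export
predict_within_window <- function(model, prefix, target_ids, n,
                                  window_days, max_future_visits = 10L,
                                  max_visit_tokens = 64L) {
  res <- .roll_forward(model, prefix, target_ids, window_days,
                       max_future_visits, max_visit_tokens)
  hit <- !is.na(res$best_rank) && res$best_rank <= n
  first_hit_step <- if (hit) {
    unname(res$first_step_at_rank[res$first_step_at_rank[, "rank"] <= n, "step"][1])
  } else NA_integer_
  list(hit = hit, first_hit_step = first_hit_step, best_rank = res$best_rank,
       n_steps = res$n_steps, elapsed_days = res$elapsed_days)
}

# single greedy pass shared by all N: records the target's candidate rank at
# every in-window decoding step
.roll_forward <- function(model, prefix, target_ids, window_days,
                          max_future_visits = 10L, max_visit_tokens = 64L) {
  stopifnot(inherits(model, "ehr_lm"))
  ids <- .as_prefix_ids(model, prefix)
  vocab <- model$vocab
  sep_id <- vocab$token_to_id[["SEP"]]
  time_ids <- unname(vocab$token_to_id[.TIME_TOKENS])
  midpoints <- .TIME_TOKEN_MIDPOINT_DAYS

  state <- .lm_state_init(model$par, model$config, ids)
  is_event_id <- .is_event_token(vocab$tokens)
  elapsed <- 0
  visits_done <- 0L
  tokens_in_visit <- 0L
  step <- 0L
  best_rank <- NA_integer_
  rank_steps <- NULL

  while (TRUE) {
    step <- step + 1L
    p <- state$logits
    ord <- order(-p, seq_along(p))
    nxt <- ord[1L]
    # candidate rank of the best-ranked target token; recorded at
    # event-emitting steps only (structural grammar slots are deterministic
    # and their softmax tail carries no patient-specific signal)
    if (is_event_id[nxt] && elapsed <= window_days) {
      r <- min(match(target_ids, ord))
      if (is.na(best_rank) || r < best_rank) {
        best_rank <- r
        rank_steps <- rbind(rank_steps, cbind(step = step, rank = r))
      }
    }
    if (nxt %in% time_ids) {
      elapsed <- elapsed + midpoints[[vocab$tokens[nxt]]]
      if (elapsed > window_days) break
    }
    if (nxt == sep_id) {
      visits_done <- visits_done + 1L
      tokens_in_visit <- 0L
      if (visits_done >= max_future_visits) break
    } else {
      tokens_in_visit <- tokens_in_visit + 1L
      if (tokens_in_visit > max_visit_tokens) break
    }
    if (state$n >= model$config$context_window) break
    state <- .lm_state_step(model$par, model$config, state, nxt)
  }
  list(best_rank = best_rank, first_step_at_rank = rank_steps,
       n_steps = step, elapsed_days = elapsed)
}

#' Zero-shot confusion percentages at top-N candidate sets
#'
#' Runs the censored-window protocol for every cohort patient with a single
#' greedy pass per patient, reused across all N: a positive-arm patient
#' whose target enters the top-N set at any in-window step is a true
#' positive at that N (else false negative); a negative-arm hit is a false
#' positive (else true negative). Percentages are per arm, so TP% + FN% =
#' 100 over positives and FP% + TN% = 100 over negatives; nesting of the
#' candidate sets makes TP% and FP% non-decreasing in N.
#'
#' @param model a fitted `ehr_lm`.
#' @param records the cohort records (for rebuilding censored inputs).
#' @param cohort an `ehr_cohort_spec` from [build_diagnostic_cohort()].
#' @param Ns candidate-set sizes, default `c(1, 5, 10, 20)`.
#' @param mapping optional code mapping used at tokenization.
#' @param max_future_visits,max_visit_tokens generation caps.
#' @param max_len context used for censored input sequences.
#' @return an `ehr_confusion`: percentage matrix (rows TP/FP/TN/FN, columns
#'   N), cohort arm sizes, and per-patient best ranks.
#' @export
confusion_at_n <- function(model, records, cohort, Ns = c(1L, 5L, 10L, 20L),
                           mapping = NULL, max_future_visits = 10L,
                           max_visit_tokens = 64L, max_len = 512L) {
  stopifnot(inherits(model, "ehr_lm"), inherits(cohort, "ehr_cohort_spec"))
  if (!nrow(cohort$positives)) stop("cohort has an empty positive arm", call. = FALSE)
  if (!nrow(cohort$negatives)) stop("cohort has an empty negative arm", call. = FALSE)
  Ns <- sort(unique(as.integer(Ns)))
  vocab <- model$vocab
  by_id <- stats::setNames(seq_along(records),
                           vapply(records, function(r) as.character(r$person_id), character(1)))

  run_arm <- function(arm) {
    ranks <- rep(NA_integer_, nrow(arm))
    for (i in seq_len(nrow(arm))) {
      rec <- records[[by_id[[as.character(arm$person_id[i])]]]]
      cen <- censor_record(rec, arm$censor_date[i])
      if (!length(cen$visits)) next
      s <- tryCatch(build_sequence(cen, vocab, mapping, max_len),
                    error = function(e) NULL)
      if (is.null(s)) next
      # censoring soundness: the input must be target-free
      if (any(s$token_ids %in% cohort$target_token_ids)) {
        stop(sprintf("censoring violation: target token in input of person %s",
                     arm$person_id[i]), call. = FALSE)
      }
      res <- .roll_forward(model, s, cohort$target_token_ids,
                           cohort$window_days, max_future_visits,
                           max_visit_tokens)
      ranks[i] <- res$best_rank
    }
    ranks
  }

  pos_ranks <- run_arm(cohort$positives)
  neg_ranks <- run_arm(cohort$negatives)

  conf <- matrix(NA_real_, nrow = 4L, ncol = length(Ns),
                 dimnames = list(c("TP", "FP", "TN", "FN"), paste0("N=", Ns)))
  for (k in seq_along(Ns)) {
    tp <- mean(!is.na(pos_ranks) & pos_ranks <= Ns[k]) * 100
    fp <- mean(!is.na(neg_ranks) & neg_ranks <= Ns[k]) * 100
    conf[, k] <- c(tp, fp, 100 - fp, 100 - tp)
  }
  structure(
    list(confusion = conf, Ns = Ns,
         n_positive = nrow(cohort$positives), n_negative = nrow(cohort$negatives),
         positive_ranks = pos_ranks, negative_ranks = neg_ranks,
         window_months = cohort$window_months,
         target_codes = cohort$target_codes),
    class = "ehr_confusion")
}

#' @export
print.ehr_confusion <- function(x, digits = 2, ...) {
  cat(sprintf("Zero-shot censored-window confusion (target {%s}, %d-month window)\n",
              paste(x$target_codes, collapse = ", "), x$window_months))
  cat(sprintf("  %d positives, %d negatives; percentages per arm\n",
              x$n_positive, x$n_negative))
  print(round(x$confusion, digits))
  invisible(x)
}
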