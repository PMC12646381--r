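#' Fit an autoregressive next-event model on a tokenized EHR corpus
#'
#' Trains a compact decoder-only transformer with the next-token objective:
#' the mean negative log-likelihood of every token given its prefix under
#' causal masking. The default desk-scale architecture (2 layers, 2 heads,
#' 128 hidden units) trains on a CPU in minutes and is configurable upward.
#' Optimization uses Adam with a fixed learning rate and early stopping on
#' validation loss; the train/validation split is made at the patient level.
#' PAD targets are excluded from the loss. Training is deterministic given
#' the seed.
#'
#' @param corpus list of `ehr_sequence` objects or plain integer id vectors.
#' @param vocab the `ehr_vocab` the corpus was tokenized with.
#' @param n_layers,n_heads,hidden_dim transformer size; `hidden_dim` must be
#'   divisible by `n_heads`.
#' @param context_window maximum sequence length (must be >= the longest
#'   corpus sequence; matches the sequence builder's `max_len`).
#' @param dropout residual dropout rate during training (default 0).
#' @param learning_rate Adam learning rate.
#' @param batch_size sequences per minibatch.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); the best-validation weights are restored.
#' @param val_fraction patient-level fraction held out for validation
#'   (default 0.1, i.e. a 90/10 split).
#' @param seed integer seed controlling initialization, the split, shuffling
#'   and dropout.
#' @param verbose print per-epoch losses.
#' @return an object of class `ehr_lm` with elements `par` (weights),
#'   `config`, `vocab`, `history` (per-epoch train/validation loss),
#'   `n_train`, `n_val`.
#' @seealso [predict.ehr_lm()], [generate_visit()], [top_n_candidates()],
#'   [next_token_distribution()]
#' @export
ehr_lm <- function(corpus, vocab,
                   n_layers = 2L, n_heads = 2L, hidden_dim = 128L,
                   context_window = 512L, dropout = 0,
                   learning_rate = 3e-3, batch_size = 32L,
                   max_epochs = 20L, patience = 3L,
                   val_fraction = 0.1, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(vocab, "ehr_vocab"))
  if (hidden_dim %% n_heads != 0L) .stop_cfg("hidden_dim", "must be divisible by n_heads")
  seqs <- lapply(corpus, function(s) {
    ids <- if (inherits(s, "ehr_sequence")) s$token_ids else as.integer(s)
    ids
  })
  seqs <- seqs[lengths(seqs) >= 2L]
  if (!length(seqs)) stop("corpus has no sequences of length >= 2", call. = FALSE)
  V <- length(vocab$tokens)
  bad <- which(vapply(seqs, function(x) any(x < 1L | x > V | is.na(x)), logical(1)))
  if (length(bad)) {
    stop(sprintf("corpus sequence %d contains token ids outside the vocabulary (size %d)",
                 bad[1], V), call. = FALSE)
  }
  maxlen <- max(lengths(seqs))
  if (maxlen > context_window) {
    stop(sprintf("corpus has a sequence of %d tokens > context_window %d",
                 maxlen, context_window), call. = FALSE)
  }

  cfg <- list(vocab_size = V, context_window = as.integer(context_window),
              n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
              hidden_dim = as.integer(hidden_dim), dropout = dropout,
              seed = as.integer(seed))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  par <- .lm_init_par(cfg)
  adam <- .adam_init(par)
  pad_id <- vocab$token_to_id[["PAD"]] %||% NA_integer_

  n <- length(seqs)
  n_val <- if (val_fraction > 0 && n >= 10L) max(1L, round(val_fraction * n)) else 0L
  idx <- sample.int(n)
  val_idx <- if (n_val > 0L) idx[seq_len(n_val)] else integer(0)
  train_idx <- setdiff(idx, val_idx)

  eval_loss <- function(par, which_idx) {
    tot <- 0; npred <- 0L
    bs <- max(batch_size, 1L)
    for (b in split(which_idx, ceiling(seq_along(which_idx) / bs))) {
      ids <- unlist(seqs[b], use.names = FALSE)
      lens <- lengths(seqs[b])
      fwd <- .lm_forward(par, cfg, ids, lens, want = "logits")
      lg <- .lm_loss_grad(fwd$logits, ids, lens, pad_id)
      tot <- tot + lg$loss * lg$n_pred
      npred <- npred + lg$n_pred
    }
    tot / npred
  }

  history <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  best_par <- par; best_val <- Inf; best_epoch <- 0L; stall <- 0L
  for (ep in seq_len(max_epochs)) {
    ord <- sample(train_idx)
    tot <- 0; npred <- 0L
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      ids <- unlist(seqs[b], use.names = FALSE)
      lens <- lengths(seqs[b])
      masks <- .make_drop_masks(cfg, length(ids))
      fwd <- .lm_forward(par, cfg, ids, lens, want = "cache", drop_masks = masks)
      lg <- .lm_loss_grad(fwd$logits, ids, lens, pad_id)
      grad <- .lm_backward(par, cfg, ids, lens, fwd, lg$dlogits, drop_masks = masks)
      st <- .adam_step(par, grad, adam, lr = learning_rate)
      par <- st$par; adam <- st$state
      tot <- tot + lg$loss * lg$n_pred; npred <- npred + lg$n_pred
    }
    train_loss <- tot / npred
    val_loss <- if (n_val > 0L) eval_loss(par, val_idx) else train_loss
    history <- rbind(history, data.frame(epoch = ep, train = train_loss, val = val_loss))
    if (verbose) {
      message(sprintf("epoch %2d  train %.4f  val %.4f", ep, train_loss, val_loss))
    }
    if (val_loss < best_val - 1e-6) {
      best_val <- val_loss; best_par <- par; best_epoch <- ep; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }

  structure(
    list(par = best_par, config = cfg, vocab = vocab, history = history,
         best_epoch = best_epoch, best_val = best_val,
         n_train = length(train_idx), n_val = n_val,
         vocab_hash = rlang::hash(vocab$tokens),
         call = match.call()),
    class = "ehr_lm")
}

# internal constructor for hand-built models (interpretability tests, toys)
.new_ehr_lm <- function(par, cfg, vocab) {
  structure(list(par = par, config = cfg, vocab = vocab,
                 history = data.frame(epoch = integer(0), train = numeric(0),
                                      val = numeric(0)),
                 best_epoch = 0L, best_val = NA_real_,
                 n_train = 0L, n_val = 0L,
                 vocab_hash = rlang::hash(vocab$tokens), call = NULL),
            class = "ehr_lm")
}

.as_prefix_ids <- function(model, prefix) {
  ids <- if (inherits(prefix, "ehr_sequence")) prefix$token_ids else as.integer(prefix)
  if (!length(ids)) stop("prefix must be non-empty", call. = FALSE)
  V <- model$config$vocab_size
  if (any(is.na(ids) | ids < 1L | ids > V)) {
    stop("prefix contains ids outside the vocabulary", call. = FALSE)
  }
  cw <- model$config$context_window
  if (length(ids) > cw) {
    message(sprintf("prefix of %d tokens exceeds the context window; using the last %d",
                    length(ids), cw))
    ids <- ids[(length(ids) - cw + 1L):length(ids)]
  }
  ids
}

#' Next-token probability distribution
#'
#' @param model a fitted `ehr_lm`.
#' @param prefix an `ehr_sequence` or integer id vector (an overlong prefix
#'   is cut to its last `context_window` tokens, with a message).
#' @return numeric probability vector over the vocabulary (sums to 1).
#' @export
next_token_distribution <- function(model, prefix) {
  stopifnot(inherits(model, "ehr_lm"))
  ids <- .as_prefix_ids(model, prefix)
  fwd <- .lm_forward(model$par, model$config, ids, length(ids), want = "logits")
  z <- fwd$logits[length(ids), ]
  z <- z - max(z)
  e <- exp(z)
  stats::setNames(e / sum(e), model$vocab$tokens)
}

#' Top-N next-token candidate set
#'
#' The N highest-probability tokens for the next position; exact probability
#' ties are broken by ascending token id, so results are deterministic
#' across platforms, and `top_n_candidates(model, prefix, 1)` equals the
#' greedy choice.
#'
#' @inheritParams next_token_distribution
#' @param n candidate-set size (1 <= n <= vocabulary size).
#' @return integer vector of `n` token ids, highest probability first.
#' @export
top_n_candidates <- function(model, prefix, n) {
  stopifnot(inherits(model, "ehr_lm"))
  n <- .assert_count(n, "n")
  if (n > model$config$vocab_size) {
    stop("n exceeds the vocabulary size", call. = FALSE)
  }
  p <- next_token_distribution(model, prefix)
  order(-p, seq_along(p))[seq_len(n)]
}

#' Greedily generate one visit
#'
#' Extends the prefix by greedy decoding (top-1 at each step) until a SEP
#' token is produced or `max_visit_tokens` tokens have been generated (the
#' cap is reported via the `capped` flag). The prefix must end at a visit
#' boundary. SEP is excluded from the returned tokens.
#'
#' @inheritParams next_token_distribution
#' @param max_visit_tokens generation cap per visit, default 64.
#' @return list with `token_ids` (generated tokens, SEP excluded), `tokens`
#'   (their strings) and `capped`.
#' @export
generate_visit <- function(model, prefix, max_visit_tokens = 64L) {
  stopifnot(inherits(model, "ehr_lm"))
  ids <- .as_prefix_ids(model, prefix)
  sep_id <- model$vocab$token_to_id[["SEP"]]
  state <- .lm_state_init(model$par, model$config, ids)
  out <- integer(0); capped <- FALSE
  for (i in seq_len(max_visit_tokens)) {
    p <- state$logits
    nxt <- order(-p, seq_along(p))[1L]
    if (nxt == sep_id) return(list(token_ids = out,
                                   tokens = model$vocab$tokens[out],
                                   capped = FALSE))
    out <- c(out, nxt)
    if (state$n >= model$config$context_window) { capped <- TRUE; break }
    state <- .lm_state_step(model$par, model$config, state, nxt)
  }
  list(token_ids = out, tokens = model$vocab$tokens[out],
       capped = TRUE)
}

#' @export
print.ehr_lm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Autoregressive EHR event model (decoder-only transformer)\n"))
  cat(sprintf("  %d layers, %d heads, %d hidden, vocab %d, context %d\n",
              cfg$n_layers, cfg$n_heads, cfg$hidden_dim, cfg$vocab_size,
              cfg$context_window))
  if (nrow(x$history)) {
    cat(sprintf("  trained %d epochs on %d sequences (best epoch %d, val loss %.4f nats/token)\n",
                nrow(x$history), x$n_train, x$best_epoch, x$best_val))
  } else {
    cat("  (untrained weights)\n")
  }
  invisible(x)
}

#' @export
summary.ehr_lm <- function(object, ...) {
  n_par <- sum(unlist(.tree_map(length, object$par)))
  out <- list(config = object$config, n_parameters = n_par,
              history = object$history, best_epoch = object$best_epoch,
              best_val = object$best_val, n_train = object$n_train,
              n_val = object$n_val)
  class(out) <- "summary.ehr_lm"
  out
}

#' @export
print.summary.ehr_lm <- function(x, ...) {
  cat(sprintf("Decoder-only transformer: %s parameters\n",
              format(x$n_parameters, big.mark = ",")))
  cat(sprintf("  train/validation sequences: %d/%d\n", x$n_train, x$n_val))
  if (nrow(x$history)) {
    cat(sprintf("  final train loss %.4f, best validation loss %.4f (epoch %d)\n",
                x$history$train[nrow(x$history)], x$best_val, x$best_epoch))
  }
  invisible(x)
}

#' @export
plot.ehr_lm <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("model has no training history", call. = FALSE)
  graphics::plot(h$epoch, h$train, type = "b", pch = 16,
                 xlab = "epoch", ylab = "loss (nats/token)",
                 ylim = range(c(h$train, h$val)), ...)
  graphics::lines(h$epoch, h$val, type = "b", pch = 1, lty = 2)
  graphics::legend("topright", c("train", "validation"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' @export
coef.ehr_lm <- function(object, ...) {
  emb <- object$par$tok
  rownames(emb) <- object$vocab$tokens
  emb
}

#' @export
logLik.ehr_lm <- function(object, ...) {
  val <- -object$best_val
  attr(val, "nobs") <- object$n_train
  attr(val, "df") <- sum(unlist(.tree_map(length, object$par)))
  class(val) <- "logLik"
  val
}

#' Predict method for fitted EHR event models
#'
#' @param object a fitted `ehr_lm`.
#' @param prefix sequence prefix (ids or `ehr_sequence`).
#' @param type `"distribution"` for the next-token probability vector,
#'   `"top_n"` for the top-N candidate ids, `"visit"` for a greedily
#'   generated visit.
#' @param n candidate-set size for `type = "top_n"`.
#' @param ... unused.
#' @export
predict.ehr_lm <- function(object, prefix, type = c("distribution", "top_n", "visit"),
                           n = 10L, ...) {
  type <- match.arg(type)
  switch(type,
         distribution = next_token_distribution(object, prefix),
         top_n = top_n_candidates(object, prefix, n),
         visit = generate_visit(object, prefix))
}

#' Simulate future visits from a fitted model
#'
#' Greedy continuation of a prefix for `nsim` visits (each ended by SEP or
#' the per-visit cap), mirroring how the zero-shot protocol rolls a patient
#' history forward.
#'
#' @param object a fitted `ehr_lm`.
#' @param nsim number of visits to generate.
#' @param seed ignored (greedy decoding is deterministic); present for the
#'   `simulate()` generic.
#' @param prefix sequence prefix ending at a visit boundary.
#' @param ... unused.
#' @return list of generated visits, each as in [generate_visit()].
#' @export
simulate.ehr_lm <- function(object, nsim = 1L, seed = NULL, prefix, ...) {
  sep_id <- object$vocab$token_to_id[["SEP"]]
  ids <- .as_prefix_ids(object, prefix)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    v <- generate_visit(object, ids)
    out[[i]] <- v
    ids <- c(ids, v$token_ids, if (!v$capped) sep_id)
    if (length(ids) >= object$config$context_window) break
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the weights, configuration, training history and a
#' hash of the vocabulary; loading against a different vocabulary is
#' refused.
#'
#' @param model a fitted `ehr_lm`.
#' @param path checkpoint file path.
#' @return `save_checkpoint`: invisibly, `path`; `load_checkpoint`: the
#'   `ehr_lm`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ehr_lm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param vocab optional `ehr_vocab` to validate the checkpoint against.
#' @export
load_checkpoint <- function(path, vocab = NULL) {
  model <- readRDS(path)
  if (!inherits(model, "ehr_lm")) stop("not an ehr_lm checkpoint", call. = FALSE)
  if (!is.null(vocab)) {
    if (!identical(model$vocab_hash, rlang::hash(vocab$tokens))) {
      stop("checkpoint vocabulary hash does not match the supplied vocabulary",
           call. = FALSE)
    }
  }
  model
}
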