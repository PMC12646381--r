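# Supervised comparator: the trained transformer is a frozen feature
# extractor (mean-pooled final-layer hidden states); only a linear binary
# head is trained, with dropout, Adam and class-balanced weighted sampling.
# Sensitivity is reported at a matched false-positive rate.

#' Mean-pooled sequence embedding from the frozen backbone
#'
#' Runs the (frozen) model forward and averages the final-layer hidden
#' states (after the final layer norm) over all non-PAD positions.
#' Deterministic: the same sequence always yields the same vector.
#'
#' @param model a fitted `ehr_lm`.
#' @param sequence an `ehr_sequence` or integer id vector.
#' @return numeric vector of length `hidden_dim`.
#' @export
extract_embedding <- function(model, sequence) {
  stopifnot(inherits(model, "ehr_lm"))
  ids <- .as_prefix_ids(model, sequence)
  pad_id <- model$vocab$token_to_id[["PAD"]] %||% NA_integer_
  fwd <- .lm_forward(model$par, model$config, ids, length(ids), want = "cache")
  H <- fwd$lnf$Y
  keep <- if (is.na(pad_id)) rep(TRUE, length(ids)) else ids != pad_id
  if (!any(keep)) stop("sequence has no non-PAD tokens", call. = FALSE)
  colMeans(H[keep, , drop = FALSE])
}

#' Train a linear probe on frozen embeddings
#'
#' A single linear layer preceded by dropout, trained with the logistic
#' loss, Adam (learning rate 1e-4), and class balancing via weighted
#' sampling: minibatches are drawn with replacement with per-example
#' probabilities inversely proportional to class frequency, so expected
#' class frequencies are balanced per batch. The backbone is untouched by
#' construction (only the embedding matrix enters); tests assert
#' byte-identity of the backbone across head training.
#'
#' @param embeddings numeric matrix, one row per example.
#' @param labels binary labels (0/1 or logical).
#' @param dropout dropout rate on the input embedding, default 0.1.
#' @param learning_rate Adam learning rate, default 1e-4.
#' @param epochs maximum epochs, default 300.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience on validation loss.
#' @param val_fraction held-out fraction (stratified), default 0.2.
#' @param seed seed for sampling, dropout and initialization.
#' @return an `ehr_probe`: weights `w`, bias `b`, training `log`.
#' @export
fit_linear_probe <- function(embeddings, labels, dropout = 0.1,
                             learning_rate = 1e-4, epochs = 300L,
                             batch_size = 32L, patience = 25L,
                             val_fraction = 0.2, seed = 1L) {
  X <- as.matrix(embeddings)
  y <- as.integer(labels)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("labels must contain both classes", call. = FALSE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- nrow(X); d <- ncol(X)

  # stratified validation split
  val_idx <- integer(0)
  if (val_fraction > 0) {
    for (cls in c(0L, 1L)) {
      ic <- which(y == cls)
      k <- floor(val_fraction * length(ic))
      if (k >= 1L && length(ic) - k >= 1L) val_idx <- c(val_idx, sample(ic, k))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(y[tr_idx])) < 2L) { tr_idx <- seq_len(n); val_idx <- integer(0) }

  # weighted sampling: inverse class frequency among training examples
  wts <- ifelse(y[tr_idx] == 1L, 1 / sum(y[tr_idx] == 1L), 1 / sum(y[tr_idx] == 0L))
  wts <- wts / sum(wts)

  w <- stats::rnorm(d, sd = 0.01); b <- 0
  mw <- vw <- numeric(d); mb <- vb <- 0; t <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  steps_per_epoch <- max(1L, ceiling(length(tr_idx) / batch_size))
  keep <- 1 - dropout

  probe_loss <- function(w, b, idx) {
    z <- drop(X[idx, , drop = FALSE] %*% w) + b
    mean(log1p(exp(-abs(z))) + pmax(z, 0) - y[idx] * z)
  }

  log_df <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  best <- list(w = w, b = b, val = Inf); stall <- 0L
  for (ep in seq_len(epochs)) {
    ep_loss <- 0
    for (sbatch in seq_len(steps_per_epoch)) {
      take <- tr_idx[sample.int(length(tr_idx), batch_size, replace = TRUE, prob = wts)]
      Xb <- X[take, , drop = FALSE]
      if (dropout > 0) {
        mask <- matrix((stats::runif(length(Xb)) < keep) / keep, nrow(Xb))
        Xb <- Xb * mask
      }
      z <- drop(Xb %*% w) + b
      p <- 1 / (1 + exp(-z))
      err <- p - y[take]
      gw <- drop(crossprod(Xb, err)) / length(take)
      gb <- mean(err)
      t <- t + 1L
      mw <- beta1 * mw + (1 - beta1) * gw; vw <- beta2 * vw + (1 - beta2) * gw^2
      mb <- beta1 * mb + (1 - beta1) * gb; vb <- beta2 * vb + (1 - beta2) * gb^2
      w <- w - learning_rate * (mw / (1 - beta1^t)) / (sqrt(vw / (1 - beta2^t)) + eps)
      b <- b - learning_rate * (mb / (1 - beta1^t)) / (sqrt(vb / (1 - beta2^t)) + eps)
      ep_loss <- ep_loss + mean(log1p(exp(-abs(z))) + pmax(z, 0) - y[take] * z)
    }
    vl <- if (length(val_idx)) probe_loss(w, b, val_idx) else probe_loss(w, b, tr_idx)
    log_df <- rbind(log_df, data.frame(epoch = ep, train = ep_loss / steps_per_epoch, val = vl))
    if (vl < best$val - 1e-7) {
      best <- list(w = w, b = b, val = vl); stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  structure(list(w = best$w, b = best$b, log = log_df,
                 dropout = dropout, learning_rate = learning_rate,
                 n_train = length(tr_idx), n_val = length(val_idx)),
            class = "ehr_probe")
}

#' @export
print.ehr_probe <- function(x, ...) {
  cat(sprintf("Linear probe on frozen embeddings: %d features, %d epochs trained\n",
              length(x$w), nrow(x$log)))
  invisible(x)
}

#' @export
predict.ehr_probe <- function(object, embeddings, type = c("score", "class"), ...) {
  type <- match.arg(type)
  z <- drop(as.matrix(embeddings) %*% object$w) + object$b
  p <- 1 / (1 + exp(-z))
  if (type == "score") p else as.integer(p >= 0.5)
}

#' Sensitivity at a matched false-positive rate
#'
#' Sweeps the decision threshold (predicted positive when score exceeds the
#' threshold) and selects the smallest threshold whose false-positive
#' percentage is at most `fp_target_percent` — the conservative choice that
#' never overstates sensitivity at the stated specificity. With tied scores
#' an exactly-zero FP% may force a threshold above every score, giving TP%
#' 0; this is noted in the result.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive).
#' @param fp_target_percent allowed false-positive percentage of the
#'   negative arm.
#' @return list with `tp_percent`, `fp_percent` (achieved), `threshold`,
#'   and `note` (non-empty when the target was unattainable exactly).
#' @export
tp_at_matched_fp <- function(scores, labels, fp_target_percent) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary", call. = FALSE)
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L) stop("both classes required", call. = FALSE)
  cand <- c(-Inf, sort(unique(scores)))
  fp_pct <- vapply(cand, function(t) 100 * sum(scores > t & y == 0L) / nneg, numeric(1))
  ok <- which(fp_pct <= fp_target_percent)
  k <- ok[1L]  # smallest threshold meeting the constraint (fp_pct is non-increasing)
  thr <- cand[k]
  tp <- 100 * sum(scores > thr & y == 1L) / npos
  note <- if (sum(scores > thr) == 0) {
    "tied scores: FP target only attainable at a threshold above every score"
  } else ""
  list(tp_percent = tp, fp_percent = fp_pct[k], threshold = thr, note = note)
}
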