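# Decoder-only transformer internals: parameter initialization, batched
# ragged forward pass, manual backpropagation, Adam. Pre-norm residual
# blocks (x + Attn(LN(x)); x + MLP(LN(x))), learned positional embeddings,
# GELU feed-forward, causal masking within each sequence. Sequences in a
# minibatch are concatenated (ragged, no padding): position-wise operations
# run as single BLAS matmuls over all tokens; attention loops over
# sequence x head with small dense score matrices.

.lm_init_par <- function(cfg) {
  d <- cfg$hidden_dim; V <- cfg$vocab_size; P <- cfg$context_window
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  layer <- function() list(
    ln1g = rep(1, d), ln1b = rep(0, d),
    Wqkv = rn(d, 3L * d), bqkv = rep(0, 3L * d),
    Wo = rn(d, d), bo = rep(0, d),
    ln2g = rep(1, d), ln2b = rep(0, d),
    W1 = rn(d, 4L * d), b1 = rep(0, 4L * d),
    W2 = rn(4L * d, d), b2 = rep(0, d)
  )
  list(tok = rn(V, d), pos = rn(P, d),
       layers = lapply(seq_len(cfg$n_layers), function(i) layer()),
       lnfg = rep(1, d), lnfb = rep(0, d),
       Wout = rn(d, V), bout = rep(0, V))
}

.ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  inv <- 1 / sqrt(v + 1e-5)
  xhat <- Xc * inv
  list(Y = .add_rowvec(xhat * rep(g, rep.int(nrow(X), length(g))), b),
       xhat = xhat, inv = inv)
}

# cleaner/faster layernorm using matrix recycling by rows is awkward in R;
# xhat * g via outer-style indexing above; backward below matches it
.ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- dY * matrix(g, nrow(dY), length(g), byrow = TRUE)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

# sigmoid-approximated GELU (x * sigmoid(1.702 x)): avoids the cost of
# normal-CDF evaluations while matching GELU closely
.gelu <- function(x) x / (1 + exp(-1.702 * x))
.gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s + 1.702 * x * s * (1 - s)
}

# add a row vector to every row (column-major aligned; cheaper than sweep)
.add_rowvec <- function(X, b) X + rep(b, rep.int(nrow(X), length(b)))

.softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# forward over a ragged batch.
# ids: integer vector (concatenated); lens: per-sequence lengths.
# want: "loss" (needs targets), "cache" (for backward), "logits", "kv",
# "attn" (final-layer per-head attention of the last block row).
.lm_forward <- function(par, cfg, ids, lens, want = "logits",
                        drop_masks = NULL) {
  d <- cfg$hidden_dim; H <- cfg$n_heads; dh <- d %/% H
  nseq <- length(lens)
  ends <- cumsum(lens); starts <- ends - lens + 1L
  N <- sum(lens)
  positions <- unlist(lapply(lens, seq_len), use.names = FALSE)
  keep_cache <- identical(want, "cache")

  X <- par$tok[ids, , drop = FALSE] + par$pos[positions, , drop = FALSE]
  layer_caches <- if (keep_cache) vector("list", cfg$n_layers)
  kv <- if (identical(want, "kv")) vector("list", cfg$n_layers)
  attn_last <- NULL
  scale <- 1 / sqrt(dh)

  for (li in seq_len(cfg$n_layers)) {
    L <- par$layers[[li]]
    ln1 <- .ln_fwd(X, L$ln1g, L$ln1b)
    QKV <- .add_rowvec(ln1$Y %*% L$Wqkv, L$bqkv)
    O <- matrix(0, N, d)
    if (identical(want, "attn") && li == cfg$n_layers) {
      attn_last <- vector("list", nseq)
    }
    for (s in seq_len(nseq)) {
      rs <- starts[s]:ends[s]
      n <- lens[s]
      for (h in seq_len(H)) {
        qc <- ((h - 1L) * dh + 1L):(h * dh)
        Q <- QKV[rs, qc, drop = FALSE]
        K <- QKV[rs, d + qc, drop = FALSE]
        Vv <- QKV[rs, 2L * d + qc, drop = FALSE]
        S <- tcrossprod(Q, K) * scale
        S[upper.tri(S)] <- -Inf
        P <- .softmax_rows(S)
        O[rs, qc] <- P %*% Vv
        if (!is.null(attn_last) && li == cfg$n_layers) {
          if (is.null(attn_last[[s]])) attn_last[[s]] <- matrix(0, H, n)
          attn_last[[s]][h, ] <- P[n, ]
        }
      }
    }
    AO <- .add_rowvec(O %*% L$Wo, L$bo)
    dm1 <- if (is.null(drop_masks)) NULL else drop_masks[[li]]$m1
    if (!is.null(dm1)) AO <- AO * dm1
    X1 <- X + AO
    ln2 <- .ln_fwd(X1, L$ln2g, L$ln2b)
    Hpre <- .add_rowvec(ln2$Y %*% L$W1, L$b1)
    G <- .gelu(Hpre)
    FF <- .add_rowvec(G %*% L$W2, L$b2)
    dm2 <- if (is.null(drop_masks)) NULL else drop_masks[[li]]$m2
    if (!is.null(dm2)) FF <- FF * dm2
    X2 <- X1 + FF

    if (keep_cache) {
      layer_caches[[li]] <- list(X = X, ln1 = ln1, QKV = QKV, O = O,
                                 X1 = X1, ln2 = ln2, Hpre = Hpre, G = G)
    }
    if (identical(want, "kv")) {
      kv[[li]] <- list(K = QKV[, (d + 1L):(2L * d), drop = FALSE],
                       V = QKV[, (2L * d + 1L):(3L * d), drop = FALSE])
    }
    X <- X2
  }
  lnf <- .ln_fwd(X, par$lnfg, par$lnfb)
  logits <- .add_rowvec(lnf$Y %*% par$Wout, par$bout)

  out <- list(logits = logits, positions = positions,
              starts = starts, ends = ends)
  if (keep_cache) { out$layer_caches <- layer_caches; out$lnf <- lnf; out$Xf <- X }
  if (identical(want, "kv")) out$kv <- kv
  if (!is.null(attn_last)) out$attn_last <- attn_last
  out
}

# mean next-token NLL and dlogits over predicting positions
.lm_loss_grad <- function(logits, ids, lens, pad_id = NA_integer_) {
  ends <- cumsum(lens); starts <- ends - lens + 1L
  pred_pos <- unlist(lapply(seq_along(lens), function(s) {
    if (lens[s] < 2L) integer(0) else starts[s]:(ends[s] - 1L)
  }), use.names = FALSE)
  targets <- ids[pred_pos + 1L]
  if (!is.na(pad_id)) {
    keep <- targets != pad_id
    pred_pos <- pred_pos[keep]; targets <- targets[keep]
  }
  n_pred <- length(pred_pos)
  if (n_pred == 0L) stop("no predictable positions in batch", call. = FALSE)
  Lp <- logits[pred_pos, , drop = FALSE]
  m <- Lp[cbind(seq_len(n_pred), max.col(Lp, ties.method = "first"))]
  lse <- m + log(rowSums(exp(Lp - m)))
  tix <- cbind(seq_len(n_pred), targets)
  nll <- lse - Lp[tix]
  Pm <- exp(Lp - lse)
  Pm[tix] <- Pm[tix] - 1
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[pred_pos, ] <- Pm / n_pred
  list(loss = mean(nll), dlogits = dlogits, n_pred = n_pred,
       per_position = stats::setNames(nll, pred_pos))
}

# full backward pass; returns gradient tree matching par
.lm_backward <- function(par, cfg, ids, lens, fwd, dlogits, drop_masks = NULL) {
  d <- cfg$hidden_dim; H <- cfg$n_heads; dh <- d %/% H
  nseq <- length(lens)
  starts <- fwd$starts; ends <- fwd$ends
  scale <- 1 / sqrt(dh)

  g <- list(tok = matrix(0, nrow(par$tok), d), pos = matrix(0, nrow(par$pos), d),
            layers = vector("list", cfg$n_layers),
            lnfg = NULL, lnfb = NULL, Wout = NULL, bout = NULL)

  g$Wout <- crossprod(fwd$lnf$Y, dlogits)
  g$bout <- colSums(dlogits)
  dY <- dlogits %*% t(par$Wout)
  lb <- .ln_bwd(dY, fwd$lnf, par$lnfg)
  g$lnfg <- lb$dg; g$lnfb <- lb$db
  dX <- lb$dX

  for (li in rev(seq_len(cfg$n_layers))) {
    L <- par$layers[[li]]
    ch <- fwd$layer_caches[[li]]
    gl <- list()

    # feed-forward branch
    dFF <- dX
    dm2 <- if (is.null(drop_masks)) NULL else drop_masks[[li]]$m2
    if (!is.null(dm2)) dFF <- dFF * dm2
    gl$W2 <- crossprod(ch$G, dFF)
    gl$b2 <- colSums(dFF)
    dG <- dFF %*% t(L$W2)
    dHpre <- dG * .gelu_grad(ch$Hpre)
    gl$W1 <- crossprod(ch$ln2$Y, dHpre)
    gl$b1 <- colSums(dHpre)
    dB <- dHpre %*% t(L$W1)
    lb2 <- .ln_bwd(dB, ch$ln2, L$ln2g)
    gl$ln2g <- lb2$dg; gl$ln2b <- lb2$db
    dX1 <- dX + lb2$dX

    # attention branch
    dAO <- dX1
    dm1 <- if (is.null(drop_masks)) NULL else drop_masks[[li]]$m1
    if (!is.null(dm1)) dAO <- dAO * dm1
    gl$Wo <- crossprod(ch$O, dAO)
    gl$bo <- colSums(dAO)
    dO <- dAO %*% t(L$Wo)

    dQKV <- matrix(0, nrow(dO), 3L * d)
    QKV <- ch$QKV
    for (s in seq_len(nseq)) {
      rs <- starts[s]:ends[s]
      for (h in seq_len(H)) {
        qc <- ((h - 1L) * dh + 1L):(h * dh)
        Q <- QKV[rs, qc, drop = FALSE]
        K <- QKV[rs, d + qc, drop = FALSE]
        Vv <- QKV[rs, 2L * d + qc, drop = FALSE]
        S <- tcrossprod(Q, K) * scale
        S[upper.tri(S)] <- -Inf
        P <- .softmax_rows(S)
        dOb <- dO[rs, qc, drop = FALSE]
        dP <- tcrossprod(dOb, Vv)
        dVv <- crossprod(P, dOb)
        dS <- P * (dP - rowSums(dP * P))
        dQ <- (dS %*% K) * scale
        dK <- crossprod(dS, Q) * scale
        dQKV[rs, qc] <- dQKV[rs, qc] + dQ
        dQKV[rs, d + qc] <- dQKV[rs, d + qc] + dK
        dQKV[rs, 2L * d + qc] <- dQKV[rs, 2L * d + qc] + dVv
      }
    }
    gl$Wqkv <- crossprod(ch$ln1$Y, dQKV)
    gl$bqkv <- colSums(dQKV)
    dA <- dQKV %*% t(L$Wqkv)
    lb1 <- .ln_bwd(dA, ch$ln1, L$ln1g)
    gl$ln1g <- lb1$dg; gl$ln1b <- lb1$db
    dX <- dX1 + lb1$dX
    g$layers[[li]] <- gl
  }

  # embedding scatter-add
  tt <- rowsum(dX, ids)
  g$tok[as.integer(rownames(tt)), ] <- tt
  pp <- rowsum(dX, fwd$positions)
  g$pos[as.integer(rownames(pp)), ] <- pp
  g
}

# --- parameter-tree utilities ------------------------------------------------

.tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, .tree_map, f = f) else f(a)
}

# zip trees matching children by name where names exist (gradient lists may
# order fields differently than the parameter list)
.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    nm <- names(a)
    for (i in seq_along(a)) {
      bi <- if (!is.null(nm) && !is.null(names(b))) b[[nm[i]]] else b[[i]]
      out[[i]] <- .tree_map2(f, a[[i]], bi)
    }
    out
  } else f(a, b)
}

.tree_map3 <- function(f, a, b, c3) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    nm <- names(a)
    for (i in seq_along(a)) {
      bi <- if (!is.null(nm) && !is.null(names(b))) b[[nm[i]]] else b[[i]]
      ci <- if (!is.null(nm) && !is.null(names(c3))) c3[[nm[i]]] else c3[[i]]
      out[[i]] <- .tree_map3(f, a[[i]], bi, ci)
    }
    out
  } else f(a, b, c3)
}

.adam_init <- function(par) {
  list(m = .tree_map(function(x) x * 0, par),
       v = .tree_map(function(x) x * 0, par),
       t = 0L)
}

.adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grad)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grad)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  par <- .tree_map3(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                    par, state$m, state$v)
  list(par = par, state = state)
}

# dropout masks per layer for one batch (NULL when rate is 0)
.make_drop_masks <- function(cfg, N) {
  p <- cfg$dropout
  if (is.null(p) || p <= 0) return(NULL)
  keep <- 1 - p
  lapply(seq_len(cfg$n_layers), function(i) {
    list(m1 = matrix((stats::runif(N * cfg$hidden_dim) < keep) / keep, N),
         m2 = matrix((stats::runif(N * cfg$hidden_dim) < keep) / keep, N))
  })
}

# --- incremental decoding (KV cache) ----------------------------------------

.lm_state_init <- function(par, cfg, ids) {
  lens <- length(ids)
  fwd <- .lm_forward(par, cfg, ids, lens, want = "kv")
  list(n = length(ids), kv = fwd$kv,
       logits = fwd$logits[length(ids), ])
}

.lm_state_step <- function(par, cfg, state, id) {
  d <- cfg$hidden_dim; H <- cfg$n_heads; dh <- d %/% H
  p <- state$n + 1L
  if (p > cfg$context_window) stop("decode state exceeded the context window", call. = FALSE)
  x <- par$tok[id, , drop = FALSE] + par$pos[p, , drop = FALSE]
  scale <- 1 / sqrt(dh)
  for (li in seq_len(cfg$n_layers)) {
    L <- par$layers[[li]]
    a <- .ln_fwd(x, L$ln1g, L$ln1b)$Y
    qkv <- a %*% L$Wqkv + matrix(L$bqkv, 1L)
    K <- rbind(state$kv[[li]]$K, qkv[, (d + 1L):(2L * d), drop = FALSE])
    Vv <- rbind(state$kv[[li]]$V, qkv[, (2L * d + 1L):(3L * d), drop = FALSE])
    state$kv[[li]]$K <- K
    state$kv[[li]]$V <- Vv
    o <- numeric(d)
    for (h in seq_len(H)) {
      qc <- ((h - 1L) * dh + 1L):(h * dh)
      s <- drop(K[, qc, drop = FALSE] %*% qkv[1L, qc]) * scale
      w <- exp(s - max(s)); w <- w / sum(w)
      o[qc] <- drop(crossprod(Vv[, qc, drop = FALSE], w))
    }
    x <- x + matrix(o, 1L) %*% L$Wo + matrix(L$bo, 1L)
    b <- .ln_fwd(x, L$ln2g, L$ln2b)$Y
    x <- x + .gelu(b %*% L$W1 + matrix(L$b1, 1L)) %*% L$W2 + matrix(L$b2, 1L)
  }
  xf <- .ln_fwd(x, par$lnfg, par$lnfb)$Y
  state$logits <- drop(xf %*% par$Wout) + par$bout
  state$n <- p
  state
}
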