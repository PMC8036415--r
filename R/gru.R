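# Gated recurrent generator internals. The generator is an autoregressive
# policy over discrete tokens: at step t it embeds the previous token
# (a start symbol at t = 1), updates a GRU hidden state and emits a
# softmax distribution over the token vocabulary. Forward passes cache
# every activation so gradients (teacher-forced likelihood or policy
# gradients with externally supplied dlogits) run by backprop through time.
# All functions are batch-first: token matrices are B x T.

gru_init_params <- function(V, emb_dim, hidden) {
  d <- emb_dim; H <- hidden
  s <- function(nr, nc) matrix(runif(nr * nc, -0.08, 0.08), nr, nc)
  list(E = s(V + 1L, d),                      # row V+1 embeds the start token
       Wz = s(d, H), Uz = s(H, H), bz = numeric(H),
       Wr = s(d, H), Ur = s(H, H), br = numeric(H),
       Wh = s(d, H), Uh = s(H, H), bh = numeric(H),
       Wo = s(H, V), bo = numeric(V))
}

# One GRU step. prev: integer vector (B) of previous tokens (V+1 = start);
# Hprev: B x H. Returns the new state, softmax probabilities and the
# intermediates needed for backprop.
gru_cell <- function(params, prev, Hprev) {
  X <- params$E[prev, , drop = FALSE]
  z <- sigmoid(X %*% params$Wz + Hprev %*% params$Uz +
                 rep(params$bz, each = nrow(X)))
  r <- sigmoid(X %*% params$Wr + Hprev %*% params$Ur +
                 rep(params$br, each = nrow(X)))
  cc <- tanh(X %*% params$Wh + (r * Hprev) %*% params$Uh +
               rep(params$bh, each = nrow(X)))
  Hn <- (1 - z) * Hprev + z * cc
  logits <- Hn %*% params$Wo + rep(params$bo, each = nrow(X))
  P <- softmax_rows(logits)
  list(H = Hn, P = P, X = X, prev = prev, Hprev = Hprev, z = z, r = r, cc = cc)
}

# Teacher-forced forward over a token matrix. Returns per-step caches and
# per-step probabilities.
gru_forward <- function(params, tokens, H0 = NULL) {
  B <- nrow(tokens); T <- ncol(tokens)
  V <- ncol(params$Wo)
  Hprev <- H0 %||% matrix(0, B, ncol(params$Uz))
  steps <- vector("list", T)
  for (t in seq_len(T)) {
    prev <- if (t == 1L) rep(V + 1L, B) else tokens[, t - 1L]
    st <- gru_cell(params, prev, Hprev)
    steps[[t]] <- st
    Hprev <- st$H
  }
  list(steps = steps, tokens = tokens, B = B, T = T)
}

# Backprop through time. dlogits: list of T matrices (B x V), the gradient
# of the scalar objective w.r.t. each step's logits. Returns parameter
# gradients shaped like params.
gru_backward <- function(params, fwd, dlogits) {
  B <- fwd$B; T <- fwd$T
  H <- ncol(params$Uz); V <- ncol(params$Wo)
  g <- lapply(params, function(p) p * 0)
  dHnext <- matrix(0, B, H)
  for (t in rev(seq_len(T))) {
    st <- fwd$steps[[t]]
    dl <- dlogits[[t]]
    g$Wo <- g$Wo + crossprod(st$H, dl)
    g$bo <- g$bo + colSums(dl)
    dH <- tcrossprod(dl, params$Wo) + dHnext
    dz <- dH * (st$cc - st$Hprev)
    dcc <- dH * st$z
    dHprev <- dH * (1 - st$z)
    dac <- dcc * (1 - st$cc^2)
    g$Wh <- g$Wh + crossprod(st$X, dac)
    g$Uh <- g$Uh + crossprod(st$r * st$Hprev, dac)
    g$bh <- g$bh + colSums(dac)
    drH <- tcrossprod(dac, params$Uh)
    dr <- drH * st$Hprev
    dHprev <- dHprev + drH * st$r
    daz <- dz * st$z * (1 - st$z)
    dar <- dr * st$r * (1 - st$r)
    g$Wz <- g$Wz + crossprod(st$X, daz)
    g$Uz <- g$Uz + crossprod(st$Hprev, daz)
    g$bz <- g$bz + colSums(daz)
    g$Wr <- g$Wr + crossprod(st$X, dar)
    g$Ur <- g$Ur + crossprod(st$Hprev, dar)
    g$br <- g$br + colSums(dar)
    dX <- tcrossprod(dac, params$Wh) + tcrossprod(daz, params$Wz) +
      tcrossprod(dar, params$Wr)
    agg <- rowsum(dX, st$prev)
    rows <- as.integer(rownames(agg))
    g$E[rows, ] <- g$E[rows, , drop = FALSE] + agg
    dHnext <- dHprev + tcrossprod(daz, params$Uz) + tcrossprod(dar, params$Ur)
  }
  g
}

# Gradient of the weighted negative log-likelihood
#   L = sum_{b,t} wgt[b,t] * (-log P(tokens[b,t]))
# under teacher forcing. Used for MLE pretraining (uniform weights).
gru_nll_grad <- function(params, tokens, wgt = NULL) {
  fwd <- gru_forward(params, tokens)
  B <- fwd$B; T <- fwd$T; V <- ncol(params$Wo)
  if (is.null(wgt)) wgt <- matrix(1 / (B * T), B, T)
  loss <- 0
  dlogits <- vector("list", T)
  for (t in seq_len(T)) {
    P <- fwd$steps[[t]]$P
    py <- P[cbind(seq_len(B), tokens[, t])]
    loss <- loss + sum(wgt[, t] * (-log(pmax(py, 1e-300))))
    dl <- P * wgt[, t]
    dl[cbind(seq_len(B), tokens[, t])] <-
      dl[cbind(seq_len(B), tokens[, t])] - wgt[, t]
    dlogits[[t]] <- dl
  }
  list(loss = loss, grads = gru_backward(params, fwd, dlogits))
}

# Sample continuations. B rows advance `steps` steps starting from hidden
# state H0 and previous tokens prev; uses the current RNG stream.
gru_sample_steps <- function(params, B, steps, H0, prev) {
  V <- ncol(params$Wo)
  out <- matrix(0L, B, steps)
  Hprev <- H0
  for (s in seq_len(steps)) {
    st <- gru_cell(params, prev, Hprev)
    y <- sample_rows(st$P, runif(B))
    out[, s] <- y
    prev <- y
    Hprev <- st$H
  }
  out
}

# Sample B complete sequences of length T from the policy.
gru_sample <- function(params, B, T) {
  V <- ncol(params$Wo)
  H <- ncol(params$Uz)
  gru_sample_steps(params, B, T, matrix(0, B, H), rep(V + 1L, B))
}

# Greedy (argmax) decode of one sequence.
gru_greedy <- function(params, T) {
  V <- ncol(params$Wo); H <- ncol(params$Uz)
  Hprev <- matrix(0, 1L, H); prev <- V + 1L
  out <- integer(T)
  for (t in seq_len(T)) {
    st <- gru_cell(params, prev, Hprev)
    out[t] <- which.max(st$P[1L, ])
    prev <- out[t]; Hprev <- st$H
  }
  out
}

# Exact probability of a full token sequence under the policy.
gru_seq_prob <- function(params, tokens) {
  fwd <- gru_forward(params, matrix(tokens, nrow = 1L))
  prod(vapply(seq_along(tokens), function(t)
    fwd$steps[[t]]$P[1L, tokens[t]], numeric(1)))
}
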