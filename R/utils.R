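# Shared numeric helpers. Everything here is internal.

DNA_BASES <- c("A", "C", "G", "T")

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(sigmoid(x)) without overflow for large |x|
log_sigmoid <- function(x) ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise softmax with max subtraction; x is a matrix, returns same shape.
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Deterministic child seed derived from a base seed and a stage tag.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# Sample one categorical index per row of a probability matrix.
# u is a vector of uniforms (length nrow) so callers control the RNG stream.
sample_rows <- function(prob, u) {
  cs <- prob %*% upper.tri(diag(ncol(prob)), diag = TRUE)
  1L + as.integer(rowSums(cs < u))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- flat parameter vector <-> named list of arrays (for finite differences)

flatten_params <- function(params) {
  unlist(lapply(params, as.numeric), use.names = FALSE)
}

unflatten_params <- function(theta, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    out[[nm]][] <- theta[pos + seq_len(n)]
    pos <- pos + n
  }
  out
}

# ---- Adam optimiser over a named list of arrays

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
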