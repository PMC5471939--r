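# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: explicit observation vectors and double loops only.

# Laplace smoothing by literally appending k pseudo-observations per outcome
# (bit present / bit absent) to each class and counting, then Bayes' rule by
# direct arithmetic.
oracle_bayes <- function(c_SP, c_SN, N_P, N_N, k) {
  stopifnot(k == round(k))
  p_post <- l <- numeric(length(c_SP))
  prior_P <- N_P / (N_P + N_N)
  prior_N <- N_N / (N_P + N_N)
  for (j in seq_along(c_SP)) {
    obs_P <- c(rep(1, c_SP[j]), rep(0, N_P - c_SP[j]), rep(1, k), rep(0, k))
    obs_N <- c(rep(1, c_SN[j]), rep(0, N_N - c_SN[j]), rep(1, k), rep(0, k))
    pSP <- sum(obs_P == 1) / length(obs_P)
    pSN <- sum(obs_N == 1) / length(obs_N)
    num <- pSP * prior_P
    p_post[j] <- num / (num + pSN * prior_N)
    l[j] <- log(p_post[j] / (1 - p_post[j])) / log(2)
  }
  list(post_P = p_post, L = l)
}

# Per-cell double-loop substructure counting.
oracle_counts <- function(X, labels) {
  c_SP <- c_SN <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    for (i in seq_len(nrow(X))) {
      if (X[i, j] == 1) {
        if (labels[i] == "positive") c_SP[j] <- c_SP[j] + 1
        if (labels[i] == "negative") c_SN[j] <- c_SN[j] + 1
      }
    }
  }
  list(c_SP = c_SP, c_SN = c_SN,
       N_P = sum(labels == "positive"), N_N = sum(labels == "negative"))
}

# Element-by-element Tanimoto on two vectors.
oracle_tanimoto <- function(a, b) {
  ab <- aa <- bb <- 0
  for (i in seq_along(a)) {
    ab <- ab + a[i] * b[i]
    aa <- aa + a[i]^2
    bb <- bb + b[i]^2
  }
  if (aa + bb - ab == 0) 0 else ab / (aa + bb - ab)
}

oracle_kernel <- function(X1, X2) {
  K <- matrix(0, nrow(X1), nrow(X2))
  for (i in seq_len(nrow(X1))) {
    for (j in seq_len(nrow(X2))) K[i, j] <- oracle_tanimoto(X1[i, ], X2[j, ])
  }
  K
}

# All positive-negative pairs; ties count one half.
oracle_auc <- function(scores, labels) {
  ps <- scores[labels == "positive"]
  ns <- scores[labels == "negative"]
  conc <- 0
  for (p in ps) {
    for (n in ns) conc <- conc + (p > n) + 0.5 * (p == n)
  }
  conc / (length(ps) * length(ns))
}

# Small labeled dataset with arbitrary binary entries.
tiny_dataset <- function(n = 12, n_bits = 8, seed = 42, p = 0.4) {
  set.seed(seed)
  X <- matrix(rbinom(n * n_bits, 1, p), n, n_bits)
  fp_dataset(sprintf("c%02d", seq_len(n)), X,
             rep(c("positive", "negative"), length.out = n),
             structure_key = sprintf("key%02d", seq_len(n)))
}

# Perfectly separable dataset: disjoint causal bits fire in exactly one class.
separable_dataset <- function(n_pos = 30, n_neg = 30, n_bits = 40, seed = 11) {
  sp <- synth_spec(n_pos = n_pos, n_neg = n_neg, n_bits = n_bits,
                   causal_bits = 0:4, p_causal_pos = 1, p_causal_neg = 0,
                   p_background = 0.2, seed = seed)
  synth_generate(sp)
}
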