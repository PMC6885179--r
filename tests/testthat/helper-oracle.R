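# Independent scalar-loop oracle for the LSTM recurrence and read-out.
# Deliberately written entry-by-entry with plain arithmetic — no matrix
# products, no shared code with the package internals — so it can serve as
# the reference the production paths are checked against.

oracle_sigmoid <- function(z) 1 / (1 + exp(-z))

# one step: params is an lstm_params; x scalar-indexed vectors throughout
oracle_step <- function(params, x, h_prev, C_prev) {
  H <- params$H; m <- params$m
  z <- c(h_prev, x)
  h <- numeric(H); C <- numeric(H)
  for (u in 1:H) {
    af <- params$b_f[u]; ai <- params$b_i[u]; ao <- params$b_o[u]; ac <- params$b_c[u]
    for (j in 1:(H + m)) {
      af <- af + params$w_f[u, j] * z[j]
      ai <- ai + params$w_i[u, j] * z[j]
      ao <- ao + params$w_o[u, j] * z[j]
      ac <- ac + params$w_c[u, j] * z[j]
    }
    f <- oracle_sigmoid(af); i <- oracle_sigmoid(ai); o <- oracle_sigmoid(ao)
    C[u] <- f * C_prev[u] + i * tanh(ac)
    h[u] <- o * tanh(C[u])
  }
  list(h = h, C = C)
}

oracle_forward <- function(params, V) {
  h <- numeric(params$H); C <- numeric(params$H)
  for (t in seq_len(ncol(V))) {
    st <- oracle_step(params, V[, t], h, C)
    h <- st$h; C <- st$C
  }
  a <- params$b_ho
  for (u in 1:params$H) a <- a + params$w_ho[u] * h[u]
  oracle_sigmoid(a)
}

# exhaustive pairwise-comparison oracle for AUROC (ties count half)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# random small parameter set with nonzero biases, for oracle comparisons
random_params <- function(H, m, seed) {
  p <- init_lstm_params(H, m, seed)
  set.seed(seed + 1000)
  for (nm in c("b_f", "b_i", "b_o", "b_c")) p[[nm]] <- rnorm(H, 0, 0.5)
  p$b_ho <- rnorm(1, 0, 0.5)
  p
}

# small separable cohort: positive-class patients drift upward on every
# variable; used for training smoke tests
separable_cohort <- function(n = 100, d = 4, tt = 6, seed = 1, drift = 1) {
  generate_cohort(synth_config(n_patients = n, D = d, T = tt,
                               imbalance_ratio = 1, n_informative = d,
                               effect_size = drift, missing_rate = 0,
                               seed = seed))
}

desk_benchmark_cohort <- function(seed = 11) {
  generate_cohort(synth_config(seed = seed))
}
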