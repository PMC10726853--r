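# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops, textbook formulas) and share no code
# with the package internals they check.

# Naive leave-one-as-singleton enumeration: for a pooled matrix (row 1 =
# the subject of interest), compute every relabeling's z by explicit
# mean/SD loops and the tie-inclusive p-value of row 1.
oracle_singleton_enumeration <- function(pooled) {
  n1 <- nrow(pooled)
  N <- ncol(pooled)
  z <- matrix(NA_real_, n1, N)
  for (i in seq_len(n1)) {
    for (k in seq_len(N)) {
      others <- pooled[-i, k]
      m <- sum(others) / length(others)
      s <- sqrt(sum((others - m)^2) / (length(others) - 1))
      if (s > 0) z[i, k] <- (pooled[i, k] - m) / s
    }
  }
  p <- rep(NA_real_, N)
  for (k in seq_len(N)) {
    if (!is.finite(z[1, k])) next
    cnt <- 0
    for (i in seq_len(n1)) if (!is.na(z[i, k]) && z[i, k] <= z[1, k])
      cnt <- cnt + 1
    p[k] <- cnt / n1
  }
  list(z = z, p = p)
}

# Crawford-Howell single-case t against a control sample, textbook form.
oracle_crawford_howell <- function(x0, controls) {
  n <- length(controls)
  m <- mean(controls)
  s <- sd(controls)
  t <- (x0 - m) / (s * sqrt(1 + 1 / n))
  list(t = t, df = n - 1, p = pt(t, df = n - 1))
}

# Random control vertex maps around a plausible thickness.
make_control_maps <- function(n, v, seed, mean = 2.4, sd = 0.15) {
  lapply(seq_len(n), function(i) {
    set.seed(seed + i)
    vertex_map(pmax(rnorm(v, mean, sd), 0.1), sprintf("hc%02d", i))
  })
}

# Patch profiles from plain numeric vectors.
profiles_from_matrix <- function(mat, prefix = "s") {
  lapply(seq_len(nrow(mat)), function(i)
    patch_profile(mat[i, ], subject_id = sprintf("%s%02d", prefix, i)))
}
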