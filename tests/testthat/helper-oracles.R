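# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations they check.

oracle_pssm_ac <- function(R, lg) {
  L <- nrow(R)
  out <- c()
  for (j in 1:20) {
    rbar <- sum(R[, j]) / L
    for (l in 1:lg) {
      s <- 0
      for (i in 1:(L - l)) s <- s + (R[i, j] - rbar) * (R[i + l, j] - rbar)
      out <- c(out, as.numeric(s) / (L - l))
    }
  }
  unname(out)
}

oracle_acacs_diff <- function(A, lambda) {
  L <- length(A)
  out <- numeric(lambda + 1)
  for (l in 0:lambda) {
    s <- 0
    for (k in 1:(L - l)) s <- s + (A[k] - A[k + l])
    out[l + 1] <- s / (L - l)
  }
  out
}

oracle_acacs_cov <- function(A, lambda) {
  L <- length(A)
  abar <- mean(A)
  out <- numeric(lambda + 1)
  for (l in 0:lambda) {
    s <- 0
    for (k in 1:(L - l)) s <- s + (A[k] - abar) * (A[k + l] - abar)
    out[l + 1] <- s / (L - l)
  }
  out
}

oracle_fscore <- function(xp, xn) {
  # xp, xn: numeric vectors of one feature's values in each class
  np <- length(xp); nn <- length(xn)
  xbar <- mean(c(xp, xn)); bp <- mean(xp); bn <- mean(xn)
  num <- (bp - xbar)^2 + (bn - xbar)^2
  den <- sum((xp - bp)^2) / (np - 1) + sum((xn - bn)^2) / (nn - 1)
  if (den == 0) { if (num > 0) Inf else 0 } else num / den
}

oracle_metrics <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  sn <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  sp <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / total
  f <- c(tp + fp, tn + fn, tp + fn, tn + fp)
  mcc <- if (any(f == 0)) 0 else
    (tp * tn - fp * fn) / sqrt(f[1]) / sqrt(f[2]) / sqrt(f[3]) / sqrt(f[4])
  list(sn = sn, sp = sp, acc = acc, mcc = mcc)
}

# random valid protein sequence
random_sequence <- function(L) paste(sample(AA_ALPHABET, L, replace = TRUE),
                                     collapse = "")

# small labeled record helper
rec <- function(seqs, id = "r1", label = "positive")
  protein_record(id, seqs, label)

# tiny separable 2-feature toy matrix: positives near (1,1), negatives (-1,-1)
toy_separable <- function(n_per = 5, eps = 0.1, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(matrix(c(1, 1), n_per, 2, byrow = TRUE) +
                 matrix(runif(2 * n_per, -eps, eps), n_per),
               matrix(c(-1, -1), n_per, 2, byrow = TRUE) +
                 matrix(runif(2 * n_per, -eps, eps), n_per))
  })
  colnames(x) <- c("f1", "f2")
  rownames(x) <- paste0("s", seq_len(2 * n_per))
  feature_matrix(x, rep(c("positive", "negative"), each = n_per))
}
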