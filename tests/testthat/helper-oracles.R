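# independent brute-force oracle for the stimulus-specific information of one
# cell: explicit joint (stimulus, response-bin) table and direct summation
oracle_cell_info <- function(r, n_bins) {
  n_s <- nrow(r)
  n_t <- ncol(r)
  rmax <- max(r)
  if (rmax <= 0) return(rep(0, n_s))
  joint <- matrix(0, n_s, n_bins) # P(s, b) with P(s) = 1/n_s, P(t|s) = 1/n_t
  for (s in seq_len(n_s)) {
    for (t in seq_len(n_t)) {
      b <- min(floor(r[s, t] / rmax * n_bins) + 1, n_bins)
      joint[s, b] <- joint[s, b] + (1 / n_s) * (1 / n_t)
    }
  }
  p_b <- colSums(joint)
  out <- numeric(n_s)
  for (s in seq_len(n_s)) {
    acc <- 0
    for (b in seq_len(n_bins)) {
      p_b_given_s <- joint[s, b] / (1 / n_s)
      if (p_b_given_s > 0) {
        acc <- acc + p_b_given_s * log2(p_b_given_s / p_b[b])
      }
    }
    out[s] <- acc
  }
  out
}

# explicit leave-one-transform-out Gaussian-Bayes argmax decoding with a
# fixed full ensemble: returns the normalized confusion table
oracle_confusion <- function(r, sd_floor) {
  n_cells <- dim(r)[1]
  n_s <- dim(r)[2]
  n_t <- dim(r)[3]
  conf <- matrix(0, n_s, n_s)
  for (s in seq_len(n_s)) {
    for (t in seq_len(n_t)) {
      logpost <- numeric(n_s)
      for (sp in seq_len(n_s)) {
        acc <- log(1 / n_s)
        for (cell in seq_len(n_cells)) {
          train <- if (sp == s) r[cell, sp, -t] else r[cell, sp, ]
          mu <- mean(train)
          sg <- max(sd(train), sd_floor)
          acc <- acc + dnorm(r[cell, s, t], mu, sg, log = TRUE)
        }
        logpost[sp] <- acc
      }
      pick <- which.max(logpost)
      conf[s, pick] <- conf[s, pick] + 1
    }
  }
  conf / sum(conf)
}

confusion_bits <- function(p) {
  acc <- 0
  for (s in seq_len(nrow(p))) for (sp in seq_len(ncol(p))) {
    if (p[s, sp] > 0) {
      acc <- acc + p[s, sp] * log2(p[s, sp] / (sum(p[s, ]) * sum(p[, sp])))
    }
  }
  acc
}
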