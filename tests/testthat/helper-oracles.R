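# Independent brute-force oracles, deliberately written from textbook
# definitions rather than reusing any package code path.

# Pearson correlation from the raw-score formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Midranks computed by explicit counting (no rank()).
oracle_midrank <- function(x) {
  vapply(seq_along(x), function(i) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    less + (ties + 1) / 2
  }, numeric(1))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# Kendall tau-a by exhaustive concordant/discordant pair counting.
oracle_tau_a <- function(x, y) {
  n <- length(x)
  conc <- 0L; disc <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1L
      if (s < 0) disc <- disc + 1L
    }
  }
  (conc - disc) / (n * (n - 1) / 2)
}

# A valid RDM filled with given upper-triangle values.
toy_rdm <- function(values, n, labels = paste0("c", seq_len(n))) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- values
  d <- d + t(d)
  dimnames(d) <- list(labels, labels)
  structure(list(dissim = d, conditions = labels, n_subjects = 1L),
            class = "rdm")
}

# A model RDM with arbitrary upper-triangle values (NA = unconstrained).
toy_model <- function(values, n, name = "toy",
                      labels = paste0("c", seq_len(n))) {
  d <- matrix(NA_real_, n, n)
  d[upper.tri(d)] <- values
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  dimnames(d) <- list(labels, labels)
  structure(list(name = name, dissim = d), class = "model_rdm")
}

random_pattern <- function(n_voxels, n_cond, labels = paste0("c", seq_len(n_cond))) {
  pattern_matrix(matrix(rnorm(n_voxels * n_cond), n_voxels, n_cond),
                 conditions = labels)
}
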