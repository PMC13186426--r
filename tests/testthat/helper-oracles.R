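# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths: direct summation, exhaustive
# enumeration, and numeric quadrature.

# Observed likelihood by direct per-row summation over components.
oracle_observed_loglik <- function(X, pi, theta) {
  n <- nrow(X)
  total <- 0
  for (i in seq_len(n)) {
    row_prob <- 0
    for (k in seq_along(pi)) {
      term <- pi[k]
      for (j in seq_len(ncol(X)))
        term <- term * (if (X[i, j] == 1) theta[j, k] else 1 - theta[j, k])
      row_prob <- row_prob + term
    }
    total <- total + log(row_prob)
  }
  total
}

# Collapsed joint p(X, z | K) by numeric quadrature over each component's
# theta (per variable) and the analytic Dirichlet-multinomial for pi.
oracle_collapsed_joint <- function(X, z, K, prior) {
  n <- nrow(X); p <- ncol(X)
  g <- prior$gamma; a <- prior$alpha; b <- prior$beta
  out <- lgamma(K * g) - lgamma(K * g + n)
  for (k in seq_len(K)) {
    nk <- sum(z == k)
    out <- out + lgamma(nk + g) - lgamma(g)
    for (j in seq_len(p)) {
      s <- if (nk > 0) sum(X[z == k, j]) else 0
      f <- function(th) th^s * (1 - th)^(nk - s) * stats::dbeta(th, a, b)
      out <- out + log(stats::integrate(f, 0, 1, rel.tol = 1e-12)$value)
    }
  }
  out
}

# Marginal p(X | K): exhaustive sum of the quadrature oracle over all z.
oracle_marginal_given_k <- function(X, K, prior) {
  n <- nrow(X)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  vals <- apply(grid, 1, function(z)
    oracle_collapsed_joint(X, as.integer(z), K, prior))
  m <- max(vals)
  m + log(sum(exp(vals - m)))
}

# Monte Carlo standard error of a proportion from a correlated trace,
# by non-overlapping batch means.
batch_se <- function(ind, n_batches = 50) {
  n <- length(ind)
  m <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(ind[((b - 1) * m + 1):(b * m)]),
                  numeric(1))
  stats::sd(means) / sqrt(n_batches)
}

# Small deterministic binary fixtures for the sampler exactness tests.
sampler_fixtures <- function() {
  list(
    m4a = matrix(c(1, 0, 0, 1,
                   0, 1, 0, 1), nrow = 4),
    m4b = matrix(c(1, 1, 0, 0,
                   1, 1, 0, 0), nrow = 4),
    m5a = matrix(c(1, 1, 0, 0, 1,
                   0, 1, 1, 0, 0), nrow = 5)
  )
}
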