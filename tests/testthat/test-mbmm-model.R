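# Likelihoods, conjugate marginalizations, and full conditionals of the
# Bernoulli mixture.

test_that("observed likelihood matches closed forms and the summation oracle", {
  # fair-coin single component: every cell contributes -log 2
  X <- matrix(rbinom(6 * 3, 1, 0.5), nrow = 6)
  params <- mixture_params(1, matrix(0.5, 3, 1))
  expect_equal(log_observed_likelihood(X, params), -6 * 3 * log(2))

  # certain outcome has log probability 0
  X1 <- matrix(1L, 4, 2)
  params1 <- mixture_params(c(0.3, 0.7), matrix(1, 2, 2))
  expect_equal(log_observed_likelihood(X1, params1), 0)

  # 2x2 instance against direct summation
  X2 <- matrix(c(1, 0, 0, 1), nrow = 2)
  theta <- cbind(c(0.9, 0.9), c(0.1, 0.1))
  params2 <- mixture_params(c(0.5, 0.5), theta)
  expect_equal(log_observed_likelihood(X2, params2),
               oracle_observed_loglik(X2, c(0.5, 0.5), theta))

  # random instances against the oracle
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2:6, 1); p <- sample(1:3, 1); K <- sample(1:3, 1)
    X <- matrix(rbinom(n * p, 1, 0.5), n, p)
    pi <- as.vector(stats::rgamma(K, 1)); pi <- pi / sum(pi)
    th <- matrix(runif(p * K), p, K)
    expect_equal(log_observed_likelihood(X, mixture_params(pi, th)),
                 oracle_observed_loglik(X, pi, th))
  }
})

test_that("complete likelihood reduces to the observed one at K = 1 and sums to it", {
  set.seed(7)
  X <- matrix(rbinom(5 * 2, 1, 0.4), 5, 2)
  params <- mixture_params(1, matrix(runif(2), 2, 1))
  expect_equal(log_complete_likelihood(X, rep(1, 5), params),
               log_observed_likelihood(X, params))

  # log-sum-exp of the complete likelihood over all K^n allocations
  # equals the observed likelihood (3 x 2 instance, K = 2)
  X3 <- matrix(c(1, 0, 1, 0, 1, 1), nrow = 3)
  params3 <- mixture_params(c(0.4, 0.6), cbind(c(0.8, 0.3), c(0.2, 0.7)))
  grid <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  lc <- apply(grid, 1, function(z) log_complete_likelihood(X3, z, params3))
  expect_equal(max(lc) + log(sum(exp(lc - max(lc)))),
               log_observed_likelihood(X3, params3))

  # deterministic emissions: theta in {0,1} reproducing X exactly
  X4 <- matrix(c(1, 0, 0, 1), nrow = 2)
  params4 <- mixture_params(c(0.5, 0.5), cbind(c(1, 0), c(0, 1)))
  expect_equal(log_complete_likelihood(X4, c(1, 2), params4), 2 * log(1 / 2))
})

test_that("collapsed joint matches the trivial value and the quadrature oracle", {
  prior <- mixture_prior()
  # n = 1, p = 1: B(1 + x, 2 - x)/B(1, 1) = 1/2 either way
  for (x in 0:1) {
    X <- matrix(as.integer(x), 1, 1)
    st <- allocation_state(1L, X, 1)
    expect_equal(log_collapsed_joint(X, st, 1, prior), log(1 / 2))
  }

  # 2 x 1 instance vs quadrature, several priors
  X <- matrix(c(1L, 0L), 2, 1)
  for (pr in list(mixture_prior(), mixture_prior(alpha = 2, beta = 3, gamma = 0.5))) {
    for (K in 1:2) {
      grid <- as.matrix(expand.grid(rep(list(seq_len(K)), 2)))
      for (r in seq_len(nrow(grid))) {
        z <- as.integer(grid[r, ])
        st <- allocation_state(z, X, K)
        expect_equal(log_collapsed_joint(X, st, K, pr),
                     oracle_collapsed_joint(X, z, K, pr), tolerance = 1e-6)
      }
    }
  }
})

test_that("summing the collapsed joint over allocations gives the quadrature marginal", {
  X <- matrix(c(1, 0, 1, 0, 0, 1, 1, 1), nrow = 4)  # 4 x 2
  prior <- mixture_prior()
  K <- 2
  grid <- as.matrix(expand.grid(rep(list(1:K), 4)))
  vals <- apply(grid, 1, function(z) {
    st <- allocation_state(as.integer(z), X, K)
    log_collapsed_joint(NULL, st, K, prior)
  })
  lhs <- max(vals) + log(sum(exp(vals - max(vals))))
  expect_equal(lhs, oracle_marginal_given_k(X, K, prior), tolerance = 1e-6)
})

test_that("collapsed joint is label-permutation invariant and add/remove exact", {
  set.seed(11)
  X <- matrix(rbinom(6 * 2, 1, 0.5), 6, 2)
  prior <- mixture_prior(alpha = 1.5, beta = 0.7, gamma = 2)
  z <- c(1L, 2L, 3L, 1L, 2L, 1L)
  base <- log_collapsed_joint(X, allocation_state(z, X, 3), 3, prior)
  for (perm in list(c(2L, 3L, 1L), c(3L, 2L, 1L), c(1L, 3L, 2L))) {
    zp <- perm[z]
    expect_equal(log_collapsed_joint(X, allocation_state(zp, X, 3), 3, prior),
                 base)
  }

  # appending a row and then computing on the restored state is exact
  X7 <- rbind(X, c(1L, 0L))
  z7 <- c(z, 2L)
  st7 <- allocation_state(z7, X7, 3)
  st_back <- allocation_state(st7$z[1:6], X7[1:6, , drop = FALSE], 3)
  expect_identical(st_back$n_k, allocation_state(z, X, 3)$n_k)
  expect_equal(log_collapsed_joint(NULL, st_back, 3, prior), base)
})

test_that("strong Beta priors concentrate the collapsed joint on the fixed-theta likelihood", {
  # alpha = beta -> infinity with mean fixed at 0.5 pins theta at 0.5
  set.seed(3)
  X <- matrix(rbinom(5 * 2, 1, 0.5), 5, 2)
  z <- rep(1L, 5)
  big <- 1e6
  prior <- mixture_prior(alpha = big, beta = big, gamma = 1)
  st <- allocation_state(z, X, 1)
  fixed <- log_complete_likelihood(X, z, mixture_params(1, matrix(0.5, 2, 1)))
  got <- log_collapsed_joint(NULL, st, 1, prior)
  expect_equal(got, fixed, tolerance = 1e-3)
})

test_that("Gibbs full conditionals equal ratios of collapsed joints", {
  set.seed(5)
  prior <- mixture_prior(alpha = 0.8, beta = 1.4, gamma = 1.2)
  X <- matrix(rbinom(5 * 2, 1, 0.5), 5, 2)
  K <- 3
  z <- sample.int(K, 5, TRUE)
  st <- allocation_state(z, X, K)
  for (i in 1:5) {
    got <- gibbs_full_conditional(i, st, X, K, prior)
    expect_equal(sum(got), 1)
    # oracle: collapsed joint with z_i set to each k, renormalized
    lj <- vapply(seq_len(K), function(k) {
      zk <- z; zk[i] <- k
      log_collapsed_joint(NULL, allocation_state(zk, X, K), K, prior)
    }, numeric(1))
    want <- exp(lj - max(lj)); want <- want / sum(want)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("Gibbs conditional symmetry and empty-component prior-predictive weight", {
  # two components whose leave-one-out statistics are identical ({1,0} each)
  # give the resampled row probabilities (1/2, 1/2)
  X2 <- matrix(c(1L, 1L, 0L, 1L, 0L), 5, 1)
  st2 <- allocation_state(c(1L, 1L, 1L, 2L, 2L), X2, 2)
  w <- gibbs_full_conditional(1, st2, X2, 2, mixture_prior())
  expect_equal(w, c(0.5, 0.5))

  # empty component, gamma = alpha = beta = 1, p = 1: weight proportional
  # to 1 * 1 / 2 regardless of x
  X3 <- matrix(c(1L, 1L), 2, 1)
  st3 <- allocation_state(c(1L, 1L), X3, 2)
  w3 <- gibbs_full_conditional(1, st3, X3, 2, mixture_prior())
  # occupied component (after removal: n=1, s=1): (1+1) * (1+1)/(2+1) / ...
  lw_occ <- log(2) + log(2 / 3)
  lw_emp <- log(1) + log(1 / 2)
  want <- exp(c(lw_occ, lw_emp)); want <- want / sum(want)
  expect_equal(w3, want)
})

test_that("invalid parameters and inconsistent states are rejected", {
  expect_error(mixture_params(c(0.5, 0.6), matrix(0.5, 2, 2)), "sum to 1")
  expect_error(mixture_params(1, matrix(1.5, 2, 1)), "\\[0, 1\\]")
  expect_error(mixture_prior(lambda_k = 0), "lambda_k")
  X <- matrix(c(1L, 0L), 2, 1)
  st <- allocation_state(c(1L, 1L), X, 2)
  st$n_k <- c(0L, 2L)
  expect_error(log_collapsed_joint(X, st, 2, mixture_prior()), "inconsistent")
})
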