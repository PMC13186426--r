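# Multivariate Bernoulli mixture model: likelihoods, conjugate priors, and the
# collapsed (marginalized) quantities the allocation sampler evaluates.

#' Prior specification for the Bernoulli mixture
#'
#' The model places a truncated Poisson prior on the number of mixture
#' components \eqn{K}, a symmetric Dirichlet prior on the component weights
#' \eqn{\pi}, and independent Beta priors on every Bernoulli success
#' probability \eqn{\theta_{j|k}}. The defaults (\eqn{\lambda = 1},
#' \eqn{K_{max} = 50}, \eqn{\gamma = 1}, \eqn{\alpha = \beta = 1}) favour
#' parsimony in the number of nonempty components while remaining uniform over
#' weights and exposure probabilities.
#'
#' @param lambda_k Rate of the truncated Poisson prior on K. Must be positive.
#' @param k_max Upper bound on the number of components (truncation point).
#' @param gamma Symmetric Dirichlet concentration for the mixture weights.
#' @param alpha,beta Beta shape parameters shared by all success probabilities.
#' @return An object of class `mixture_prior`.
#' @export
mixture_prior <- function(lambda_k = 1, k_max = 50, gamma = 1,
                          alpha = 1, beta = 1) {
  stopifnot(is.numeric(lambda_k), length(lambda_k) == 1L, lambda_k > 0,
            is.numeric(k_max), length(k_max) == 1L, k_max >= 1,
            k_max == as.integer(k_max),
            is.numeric(gamma), gamma > 0,
            is.numeric(alpha), alpha > 0,
            is.numeric(beta), beta > 0)
  structure(
    list(lambda_k = as.numeric(lambda_k), k_max = as.integer(k_max),
         gamma = as.numeric(gamma), alpha = as.numeric(alpha),
         beta = as.numeric(beta)),
    class = "mixture_prior"
  )
}

#' Mixture parameter bundle
#'
#' @param pi Length-K probability vector of component weights.
#' @param theta p x K matrix; `theta[j, k]` is the probability that indicator
#'   j is 1 (high exposure) under component k.
#' @return An object of class `mixture_params`.
#' @export
mixture_params <- function(pi, theta) {
  pi <- as.numeric(pi)
  theta <- as.matrix(theta)
  if (abs(sum(pi) - 1) > 1e-12)
    stop("mixture weights `pi` must sum to 1 (within 1e-12)")
  if (any(pi < 0)) stop("mixture weights must be non-negative")
  if (ncol(theta) != length(pi))
    stop("`theta` must have one column per mixture component")
  if (any(theta < 0 | theta > 1))
    stop("all entries of `theta` must lie in [0, 1]")
  structure(list(K = length(pi), pi = pi, theta = theta),
            class = "mixture_params")
}

#' Allocation state: labels plus sufficient statistics
#'
#' Holds the component label of every row together with the per-component
#' counts the collapsed sampler needs: `n_k` (rows per component) and
#' `s_jk` (per-component count of ones for each indicator). All collapsed
#' quantities are functions of these statistics alone.
#'
#' @param z Integer vector of component labels in 1..K.
#' @param X Binary matrix (n x p) the labels refer to.
#' @param K Number of labelled components (empty components allowed).
#' @return An object of class `allocation_state` with fields `z`, `n_k`
#'   (length K), `s_jk` (p x K), and `occupied` (labels with `n_k > 0`).
#' @export
allocation_state <- function(z, X, K = max(z)) {
  X <- as.matrix(X)
  z <- as.integer(z)
  if (length(z) != nrow(X)) stop("`z` must have one label per row of `X`")
  if (any(z < 1L) || any(z > K)) stop("labels in `z` must lie in 1..K")
  if (any(X != 0 & X != 1)) stop("`X` must be a 0/1 matrix")
  n_k <- tabulate(z, nbins = K)
  s_jk <- matrix(0, nrow = ncol(X), ncol = K)
  for (k in seq_len(K)) {
    if (n_k[k] > 0L) s_jk[, k] <- colSums(X[z == k, , drop = FALSE])
  }
  structure(list(z = z, n_k = n_k, s_jk = s_jk,
                 occupied = which(n_k > 0L)),
            class = "allocation_state")
}

check_state_consistency <- function(state, X, K) {
  n_k <- tabulate(state$z, nbins = K)
  if (!identical(as.integer(n_k), as.integer(state$n_k)))
    stop("allocation state is inconsistent: `n_k` does not match `z`")
  fresh <- allocation_state(state$z, X, K)
  if (max(abs(fresh$s_jk - state$s_jk)) > 0)
    stop("allocation state is inconsistent: `s_jk` does not match `z` and `X`")
  invisible(TRUE)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Observed-data log likelihood of the Bernoulli mixture
#'
#' Computes \eqn{\sum_i \log \sum_k \pi_k \prod_j \theta_{j|k}^{x_{ij}}
#' (1-\theta_{j|k})^{1-x_{ij}}} in log space with a stable log-sum-exp. A row
#' with probability zero under every component yields `-Inf` rather than an
#' error, so Metropolis ratios evaluate rejections naturally.
#'
#' @param X Binary n x p matrix.
#' @param params A `mixture_params` object.
#' @return The log likelihood (scalar, possibly `-Inf`).
#' @export
log_observed_likelihood <- function(X, params) {
  stopifnot(inherits(params, "mixture_params"))
  X <- as.matrix(X)
  if (ncol(X) != nrow(params$theta))
    stop("`X` and `theta` disagree on the number of indicators")
  if (any(X != 0 & X != 1)) stop("`X` must be a 0/1 matrix")
  # n x K matrix of per-row per-component log emission probabilities
  lth1 <- log(params$theta)          # p x K, may contain -Inf
  lth0 <- log1p(-params$theta)
  ll_rows <- vapply(seq_len(nrow(X)), function(i) {
    sel <- X[i, ] == 1
    # select rather than multiply: 0 * -Inf from an unused impossible
    # emission must not poison the sum
    lw <- log(params$pi) + colSums(lth1[sel, , drop = FALSE]) +
      colSums(lth0[!sel, , drop = FALSE])
    logsumexp(lw)
  }, numeric(1))
  sum(ll_rows)
}

#' Complete-data log likelihood given allocations
#'
#' @param X Binary n x p matrix.
#' @param z Integer labels in 1..K.
#' @param params A `mixture_params` object.
#' @return \eqn{\sum_i [\log \pi_{z_i} + \sum_j \log \theta^{x}(1-\theta)^{1-x}]}.
#' @export
log_complete_likelihood <- function(X, z, params) {
  stopifnot(inherits(params, "mixture_params"))
  X <- as.matrix(X)
  z <- as.integer(z)
  if (any(z < 1L | z > params$K)) stop("labels in `z` must lie in 1..K")
  if (length(z) != nrow(X)) stop("`z` must have one label per row of `X`")
  total <- 0
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    th <- params$theta[, z[i]]
    term <- log(params$pi[z[i]]) +
      sum(ifelse(x == 1, log(th), log1p(-th)))
    if (is.nan(term)) term <- -Inf
    total <- total + term
  }
  total
}

#' Collapsed joint log probability of data and allocations
#'
#' Marginalizes the mixture weights (Dirichlet-multinomial) and every
#' Bernoulli success probability (Beta-binomial) analytically:
#' \deqn{\log p(X, z \mid K) = \log\frac{\Gamma(K\gamma)}{\Gamma(K\gamma+n)}
#'   + \sum_k \log\frac{\Gamma(n_k+\gamma)}{\Gamma(\gamma)}
#'   + \sum_{k,j} \log\frac{B(\alpha+s_{jk}, \beta+n_k-s_{jk})}{B(\alpha,\beta)}.}
#' Empty components contribute nothing, as their terms cancel.
#'
#' @param X Binary matrix (used only to validate the sufficient statistics;
#'   pass `NULL` to trust `state`).
#' @param state An `allocation_state`.
#' @param K Number of labelled components.
#' @param prior A `mixture_prior`.
#' @return Scalar log probability.
#' @export
log_collapsed_joint <- function(X, state, K, prior) {
  stopifnot(inherits(prior, "mixture_prior"))
  if (!is.null(X)) check_state_consistency(state, X, K)
  g <- prior$gamma; a <- prior$alpha; b <- prior$beta
  n <- length(state$z)
  out <- lgamma(K * g) - lgamma(K * g + n)
  for (k in seq_len(K)) {
    nk <- state$n_k[k]
    if (nk == 0L) next
    out <- out + lgamma(nk + g) - lgamma(g)
    s <- state$s_jk[, k]
    out <- out + sum(lbeta(a + s, b + nk - s) - lbeta(a, b))
  }
  out
}

#' Truncated Poisson log prior on the number of components
#'
#' @param K Component count (vectorized).
#' @param prior A `mixture_prior`; uses `lambda_k` and `k_max`.
#' @return Log prior mass, `-Inf` outside 1..k_max.
#' @export
log_k_prior <- function(K, prior) {
  ks <- seq_len(prior$k_max)
  log_norm <- logsumexp(ks * log(prior$lambda_k) - lgamma(ks + 1))
  out <- ifelse(K >= 1 & K <= prior$k_max,
                K * log(prior$lambda_k) - lgamma(K + 1) - log_norm,
                -Inf)
  out
}

#' Full conditional of one allocation under the collapsed model
#'
#' Returns \eqn{p(z_i = k \mid z_{-i}, X, K)} for k = 1..K, proportional to
#' \eqn{(n_k^{-i}+\gamma) \prod_j (\alpha+s_{jk}^{-i})^{x_{ij}}
#' (\beta+n_k^{-i}-s_{jk}^{-i})^{1-x_{ij}} / (\alpha+\beta+n_k^{-i})}.
#'
#' @param i Row index whose allocation is resampled.
#' @param state An `allocation_state` consistent with `X`.
#' @param X Binary n x p matrix.
#' @param K Number of labelled components.
#' @param prior A `mixture_prior`.
#' @return Length-K probability vector summing to 1.
#' @export
gibbs_full_conditional <- function(i, state, X, K, prior) {
  stopifnot(inherits(prior, "mixture_prior"))
  X <- as.matrix(X)
  x <- X[i, ]
  zi <- state$z[i]
  n_k <- state$n_k
  s_jk <- state$s_jk
  # leave-one-out statistics
  n_k[zi] <- n_k[zi] - 1L
  s_jk[, zi] <- s_jk[, zi] - x
  a <- prior$alpha; b <- prior$beta; g <- prior$gamma
  lw <- vapply(seq_len(K), function(k) {
    log(n_k[k] + g) +
      sum(x * log(a + s_jk[, k]) + (1 - x) * log(b + n_k[k] - s_jk[, k])) -
      length(x) * log(a + b + n_k[k])
  }, numeric(1))
  w <- exp(lw - logsumexp(lw))
  w / sum(w)
}
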