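# Metropolis-coupled collapsed allocation sampler: R-facing configuration and
# driver around the compiled core.

#' Chain configuration for the MC3 allocation sampler
#'
#' @param n_chains Number of tempered chains (the first is the cold chain).
#' @param temperatures Decreasing ladder in (0, 1] starting at 1. The default
#'   is \eqn{t_c = 1/(1 + 0.3 (c - 1))}, mild heating adequate for a few dozen
#'   binary indicators.
#' @param n_iter Post-burn-in sweeps.
#' @param burn_in Discarded initial sweeps.
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param swap_attempts_per_sweep Adjacent-pair state-swap attempts per sweep.
#' @param move_mix Probabilities of (full Gibbs pass, Metropolis block
#'   reallocation, eject, absorb) per sweep; must sum to 1.
#' @param eject_alpha Shape of the symmetric Beta proposal for the ejection
#'   reallocation probability (1 = uniform).
#' @param k_init Number of components the allocation is initialized over
#'   (capped at `k_max`).
#' @param seed Integer seed; all randomness in `run_mc3()` flows from it.
#' @param verbose Print progress every 1,000 sweeps.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_chains = 4,
                         temperatures = 1 / (1 + 0.3 * (seq_len(n_chains) - 1)),
                         n_iter = 10000, burn_in = 1000, thin = 10,
                         swap_attempts_per_sweep = 1,
                         move_mix = c(0.70, 0.10, 0.10, 0.10),
                         eject_alpha = 1, k_init = 20, seed = 1,
                         verbose = FALSE) {
  if (n_chains < 1) stop("`n_chains` must be at least 1")
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) != n_chains)
    stop("`temperatures` must have one entry per chain")
  if (abs(temperatures[1] - 1) > 1e-12)
    stop("the first (cold) temperature must be exactly 1")
  if (any(temperatures <= 0 | temperatures > 1))
    stop("temperatures must lie in (0, 1]")
  if (any(diff(temperatures) > 0))
    stop("temperatures must be non-increasing")
  if (length(move_mix) != 4 || abs(sum(move_mix) - 1) > 1e-12 ||
      any(move_mix < 0))
    stop("`move_mix` must be 4 non-negative probabilities summing to 1")
  if (n_iter < 0 || burn_in < 0) stop("`n_iter` and `burn_in` must be >= 0")
  if (thin < 1) stop("`thin` must be >= 1")
  structure(
    list(n_chains = as.integer(n_chains), temperatures = temperatures,
         n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
         thin = as.integer(thin),
         swap_attempts_per_sweep = as.integer(swap_attempts_per_sweep),
         move_mix = as.numeric(move_mix), eject_alpha = as.numeric(eject_alpha),
         k_init = as.integer(k_init), seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "chain_config"
  )
}

#' Posterior sampling of allocations and the number of profiles
#'
#' Draws from the posterior over (K, z) of the multivariate Bernoulli mixture
#' with weights and success probabilities integrated out. The cold chain
#' targets \eqn{p(z, K \mid X) \propto p(X, z \mid K) p(K)} with the
#' truncated Poisson prior on K; heated chains target the same density raised
#' to their temperature, and adjacent chains exchange states by the standard
#' Metropolis-coupled swap. Only cold-chain draws are retained.
#'
#' @param X Binary design matrix: an n x p 0/1 matrix, or a
#'   `binary_design_matrix` object.
#' @param prior A `mixture_prior`.
#' @param config A `chain_config`.
#' @return An object of class `posterior_samples`: `z_draws` (draws x n
#'   integer matrix of allocations), `k_trace` (nonempty components per
#'   draw), `logpost_trace` (collapsed log joint plus log prior on K),
#'   `acceptance_report`, `final_state`, and the `prior` and `config` used.
#' @export
run_mc3 <- function(X, prior = mixture_prior(), config = chain_config()) {
  stopifnot(inherits(prior, "mixture_prior"), inherits(config, "chain_config"))
  Xm <- design_values(X)
  if (nrow(Xm) < 1) stop("`X` must have at least one row")
  set.seed(config$seed)
  res <- run_mc3_cpp(Xm, prior$lambda_k, prior$k_max, prior$gamma,
                     prior$alpha, prior$beta, config$temperatures,
                     config$n_iter, config$burn_in, config$thin,
                     config$swap_attempts_per_sweep, config$move_mix,
                     config$eject_alpha, min(config$k_init, prior$k_max),
                     config$verbose)
  acc <- res$acceptance
  rate <- function(v) if (v[["attempted"]] > 0) v[["accepted"]] / v[["attempted"]] else NA_real_
  report <- list(
    gibbs_passes = acc$gibbs_passes,
    block = c(acc$block, rate = rate(acc$block)),
    eject = c(acc$eject, rate = rate(acc$eject)),
    absorb = c(acc$absorb, rate = rate(acc$absorb)),
    swap = c(acc$swap, rate = rate(acc$swap))
  )
  structure(
    list(z_draws = res$z_draws, k_trace = as.integer(res$k_trace),
         logpost_trace = as.numeric(res$logpost_trace),
         acceptance_report = report, final_state = res$final_state,
         prior = prior, config = config, n = nrow(Xm), p = ncol(Xm)),
    class = "posterior_samples"
  )
}

#' @export
print.posterior_samples <- function(x, ...) {
  tab <- table(x$k_trace)
  cat("Posterior allocation samples:", length(x$k_trace), "retained draws,",
      x$n, "rows x", x$p, "indicators\n")
  cat("Nonempty-component counts:\n")
  print(tab)
  invisible(x)
}

#' Exhaustive posterior over allocations and K for tiny instances
#'
#' Independent enumeration oracle: sums the collapsed joint times the
#' truncated Poisson prior over every labelled state (K, z) with
#' \eqn{z \in \{1..K\}^n}, K = 1..k_max. Intended for validating the sampler
#' on instances with a handful of rows; the state count is
#' \eqn{\sum_K K^n}.
#'
#' @param X Binary n x p matrix (small n).
#' @param prior A `mixture_prior` (small `k_max`).
#' @return A list with `k_posterior` (named probability vector over nonempty
#'   component counts) and `partition_posterior` (named vector over canonical
#'   partition signatures).
#' @export
enumerate_k_posterior <- function(X, prior) {
  Xm <- design_values(X)
  n <- nrow(Xm)
  if (n > 8) stop("enumeration is intended for n <= 8")
  k_mass <- numeric(prior$k_max)          # by nonempty count
  part_mass <- new.env(parent = emptyenv())
  for (K in seq_len(prior$k_max)) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
    lp_k <- log_k_prior(K, prior)
    for (r in seq_len(nrow(grid))) {
      z <- as.integer(grid[r, ])
      st <- allocation_state(z, Xm, K)
      lw <- log_collapsed_joint(NULL, st, K, prior) + lp_k
      w <- exp(lw)
      k0 <- length(st$occupied)
      k_mass[k0] <- k_mass[k0] + w
      sig <- partition_signature(z)
      part_mass[[sig]] <- (if (is.null(part_mass[[sig]])) 0 else part_mass[[sig]]) + w
    }
  }
  total <- sum(k_mass)
  parts <- unlist(as.list(part_mass))
  list(k_posterior = k_mass / total,
       partition_posterior = sort(parts / total, decreasing = TRUE))
}

#' Canonical signature of a set partition induced by labels
#'
#' Labels renumbered by first appearance, so the signature is invariant to
#' label permutations.
#'
#' @param z Integer label vector.
#' @return A single string, e.g. `"1-1-2-1"`.
#' @export
partition_signature <- function(z) {
  z <- as.integer(z)
  canon <- match(z, unique(z))
  paste(canon, collapse = "-")
}
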