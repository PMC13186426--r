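# Post-processing of allocation draws: MAP number of profiles, ECR
# label-switching correction, conditional posterior summaries, and hard
# profile assignment.

#' Exact minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the square assignment problem exactly in O(n^3) by shortest
#' augmenting paths with potentials. Used by the ECR relabeler, where the
#' cost matrix is the (negated) label co-occurrence count between a draw and
#' the pivot.
#'
#' @param cost Square numeric cost matrix.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`,
#'   minimizing `sum(cost[cbind(seq_len(n), a)])`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) stop("`cost` must be square")
  if (n == 1L) return(1L)
  # columns indexed 1..n+1 where 1 is a virtual column; rows 1..n
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq.int(2L, n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j] + 1L] <- u[p[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  out <- integer(n)
  for (j in seq.int(2L, n + 1L)) out[p[j]] <- j - 1L
  out
}

#' Maximum a posteriori number of nonempty profiles
#'
#' The modal value of the nonempty-component trace; ties break toward the
#' smaller count.
#'
#' @param samples A `posterior_samples` object (or an integer trace).
#' @return Integer K_map.
#' @export
select_kmap <- function(samples) {
  k_trace <- if (inherits(samples, "posterior_samples")) samples$k_trace
             else as.integer(samples)
  if (length(k_trace) == 0) stop("the nonempty-component trace is empty")
  tab <- table(k_trace)
  ks <- as.integer(names(tab))
  ks[which(tab == max(tab))][1]  # names(table) sorted ascending: tie -> smaller
}

canonical_labels <- function(z) {
  # map the sorted set of occupied labels to 1..K0
  lev <- sort(unique(z))
  match(z, lev)
}

#' ECR relabeling of allocation draws against a pivot
#'
#' For each retained draw with exactly `k_map` nonempty components, finds the
#' label permutation minimizing the number of positions that disagree with
#' the pivot allocation — equivalently, maximizing the label co-occurrence
#' count — by solving the k_map x k_map assignment problem exactly, and
#' applies it. Draws with a different number of nonempty components are
#' excluded (their count is reported).
#'
#' @param z_draws Draws x n integer matrix of allocations.
#' @param pivot Allocation vector with exactly `k_map` nonempty labels.
#'   Defaults to `NULL`, in which case the caller must pass labels already
#'   restricted; see [run_ecr()] for the pipeline entry point.
#' @param k_map Number of profiles conditioned on.
#' @return A list: `z_relab` (kept draws, relabeled), `permutations` (kept
#'   draws x k_map; row `d` maps draw label b to `permutations[d, b]`),
#'   `kept` (row indices into `z_draws`), `n_excluded`.
#' @export
ecr_relabel <- function(z_draws, pivot, k_map = length(unique(pivot))) {
  z_draws <- as.matrix(z_draws)
  pivot <- canonical_labels(as.integer(pivot))
  if (length(unique(pivot)) != k_map)
    stop("`pivot` must have exactly `k_map` nonempty labels")
  if (ncol(z_draws) != length(pivot))
    stop("`z_draws` and `pivot` disagree on the number of rows allocated")
  counts <- apply(z_draws, 1, function(z) length(unique(z)))
  kept <- which(counts == k_map)
  n_excluded <- nrow(z_draws) - length(kept)
  if (n_excluded > 0)
    message(sprintf("ECR: excluding %d draw(s) without exactly %d nonempty components",
                    n_excluded, k_map))
  if (length(kept) == 0)
    stop("no draws with exactly `k_map` nonempty components")
  z_relab <- matrix(0L, nrow = length(kept), ncol = ncol(z_draws))
  perms <- matrix(0L, nrow = length(kept), ncol = k_map)
  for (d in seq_along(kept)) {
    z <- canonical_labels(z_draws[kept[d], ])
    # agreement[a, b] = #\{i : pivot_i = a, z_i = b\}
    agree <- matrix(0L, k_map, k_map)
    for (i in seq_along(z)) agree[pivot[i], z[i]] <- agree[pivot[i], z[i]] + 1L
    # assign draw-label b (columns) to pivot-label a (rows), maximizing
    # agreement: minimize -agreement with rows = draw labels
    a <- solve_assignment(-t(agree))
    perms[d, ] <- a            # draw label b -> pivot label a[b]
    z_relab[d, ] <- a[z]
  }
  list(z_relab = z_relab, permutations = perms, kept = kept,
       n_excluded = n_excluded, pivot = pivot, k_map = as.integer(k_map))
}

#' Pivot selection: highest-posterior retained draw at K_map
#'
#' @param samples A `posterior_samples` object.
#' @param k_map Number of nonempty components to condition on.
#' @return Allocation vector of the chosen draw.
#' @export
pick_pivot <- function(samples, k_map = select_kmap(samples)) {
  stopifnot(inherits(samples, "posterior_samples"))
  idx <- which(samples$k_trace == k_map)
  if (length(idx) == 0)
    stop("no retained draws have exactly `k_map` nonempty components")
  best <- idx[which.max(samples$logpost_trace[idx])]
  samples$z_draws[best, ]
}

#' Conditional posterior summaries of the profiles
#'
#' Given relabeled draws, computes Rao-Blackwellized posterior means of the
#' exposure probabilities, \eqn{E[\theta_{j|k} \mid z] = (\alpha + s_{jk}) /
#' (\alpha + \beta + n_k)} averaged over draws, the matching weight means
#' \eqn{(n_k + \gamma)/(n + K\gamma)}, per-tract membership probabilities
#' (label frequencies across draws), and equal-tailed 95% intervals for each
#' \eqn{\theta_{j|k}} from one Beta draw per retained allocation.
#'
#' @param X Binary design matrix (matrix or `binary_design_matrix`).
#' @param relab Output of [ecr_relabel()].
#' @param prior A `mixture_prior`.
#' @param ci_level Credible level for the theta intervals.
#' @return An object of class `relabeled_posterior`: `k_map`,
#'   `theta_post_mean` (p x K), `pi_post_mean`, `membership_probs` (n x K),
#'   `theta_ci_lower`, `theta_ci_upper`, `theta_draws`.
#' @export
summarize_profiles <- function(X, relab, prior = mixture_prior(),
                               ci_level = 0.95) {
  Xm <- design_values(X)
  k_map <- relab$k_map
  n <- nrow(Xm); p <- ncol(Xm)
  draws <- relab$z_relab
  n_draws <- nrow(draws)
  a <- prior$alpha; b <- prior$beta; g <- prior$gamma
  theta_sum <- matrix(0, p, k_map)
  pi_sum <- numeric(k_map)
  member <- matrix(0, n, k_map)
  theta_draws <- array(0, dim = c(n_draws, p, k_map))
  for (d in seq_len(n_draws)) {
    z <- draws[d, ]
    nk <- tabulate(z, nbins = k_map)
    for (k in seq_len(k_map)) {
      s <- if (nk[k] > 0) colSums(Xm[z == k, , drop = FALSE]) else rep(0, p)
      theta_sum[, k] <- theta_sum[, k] + (a + s) / (a + b + nk[k])
      theta_draws[d, , k] <- stats::rbeta(p, a + s, b + nk[k] - s)
    }
    pi_sum <- pi_sum + (nk + g) / (n + k_map * g)
    member[cbind(seq_len(n), z)] <- member[cbind(seq_len(n), z)] + 1
  }
  lo <- (1 - ci_level) / 2
  ci_l <- apply(theta_draws, c(2, 3), stats::quantile, probs = lo)
  ci_u <- apply(theta_draws, c(2, 3), stats::quantile, probs = 1 - lo)
  vn <- if (inherits(X, "binary_design_matrix")) X$variable_names
        else colnames(Xm)
  out <- list(k_map = k_map,
              theta_post_mean = theta_sum / n_draws,
              pi_post_mean = pi_sum / n_draws,
              membership_probs = member / n_draws,
              theta_ci_lower = ci_l, theta_ci_upper = ci_u,
              theta_draws = theta_draws,
              variable_names = vn, n_draws = n_draws)
  if (!is.null(vn)) {
    rownames(out$theta_post_mean) <- vn
    rownames(out$theta_ci_lower) <- vn
    rownames(out$theta_ci_upper) <- vn
  }
  class(out) <- "relabeled_posterior"
  out
}

#' Hard profile assignment with uncertainty summary
#'
#' Assigns each tract to the profile with the greatest posterior membership
#' probability (ties to the lowest profile index) and summarizes assignment
#' certainty by the median and IQR of the row maxima, plus each profile's
#' share of tracts.
#'
#' @param membership_probs n x K matrix of per-tract membership
#'   probabilities (rows sum to 1), or a `relabeled_posterior`.
#' @param tract_ids Row identifiers.
#' @return A data frame (`tract_id`, `assigned_profile`, `assignment_prob`)
#'   with attribute `summary`: `median_prob`, `iqr_prob`, `shares`.
#' @export
assign_profiles <- function(membership_probs, tract_ids = NULL) {
  if (inherits(membership_probs, "relabeled_posterior"))
    membership_probs <- membership_probs$membership_probs
  m <- as.matrix(membership_probs)
  if (is.null(tract_ids)) tract_ids <- rownames(m)
  if (is.null(tract_ids)) tract_ids <- as.character(seq_len(nrow(m)))
  hard <- apply(m, 1, which.max)  # which.max ties to the lowest index
  prob <- m[cbind(seq_len(nrow(m)), hard)]
  out <- data.frame(tract_id = as.character(tract_ids),
                    assigned_profile = as.integer(hard),
                    assignment_prob = prob, stringsAsFactors = FALSE)
  shares <- tabulate(hard, nbins = ncol(m)) / nrow(m)
  attr(out, "summary") <- list(median_prob = stats::median(prob),
                               iqr_prob = stats::IQR(prob),
                               shares = shares)
  out
}

#' Disagreement count between a draw and the pivot
#'
#' @param z Allocation vector.
#' @param pivot Pivot allocation vector of the same length.
#' @return Number of positions where the labels differ.
#' @export
pivot_disagreement <- function(z, pivot) sum(z != pivot)
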