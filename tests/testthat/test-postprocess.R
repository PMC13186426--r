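# MAP profile count, ECR relabeling, conditional summaries, and hard
# assignment.

canonical_labels_for_test <- function(z) match(z, sort(unique(z)))

brute_force_best_perm <- function(z, pivot, k) {
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == k), ,
                 drop = FALSE]
  best <- Inf; best_z <- NULL
  for (r in seq_len(nrow(perms))) {
    zr <- as.integer(perms[r, ])[z]
    d <- sum(zr != pivot)
    if (d < best) { best <- d; best_z <- zr }
  }
  list(disagreement = best, z = best_z)
}

test_that("select_kmap takes the mode and breaks ties toward smaller K", {
  expect_identical(select_kmap(c(rep(2L, 10), rep(3L, 90))), 3L)
  expect_identical(select_kmap(c(rep(2L, 50), rep(3L, 50))), 2L)
  expect_identical(select_kmap(rep(7L, 5)), 7L)
  expect_error(select_kmap(integer(0)), "empty")
})

test_that("assignment-problem relabeling equals exhaustive permutation search", {
  set.seed(99)
  for (k in 2:5) {
    pivot <- c(seq_len(k), sample.int(k, 40, TRUE))  # all labels present
    n <- length(pivot)
    for (rep in 1:5) {
      z <- c(seq_len(k), sample.int(k, n - k, TRUE))
      relab <- ecr_relabel(matrix(z, 1), pivot, k)
      got <- sum(relab$z_relab[1, ] != pivot)
      want <- brute_force_best_perm(z, pivot, k)$disagreement
      expect_identical(got, as.integer(want))
    }
  }
})

test_that("label-permuted copies of the pivot relabel to zero disagreement", {
  set.seed(4)
  k <- 4
  pivot <- c(1:4, sample.int(k, 30, TRUE))
  perms <- rbind(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2), 1:4)
  z_draws <- t(apply(perms, 1, function(p) p[pivot]))
  relab <- ecr_relabel(z_draws, pivot, k)
  for (d in 1:nrow(z_draws)) {
    expect_identical(relab$z_relab[d, ], as.integer(pivot))
    # the recovered permutation undoes the applied one
    expect_identical(relab$permutations[d, perms[d, ]], 1:4)
  }
  # K_map = 1: identity always
  r1 <- ecr_relabel(matrix(1L, 3, 5), rep(1L, 5), 1)
  expect_true(all(r1$z_relab == 1L))
})

test_that("ECR never increases disagreement and excludes off-K draws", {
  set.seed(12)
  k <- 3
  pivot <- c(1:3, sample.int(3, 27, TRUE))
  z_draws <- rbind(
    c(1:3, sample.int(3, 27, TRUE)),
    c(1:3, sample.int(3, 27, TRUE)),
    rep(1L, 30)                      # only one nonempty component
  )
  expect_message(relab <- ecr_relabel(z_draws, pivot, k), "excluding 1")
  expect_identical(relab$kept, c(1L, 2L))
  for (d in 1:2) {
    before <- sum(z_draws[d, ] != pivot)
    after <- sum(relab$z_relab[d, ] != pivot)
    expect_lte(after, before)
  }
})

test_that("Hungarian solver matches brute force on random cost matrices", {
  set.seed(8)
  for (k in 2:6) {
    for (rep in 1:4) {
      cost <- matrix(stats::runif(k * k, -5, 5), k, k)
      a <- solve_assignment(cost)
      expect_identical(sort(a), 1:k)  # a permutation
      got <- sum(cost[cbind(1:k, a)])
      perms <- as.matrix(expand.grid(rep(list(1:k), k)))
      perms <- perms[apply(perms, 1, function(p) length(unique(p)) == k), ,
                     drop = FALSE]
      want <- min(apply(perms, 1, function(p) sum(cost[cbind(1:k, p)])))
      expect_equal(got, want)
    }
  }
})

test_that("profile summaries have the conjugate posterior-mean form", {
  # three identical draws; component 1 holds rows 1..3, all ones at
  # variable 1; alpha = beta = 1 gives E[theta] = (1+3)/(2+3) = 4/5
  X <- rbind(c(1, 0), c(1, 1), c(1, 0), c(0, 1), c(0, 1))
  relab <- list(z_relab = matrix(rep(c(1L, 1L, 1L, 2L, 2L), 3),
                                 nrow = 3, byrow = TRUE), k_map = 2L)
  set.seed(1)
  post <- summarize_profiles(X, relab, mixture_prior())
  expect_equal(unname(post$theta_post_mean[1, 1]), 4 / 5)
  expect_equal(unname(post$theta_post_mean[2, 2]), 3 / 4)
  # membership rows sum to one, and match the draw frequencies exactly
  expect_equal(rowSums(post$membership_probs), rep(1, 5))
  expect_equal(post$membership_probs[1, ], c(1, 0))
  # pi posterior mean: (n_k + 1)/(n + K)
  expect_equal(post$pi_post_mean, c(4 / 7, 3 / 7))
})

test_that("summaries are equivariant under a relabeling of the pivot", {
  set.seed(33)
  truth <- true_mixture(c(0.5, 0.5),
                        cbind(c(0.9, 0.1, 0.8), c(0.1, 0.9, 0.2)))
  sim <- simulate_mbmm(truth, 80, seed = 3)
  s <- run_mc3(sim$X, mixture_prior(k_max = 5),
               chain_config(n_chains = 2, temperatures = c(1, 0.8),
                            n_iter = 600, burn_in = 200, thin = 2,
                            k_init = 4, seed = 2))
  km <- select_kmap(s)
  piv <- pick_pivot(s, km)
  relab1 <- ecr_relabel(s$z_draws, piv, km)
  perm <- rev(seq_len(km))
  relab2 <- ecr_relabel(s$z_draws, perm[canonical_labels_for_test(piv)], km)
  set.seed(10); p1 <- summarize_profiles(sim$X, relab1)
  set.seed(10); p2 <- summarize_profiles(sim$X, relab2)
  expect_equal(p1$theta_post_mean, p2$theta_post_mean[, perm])
  expect_equal(p1$membership_probs, p2$membership_probs[, perm])
})

test_that("hard assignment is the row argmax with a faithful summary", {
  set.seed(14)
  m <- matrix(stats::rgamma(40 * 3, 1), 40, 3)
  m <- m / rowSums(m)
  asg <- assign_profiles(m, tract_ids = sprintf("t%02d", 1:40))
  # independent scan oracle
  for (i in 1:40) {
    expect_identical(asg$assigned_profile[i],
                     as.integer(which(m[i, ] == max(m[i, ]))[1]))
    expect_equal(asg$assignment_prob[i], max(m[i, ]))
  }
  summ <- attr(asg, "summary")
  expect_equal(summ$median_prob, stats::median(asg$assignment_prob))
  expect_equal(sum(summ$shares), 1)
  # degenerate certainty: one entry 1 per row
  md <- diag(3)[c(1, 2, 3, 1), ]
  asgd <- assign_profiles(md)
  expect_true(all(asgd$assignment_prob == 1))
  expect_equal(attr(asgd, "summary")$iqr_prob, 0)
  # assignment probability can never fall below 1/K
  expect_true(all(asg$assignment_prob >= 1 / 3))
})
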