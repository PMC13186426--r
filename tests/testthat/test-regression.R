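# Design construction, the Bayesian logistic sampler, and crude odds
# ratios.

make_patients <- function(n, or2 = 0.8, seed = 1) {
  covs <- simulate_covariates(n, seed = seed + 1)
  tom <- true_outcome_model(
    intercept = qlogis(0.8),
    profile_effects = c("1" = 0, "2" = log(or2), "3" = 0, "4" = 0, "5" = 0),
    covariate_effects = list(
      year_dx = c("2015" = 0, "2016" = 0, "2017" = 0),
      age_group = c("<50" = 0, "50-64" = 0, ">=65" = 0),
      insurance = c(Private = 0, Medicare = 0, Public = 0, Other = 0,
                    Uninsured = 0),
      facility_type = c(Academic = 0, Community = 0, Specialty = 0,
                        Teaching = 0)),
    seed = seed)
  set.seed(seed + 2)
  prof <- sample(as.character(1:5), n, TRUE,
                 prob = c(0.39, 0.18, 0.21, 0.14, 0.08))
  simulate_patients(prof, tom, covs)
}

test_that("the design matrix is full-rank dummy coding with stated references", {
  rec <- make_patients(400, seed = 3)
  bd <- build_design(rec, reference_profile = "1")
  # 4 profile columns + sum(levels - 1) covariate columns + intercept
  n_expected <- 1L + 4L + (3L - 1L) + (3L - 1L) + (5L - 1L) + (4L - 1L)
  expect_identical(ncol(bd$design), n_expected)
  expect_true(all(bd$design[, "(Intercept)"] == 1))
  expect_false("profile1" %in% bd$terms)
  expect_identical(unname(bd$design[, "profile2"]),
                   as.numeric(rec$profile == "2"))
  # single-level covariate contributes no columns
  rec2 <- rec; rec2$year_dx <- "2015"
  bd2 <- build_design(rec2)
  expect_identical(ncol(bd2$design), n_expected - 2L)
  expect_error(build_design(rec, reference_profile = "99"), "99")
  expect_error(build_design(rec, reference_levels = list(insurance = "Moon")),
               "Moon")
})

test_that("with a near-flat prior the posterior mode matches the glm MLE", {
  rec <- make_patients(5000, or2 = 0.7, seed = 11)
  bd <- build_design(rec)
  fit <- fit_bayes_logistic(bd$design, bd$outcome, prior_scale = 1e6,
                            mcmc = list(n_chains = 1, n_iter = 200,
                                        adapt = 200, seed = 1))
  # independent IRLS oracle
  df <- as.data.frame(bd$design[, -1])
  df$y <- bd$outcome
  ml <- stats::glm(y ~ ., data = df, family = stats::binomial())
  expect_equal(unname(fit$mode), unname(stats::coef(ml)), tolerance = 1e-4)
  expect_true(max(abs(fit$mode - stats::coef(ml))) < 5e-4)
})

test_that("the sampler recovers a known profile odds ratio and covers the null", {
  rec <- make_patients(100000, or2 = 0.8, seed = 21)
  bd <- build_design(rec)
  fit <- fit_bayes_logistic(bd$design, bd$outcome,
                            mcmc = list(n_chains = 2, n_iter = 4000,
                                        adapt = 1000, seed = 7))
  row2 <- fit$or_table[fit$or_table$term == "profile2", ]
  expect_gt(row2$or, 0.75)
  expect_lt(row2$or, 0.85)
  expect_lt(row2$ci_lower, 0.8)
  expect_gt(row2$ci_upper, 0.8)
  # truly-null terms cover OR = 1 at roughly the nominal 95% rate
  nulls <- fit$or_table[fit$or_table$term != "profile2", ]
  covered <- nulls$ci_lower < 1 & nulls$ci_upper > 1
  expect_gte(sum(covered), nrow(nulls) - 2)
  expect_gt(fit$diagnostics$acceptance_rate, 0.05)
  expect_lt(fit$diagnostics$acceptance_rate, 0.6)
})

test_that("two seeds agree within Monte-Carlo error", {
  rec <- make_patients(20000, or2 = 0.8, seed = 31)
  bd <- build_design(rec)
  f1 <- fit_bayes_logistic(bd$design, bd$outcome,
                           mcmc = list(n_chains = 2, n_iter = 3000,
                                       adapt = 1000, seed = 101))
  f2 <- fit_bayes_logistic(bd$design, bd$outcome,
                           mcmc = list(n_chains = 2, n_iter = 3000,
                                       adapt = 1000, seed = 202))
  for (term in f1$or_table$term) {
    d1 <- f1$draws[, term]
    d2 <- f2$draws[, term]
    ess1 <- max(f1$diagnostics$ess[term], 10, na.rm = TRUE)
    ess2 <- max(f2$diagnostics$ess[term], 10, na.rm = TRUE)
    se <- sqrt(sd(d1)^2 / ess1 + sd(d2)^2 / ess2)
    expect_lt(abs(mean(d1) - mean(d2)), 4 * se)
  }
  # identical seed reproduces draws exactly
  f3 <- fit_bayes_logistic(bd$design, bd$outcome,
                           mcmc = list(n_chains = 2, n_iter = 3000,
                                       adapt = 1000, seed = 101))
  expect_identical(f1$draws, f3$draws)
})

test_that("pattern collapse leaves the log posterior exact", {
  # binomial collapse must equal the row-by-row Bernoulli likelihood;
  # checked through the mode, which depends on the likelihood alone
  rec <- make_patients(800, seed = 41)
  bd <- build_design(rec)
  fit <- fit_bayes_logistic(bd$design, bd$outcome, prior_scale = 1e8,
                            mcmc = list(n_chains = 1, n_iter = 50,
                                        adapt = 50, seed = 1))
  df <- as.data.frame(bd$design[, -1]); df$y <- bd$outcome
  ml <- stats::glm(y ~ ., data = df, family = stats::binomial())
  expect_equal(unname(fit$mode), unname(coef(ml)), tolerance = 1e-5)
})

test_that("crude odds ratios follow the two-by-two arithmetic", {
  counts <- optimal_care_counts()
  or <- crude_or_from_table(counts, ref = 1)
  expect_equal(or$crude_or[or$profile == "1"], 1)
  expect_equal(or$crude_or[or$profile == "2"], (351 * 158) / (88 * 794))
  # identical rows give OR 1; doubling counts changes nothing
  same <- data.frame(profile = c("1", "2"), not_optimal = c(50, 50),
                     optimal = c(150, 150))
  expect_equal(crude_or_from_table(same, ref = 1)$crude_or, c(1, 1))
  doubled <- counts; doubled$not_optimal <- doubled$not_optimal * 2
  doubled$optimal <- doubled$optimal * 2
  expect_equal(crude_or_from_table(doubled, ref = 1)$crude_or,
               or$crude_or)
  # zero cells flag, and the continuity correction resolves them
  zc <- data.frame(profile = c("1", "2"), not_optimal = c(0, 5),
                   optimal = c(10, 10))
  expect_warning(crude_or_from_table(zc, ref = 1), "zero cell")
  corrected <- crude_or_from_table(zc, ref = 1, correction = TRUE)
  expect_equal(corrected$crude_or[2], (10.5 / 5.5) / (10.5 / 0.5))
})

test_that("outcome validation rejects non-binary input", {
  rec <- make_patients(50, seed = 51)
  bd <- build_design(rec)
  expect_error(fit_bayes_logistic(bd$design, rep(2, 50)), "binary")
  rec$outcome[1] <- 3
  expect_error(build_design(rec), "binary")
})
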