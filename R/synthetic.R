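# Synthetic tract and patient generators with known truth, so every stage of
# the pipeline can be validated end to end without external data.

#' Known mixture truth for simulation
#'
#' @param pi_true Probability vector of component weights (length K).
#' @param theta_true p x K matrix of Bernoulli success probabilities.
#' @param seed Integer seed attached to the truth; generators default to it.
#' @return An object of class `true_mixture`.
#' @export
true_mixture <- function(pi_true, theta_true, seed = 1) {
  pi_true <- as.numeric(pi_true)
  theta_true <- as.matrix(theta_true)
  if (length(pi_true) < 1) stop("at least one component is required")
  if (abs(sum(pi_true) - 1) > 1e-12) stop("`pi_true` must sum to 1")
  if (any(pi_true < 0)) stop("`pi_true` must be non-negative")
  if (ncol(theta_true) != length(pi_true))
    stop("`theta_true` needs one column per component")
  if (any(theta_true < 0 | theta_true > 1))
    stop("`theta_true` entries must lie in [0, 1]")
  structure(list(K_true = length(pi_true), pi_true = pi_true,
                 theta_true = theta_true, seed = as.integer(seed)),
            class = "true_mixture")
}

#' Well-separated five-profile truth at study dimensions
#'
#' A default truth mimicking the Massachusetts analysis scale: 14 indicators,
#' five profiles with distinct high/low exposure blocks (success
#' probabilities 0.9 vs 0.1) and weights echoing the reported profile shares
#' (roughly 32%, 25%, 18%, 15%, 10%).
#'
#' @param seed Seed stored in the truth object.
#' @return A `true_mixture` with K = 5, p = 14.
#' @export
study_truth <- function(seed = 20150) {
  patterns <- rbind(
    # one row per profile, one column per indicator; 1 = high exposure.
    # every pair of patterns differs in at least 6 indicators, so the
    # profiles are well separated at the 0.9/0.1 exposure probabilities
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),  # advantaged
    c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0),  # disadvantaged, diverse
    c(0, 0, 0, 1, 1, 1, 1, 0, 1, 1, 0, 1, 0, 0),  # working class, low educ.
    c(1, 1, 0, 1, 0, 0, 0, 1, 0, 0, 1, 0, 0, 1),  # renter/Asian, secure
    c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1)   # diverse renter, limited EN
  )
  theta <- t(ifelse(patterns == 1, 0.9, 0.1))
  true_mixture(pi_true = c(0.32, 0.25, 0.18, 0.15, 0.10),
               theta_true = theta, seed = seed)
}

#' Sample binary tract indicators from a known mixture
#'
#' Each row draws a component \eqn{z_i \sim \mathrm{Categorical}(\pi)} and
#' then independent Bernoulli indicators \eqn{x_{ij} \sim
#' \mathrm{Bern}(\theta_{j|z_i})}.
#'
#' @param truth A `true_mixture`.
#' @param n Number of tracts.
#' @param seed Seed; defaults to the one in `truth`.
#' @return A list with `X` (a `binary_design_matrix`) and `z` (true
#'   allocations).
#' @export
simulate_mbmm <- function(truth, n, seed = truth$seed) {
  stopifnot(inherits(truth, "true_mixture"))
  if (n < 1) stop("`n` must be at least 1")
  set.seed(seed)
  p <- nrow(truth$theta_true)
  z <- sample.int(truth$K_true, n, replace = TRUE, prob = truth$pi_true)
  probs <- t(truth$theta_true)[z, , drop = FALSE]          # n x p
  X <- matrix(stats::rbinom(n * p, 1L, as.vector(probs)), nrow = n)
  vn <- if (p == 14) default_variable_catalog()$name else paste0("v", seq_len(p))
  list(X = binary_design_matrix(X, tract_ids = sprintf("tract_%04d", seq_len(n)),
                                variable_names = vn),
       z = z)
}

#' Sample ACS-like raw tract tables with latent cluster structure
#'
#' Produces bounded, skewed proportion columns (plus one unbounded income
#' column when the 14-variable catalog applies) whose median
#' dichotomization approximately recovers a binary matrix drawn from the
#' mixture truth. Each tract first draws its intended binary exposure
#' vector from the mixture; the raw value is then placed strictly on the
#' matching side of a per-variable anchor with a right-skewed Beta(2, 5)
#' offset, which reproduces the skewness that motivates median splits.
#'
#' @param n Number of tracts.
#' @param p Number of indicators; must match `truth`.
#' @param truth A `true_mixture`.
#' @param seed Seed; defaults to the one in `truth`.
#' @return A list with `raw` (data frame with `tract_id` and indicator
#'   columns), `z` (true allocations), and `x_intended` (the generating
#'   binary matrix).
#' @export
simulate_acs_like_raw <- function(n, p, truth, seed = truth$seed) {
  stopifnot(inherits(truth, "true_mixture"))
  if (p != nrow(truth$theta_true))
    stop("`p` must equal the number of rows of `theta_true`")
  sim <- simulate_mbmm(truth, n, seed = seed)
  X <- sim$X$values
  use_catalog <- (p == 14)
  catalog <- if (use_catalog) default_variable_catalog() else
    data.frame(name = paste0("v", seq_len(p)),
               direction = rep("standard", p), stringsAsFactors = FALSE)
  # anchors echoing the scale of the Massachusetts medians (as proportions)
  anchors <- if (use_catalog) {
    c(0.34, 0.077, 0.013, 0, 82265, 0.039, 0.077, 0.029, 0.539,
      0.065, 0.058, 0.06, 0.028, 0.032)
  } else rep(0.3, p)
  raw <- matrix(0, nrow = n, ncol = p)
  for (j in seq_len(p)) {
    x <- X[, j]
    dir <- catalog$direction[j]
    if (dir == "zero_threshold") {
      raw[, j] <- ifelse(x == 1, stats::rbeta(n, 1, 30) * 0.5 + 1e-4, 0)
    } else if (dir == "reversed") {
      m <- anchors[j]
      off <- stats::rbeta(n, 2, 5)
      raw[, j] <- ifelse(x == 1, m * (1 - 0.6 * off - 1e-6),
                         m * (1 + 0.8 * off + 1e-6))
    } else {
      m <- anchors[j]
      off <- stats::rbeta(n, 2, 5)
      raw[, j] <- ifelse(x == 1, m + (1 - m) * off, m - m * off)
    }
  }
  df <- as.data.frame(raw)
  names(df) <- catalog$name
  df <- cbind(tract_id = sprintf("tract_%04d", seq_len(n)), df,
              stringsAsFactors = FALSE)
  list(raw = df, z = sim$z, x_intended = X)
}

#' Known outcome-model truth for patient simulation
#'
#' @param intercept Log-odds intercept.
#' @param profile_effects Named numeric vector of per-profile log-odds
#'   offsets; the reference profile must have effect exactly 0.
#' @param covariate_effects Named list; each element a named numeric vector
#'   of per-level log-odds offsets with the reference level at exactly 0.
#' @param seed Integer seed.
#' @return An object of class `true_outcome_model`.
#' @export
true_outcome_model <- function(intercept = 0,
                               profile_effects,
                               covariate_effects = list(),
                               seed = 1) {
  if (!all(is.finite(c(intercept, profile_effects,
                       unlist(covariate_effects, use.names = FALSE)))))
    stop("all effects must be finite")
  if (is.null(names(profile_effects)))
    names(profile_effects) <- as.character(seq_along(profile_effects))
  if (!any(profile_effects == 0))
    stop("the reference profile must have effect exactly 0")
  for (nm in names(covariate_effects)) {
    v <- covariate_effects[[nm]]
    if (is.null(names(v)) || !any(v == 0))
      stop("covariate `", nm,
           "` needs named levels with a reference effect of exactly 0")
  }
  structure(list(intercept = intercept, profile_effects = profile_effects,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "true_outcome_model")
}

#' Sample binary patient outcomes from a logistic truth
#'
#' \eqn{\mathrm{outcome}_i \sim \mathrm{Bern}(\mathrm{logit}^{-1}(
#' \mathrm{intercept} + \mathrm{profile\ effect} + \sum \mathrm{covariate\
#' effects}))}.
#'
#' @param assignments Profile label per patient (values among the names of
#'   `truth$profile_effects`).
#' @param truth A `true_outcome_model`.
#' @param covariate_design Data frame of per-patient covariate levels; its
#'   columns must match `truth$covariate_effects` and every level must be
#'   declared there.
#' @param seed Seed; defaults to the one in `truth`.
#' @return A data frame of patient records: `outcome`, `profile`, and the
#'   covariates.
#' @export
simulate_patients <- function(assignments, truth,
                              covariate_design = NULL, seed = truth$seed) {
  stopifnot(inherits(truth, "true_outcome_model"))
  assignments <- as.character(assignments)
  bad <- setdiff(unique(assignments), names(truth$profile_effects))
  if (length(bad) > 0)
    stop("unknown profile label(s): ", paste(bad, collapse = ", "))
  n <- length(assignments)
  eta <- truth$intercept + unname(truth$profile_effects[assignments])
  covs <- names(truth$covariate_effects)
  if (length(covs) > 0) {
    if (is.null(covariate_design))
      stop("`covariate_design` is required when covariate effects are declared")
    for (nm in covs) {
      lev <- as.character(covariate_design[[nm]])
      if (is.null(lev)) stop("covariate column missing: ", nm)
      unknown <- setdiff(unique(lev), names(truth$covariate_effects[[nm]]))
      if (length(unknown) > 0)
        stop("unknown level(s) for `", nm, "`: ",
             paste(unknown, collapse = ", "))
      eta <- eta + unname(truth$covariate_effects[[nm]][lev])
    }
  }
  set.seed(seed)
  outcome <- stats::rbinom(n, 1L, stats::plogis(eta))
  out <- data.frame(outcome = outcome, profile = assignments,
                    stringsAsFactors = FALSE)
  if (length(covs) > 0)
    out <- cbind(out, covariate_design[, covs, drop = FALSE])
  out
}

#' Study-like categorical covariate design
#'
#' Draws year of diagnosis, age group, insurance status, and facility type
#' with frequencies echoing the Massachusetts endometrial-cancer registry
#' sample.
#'
#' @param n Number of patients.
#' @param seed Seed.
#' @return A data frame with columns `year_dx`, `age_group`, `insurance`,
#'   `facility_type`.
#' @export
simulate_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    year_dx = sample(c("2015", "2016", "2017"), n, TRUE,
                     prob = c(0.34, 0.35, 0.31)),
    age_group = sample(c("<50", "50-64", ">=65"), n, TRUE,
                       prob = c(0.09, 0.46, 0.45)),
    insurance = sample(c("Private", "Medicare", "Public", "Other", "Uninsured"),
                       n, TRUE, prob = c(0.44, 0.41, 0.08, 0.055, 0.015)),
    facility_type = sample(c("Academic", "Community", "Specialty", "Teaching"),
                           n, TRUE, prob = c(0.39, 0.35, 0.015, 0.245)),
    stringsAsFactors = FALSE
  )
}
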