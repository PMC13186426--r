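# Bayesian logistic regression of a binary care outcome on profile
# membership plus categorical covariates, with a crude-odds-ratio
# descriptive comparator.

#' Full-rank dummy-coded design matrix from patient records
#'
#' Intercept plus indicator columns for every non-reference level of the
#' profile and of each categorical covariate. A covariate with a single
#' observed level contributes no columns.
#'
#' @param records Data frame with columns `outcome`, `profile`, and
#'   categorical covariates (every remaining column is treated as one).
#' @param reference_profile Profile used as the reference (default "1").
#' @param reference_levels Named list of reference levels per covariate;
#'   defaults to the first level in sort order.
#' @return A list: `design` (n x d numeric matrix), `terms` (column names),
#'   `outcome` (integer vector, if present in `records`).
#' @export
build_design <- function(records, reference_profile = "1",
                         reference_levels = list()) {
  n <- nrow(records)
  if (!"profile" %in% names(records)) stop("`records` must have a `profile` column")
  prof <- as.character(records$profile)
  reference_profile <- as.character(reference_profile)
  if (!reference_profile %in% prof)
    stop("reference profile absent from the data: ", reference_profile)
  cols <- list("(Intercept)" = rep(1, n))
  for (lev in setdiff(sort(unique(prof)), reference_profile))
    cols[[paste0("profile", lev)]] <- as.numeric(prof == lev)
  covariates <- setdiff(names(records), c("outcome", "profile"))
  for (nm in covariates) {
    v <- as.character(records[[nm]])
    levs <- sort(unique(v))
    ref <- if (!is.null(reference_levels[[nm]])) as.character(reference_levels[[nm]])
           else levs[1]
    if (!ref %in% levs)
      stop("reference level absent from the data for `", nm, "`: ", ref)
    for (lev in setdiff(levs, ref))
      cols[[paste0(nm, lev)]] <- as.numeric(v == lev)
  }
  design <- do.call(cbind, cols)
  colnames(design) <- names(cols)
  out <- list(design = design, terms = names(cols))
  if ("outcome" %in% names(records)) {
    y <- records$outcome
    if (!all(y %in% c(0, 1))) stop("`outcome` must be binary 0/1")
    out$outcome <- as.integer(y)
  }
  out
}

log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(x)))

ess_batch <- function(x, n_batches = 50) {
  n <- length(x)
  m <- floor(n / n_batches)
  if (m < 2) return(NA_real_)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(x[((b - 1) * m + 1):(b * m)]), numeric(1))
  v_bm <- m * stats::var(means)
  if (v_bm <= 0) return(n)
  min(n, n * stats::var(x) / v_bm)
}

#' Posterior mode and curvature of the logistic model
#'
#' Newton iterations on the log posterior under independent Normal(0, sd^2)
#' coefficient priors, using the binomial collapse of repeated covariate
#' patterns.
#' @keywords internal
logistic_map_fit <- function(P, y_succ, trials, prior_sd, max_iter = 100,
                             tol = 1e-12) {
  d <- ncol(P)
  beta <- numeric(d)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(P %*% beta)
    mu <- stats::plogis(eta)
    grad <- as.vector(crossprod(P, y_succ - trials * mu)) - beta / prior_sd^2
    W <- trials * mu * (1 - mu)
    H <- -crossprod(P, P * W) - diag(1 / prior_sd^2, d)
    step <- solve(H, -grad)
    beta_new <- beta + step
    if (max(abs(step)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  list(mode = beta, neg_hessian = -H)
}

#' Bayesian logistic regression by adaptive random-walk Metropolis
#'
#' Samples the exact posterior of the logistic coefficients under
#' independent Normal(0, `prior_scale`^2) priors (default sd 2.5 on
#' indicator predictors, 10 on the intercept). Repeated covariate patterns
#' are collapsed to binomial counts, so the likelihood cost is independent
#' of the number of patients. The proposal is a multivariate normal scaled
#' from the Laplace curvature at the posterior mode, with the global step
#' size adapted toward 23% acceptance during a discarded adaptation phase.
#'
#' @param design n x d design matrix (see [build_design()]).
#' @param outcomes Binary 0/1 vector of length n.
#' @param prior_scale Either a scalar prior sd for all terms, or a length-2
#'   vector `c(intercept, predictors)`.
#' @param mcmc List of sampler settings: `n_chains`, `n_iter` (post
#'   adaptation, per chain), `adapt`, `thin`, `seed`.
#' @return An object of class `regression_result`: `draws` (matrix of
#'   posterior draws), `or_table` (posterior-mean OR with 95% equal-tailed
#'   credible intervals per non-reference term), `mode`, `diagnostics`
#'   (acceptance rate, per-term effective sample size).
#' @export
fit_bayes_logistic <- function(design, outcomes,
                               prior_scale = c(10, 2.5),
                               mcmc = list()) {
  design <- as.matrix(design)
  outcomes <- as.integer(outcomes)
  if (!all(outcomes %in% c(0L, 1L))) stop("`outcomes` must be binary 0/1")
  if (length(outcomes) != nrow(design))
    stop("`outcomes` must match the design rows")
  d <- ncol(design)
  if (nrow(design) < d)
    warning("fewer observations than coefficients; the prior will dominate")
  cfg <- utils::modifyList(
    list(n_chains = 4, n_iter = 5000, adapt = 1000, thin = 1, seed = 1),
    mcmc)
  terms <- colnames(design)
  if (is.null(terms)) terms <- paste0("b", seq_len(d))
  is_int <- terms == "(Intercept)"
  prior_sd <- if (length(prior_scale) == 1) rep(prior_scale, d)
              else ifelse(is_int, prior_scale[1], prior_scale[2])

  # collapse identical covariate patterns to binomial counts
  key <- apply(design, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  P <- design[first, , drop = FALSE]
  idx <- match(key, key[first])
  trials <- as.vector(tabulate(idx, nbins = nrow(P)))
  y_succ <- as.vector(rowsum(as.numeric(outcomes), idx)[, 1])

  log_post <- function(beta) {
    eta <- as.vector(P %*% beta)
    sum(y_succ * eta - trials * log1pexp(eta)) - sum(beta^2 / (2 * prior_sd^2))
  }

  fit <- logistic_map_fit(P, y_succ, trials, prior_sd)
  Sigma <- solve(fit$neg_hessian)
  L <- t(chol((Sigma + t(Sigma)) / 2))
  base_scale <- 2.38 / sqrt(d)

  set.seed(cfg$seed)
  keep_per_chain <- floor(cfg$n_iter / cfg$thin)
  draws <- matrix(0, nrow = cfg$n_chains * keep_per_chain, ncol = d,
                  dimnames = list(NULL, terms))
  acc_total <- 0; att_total <- 0
  row_at <- 0
  for (ch in seq_len(cfg$n_chains)) {
    beta <- fit$mode + as.vector(L %*% stats::rnorm(d)) * 0.1
    lp <- log_post(beta)
    scale <- base_scale
    acc_window <- 0
    for (it in seq_len(cfg$adapt + cfg$n_iter)) {
      prop <- beta + as.vector(L %*% stats::rnorm(d)) * scale
      lp_prop <- log_post(prop)
      if (log(stats::runif(1)) <= lp_prop - lp) {
        beta <- prop; lp <- lp_prop
        acc_window <- acc_window + 1
        if (it > cfg$adapt) acc_total <- acc_total + 1
      }
      if (it <= cfg$adapt && it %% 100 == 0) {
        rate <- acc_window / 100
        scale <- scale * exp(rate - 0.234)
        acc_window <- 0
      }
      if (it > cfg$adapt) {
        att_total <- att_total + 1
        k <- it - cfg$adapt
        if (k %% cfg$thin == 0) {
          row_at <- row_at + 1
          draws[row_at, ] <- beta
        }
      }
    }
  }

  keep_terms <- !is_int
  qs <- apply(draws[, keep_terms, drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  or_table <- data.frame(
    term = terms[keep_terms],
    or = exp(colMeans(draws[, keep_terms, drop = FALSE])),
    ci_lower = exp(qs[1, ]),
    ci_upper = exp(qs[2, ]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ess <- apply(draws, 2, ess_batch)
  structure(
    list(draws = draws, or_table = or_table, mode = stats::setNames(fit$mode, terms),
         diagnostics = list(acceptance_rate = acc_total / att_total,
                            ess = ess),
         terms = terms, prior_sd = stats::setNames(prior_sd, terms),
         config = cfg),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat("Bayesian logistic regression:", length(x$terms), "terms,",
      nrow(x$draws), "posterior draws\n")
  cat(sprintf("Acceptance rate %.2f; min ESS %.0f\n",
              x$diagnostics$acceptance_rate, min(x$diagnostics$ess, na.rm = TRUE)))
  print(x$or_table, digits = 3)
  invisible(x)
}

#' Crude odds ratios from a profile-by-outcome contingency table
#'
#' \eqn{OR_k = (opt_k / not_k) / (opt_{ref} / not_{ref})}. Zero cells are
#' flagged; an optional 0.5 continuity correction is applied to every cell
#' when requested.
#'
#' @param contingency Data frame or matrix with one row per profile and
#'   columns `not_optimal` and `optimal` (row names or a `profile` column
#'   identify profiles).
#' @param ref Reference profile.
#' @param correction Apply the 0.5 continuity correction to all cells.
#' @return A data frame with `profile` and `crude_or` (reference row = 1).
#' @export
crude_or_from_table <- function(contingency, ref = 1, correction = FALSE) {
  tab <- as.data.frame(contingency)
  if ("profile" %in% names(tab)) {
    rownames(tab) <- as.character(tab$profile)
    tab$profile <- NULL
  }
  if (!all(c("not_optimal", "optimal") %in% names(tab)))
    stop("contingency needs `not_optimal` and `optimal` columns")
  ref <- as.character(ref)
  if (!ref %in% rownames(tab)) stop("reference profile absent: ", ref)
  m <- as.matrix(tab[, c("not_optimal", "optimal")])
  if (any(m == 0)) {
    if (correction) m <- m + 0.5
    else warning("zero cell(s) in the contingency table; odds ratios may be degenerate")
  }
  odds <- m[, "optimal"] / m[, "not_optimal"]
  data.frame(profile = rownames(tab), crude_or = unname(odds / odds[ref]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Published optimal-care counts by neighbourhood profile
#'
#' The cross-tabulation of NCCN-optimal care status against the five
#' neighbourhood SDoH profiles for Massachusetts endometrial carcinoma cases
#' diagnosed 2015-2017 (n = 2,412), as bundled in `inst/extdata`. Used for
#' worked crude-odds-ratio examples and marginal arithmetic.
#'
#' @return Data frame with columns `profile`, `not_optimal`, `optimal`.
#' @export
optimal_care_counts <- function() {
  path <- system.file("extdata", "optimal_care_by_profile.csv",
                      package = "nsdohmix", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
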