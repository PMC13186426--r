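# End-to-end pipeline: dichotomize -> fit -> relabel/summarize -> assign ->
# regress, driven by one config object with a single reproducibility seed.

#' Default pipeline configuration
#'
#' Returns the full configuration list the pipeline understands. Data can
#' come from delimited files (`raw_table`, `patients` paths) or, when these
#' are `NULL`, from the synthetic generators at the stated dimensions.
#'
#' @param seed Global seed; per-stage seeds are derived from it
#'   deterministically.
#' @param out_dir Run directory for all outputs.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("nsdoh_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    data = list(raw_table = NULL, patients = NULL,
                synthetic = list(n_tracts = 1478, n_patients = 2412,
                                 profile_or = c(1, 0.8, 1, 1, 1))),
    prior = list(lambda_k = 1, k_max = 50, gamma = 1, alpha = 1, beta = 1),
    chain = list(n_chains = 4, n_iter = 10000, burn_in = 1000, thin = 10,
                 swap_attempts_per_sweep = 1, k_init = 20, verbose = FALSE),
    regression = list(reference_profile = "1",
                      prior_scale = c(10, 2.5),
                      mcmc = list(n_chains = 4, n_iter = 5000, adapt = 1000,
                                  thin = 1))
  )
}

config_hash <- function(config) {
  semantic <- config[setdiff(names(config), "out_dir")]
  rlang::hash(semantic)
}

stage_seed <- function(seed, offset) (as.integer(seed) * 1009L + offset) %% 2147483629L

#' Run the full profile-and-outcome pipeline
#'
#' Executes, in order: median dichotomization of the tract table, posterior
#' sampling of the allocation model, MAP selection of the number of
#' profiles, ECR relabeling and conditional summaries, hard profile
#' assignment, and the outcome regression. All stochastic stages draw their
#' seeds deterministically from the global seed, so re-running the same
#' config reproduces every output byte-identically.
#'
#' @param config Configuration list (see [default_config()]) or the path to
#'   a YAML file holding one.
#' @return Invisibly, a list with the run directory, the manifest, and the
#'   in-memory stage results (`samples`, `posterior`, `assignments`,
#'   `regression`).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  config <- utils::modifyList(base, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed

  fail <- function(stage, e) {
    manifest <- list(status = "failed", failed_stage = stage,
                     error = conditionMessage(e), config_hash = hash)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # --- stage 1: tract table ------------------------------------------------
  truth <- NULL
  raw <- tryCatch({
    if (!is.null(config$data$raw_table)) {
      utils::read.csv(config$data$raw_table, stringsAsFactors = FALSE)
    } else {
      truth <- study_truth(seed = stage_seed(seed, 11L))
      simulate_acs_like_raw(config$data$synthetic$n_tracts, 14, truth)$raw
    }
  }, error = function(e) fail("load_raw", e))

  # --- stage 2: binarize ---------------------------------------------------
  res2 <- tryCatch({
    catalog <- default_variable_catalog()
    medians <- compute_state_medians(raw, catalog)
    X <- binarize(raw, medians, catalog)
    utils::write.csv(medians, file.path(config$out_dir, "medians.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(tract_id = X$tract_ids, X$values,
                                check.names = FALSE),
                     file.path(config$out_dir, "binary_matrix.csv"),
                     row.names = FALSE)
    list(X = X, medians = medians)
  }, error = function(e) fail("binarize", e))
  X <- res2$X

  # --- stage 3: allocation sampler ----------------------------------------
  samples <- tryCatch({
    prior <- do.call(mixture_prior, config$prior)
    cc <- do.call(chain_config,
                  c(config$chain, list(seed = stage_seed(seed, 23L))))
    s <- run_mc3(X, prior, cc)
    utils::write.csv(data.frame(draw = seq_along(s$k_trace),
                                k_nonempty = s$k_trace,
                                logpost = s$logpost_trace),
                     file.path(config$out_dir, "k_trace.csv"),
                     row.names = FALSE)
    s
  }, error = function(e) fail("fit", e))

  # --- stage 4: relabel, summarize, assign --------------------------------
  res4 <- tryCatch({
    k_map <- select_kmap(samples)
    pivot <- pick_pivot(samples, k_map)
    relab <- ecr_relabel(samples$z_draws, pivot, k_map)
    set.seed(stage_seed(seed, 37L))
    post <- summarize_profiles(X, relab, samples$prior)
    assignments <- assign_profiles(post, X$tract_ids)
    theta <- data.frame(variable = rownames(post$theta_post_mean),
                        post$theta_post_mean, check.names = FALSE)
    names(theta)[-1] <- paste0("profile_", seq_len(k_map))
    utils::write.csv(theta, file.path(config$out_dir, "profile_theta.csv"),
                     row.names = FALSE)
    utils::write.csv(assignments, file.path(config$out_dir, "assignments.csv"),
                     row.names = FALSE)
    list(k_map = k_map, post = post, assignments = assignments)
  }, error = function(e) fail("postprocess", e))

  # --- stage 5: outcome regression ----------------------------------------
  regression <- tryCatch({
    if (!is.null(config$data$patients)) {
      patients <- utils::read.csv(config$data$patients,
                                  stringsAsFactors = FALSE)
      if (!"profile" %in% names(patients)) {
        patients <- merge(patients, res4$assignments[, c("tract_id",
                                                         "assigned_profile")],
                          by = "tract_id")
        names(patients)[names(patients) == "assigned_profile"] <- "profile"
        patients$tract_id <- NULL
      }
    } else {
      npat <- config$data$synthetic$n_patients
      or <- config$data$synthetic$profile_or
      k_map <- res4$k_map
      shares <- attr(res4$assignments, "summary")$shares
      set.seed(stage_seed(seed, 41L))
      prof <- sample(seq_len(k_map), npat, TRUE,
                     prob = shares + 1e-9)
      eff <- log(or)[seq_len(k_map)]
      eff[is.na(eff)] <- 0
      eff <- eff - eff[1]
      covs <- simulate_covariates(npat, seed = stage_seed(seed, 43L))
      tom <- true_outcome_model(
        intercept = stats::qlogis(0.823),
        profile_effects = stats::setNames(eff, seq_len(k_map)),
        covariate_effects = list(
          year_dx = c("2015" = 0, "2016" = 0, "2017" = 0),
          age_group = c("<50" = 0, "50-64" = 0, ">=65" = 0),
          insurance = c(Private = 0, Medicare = 0, Public = 0, Other = 0,
                        Uninsured = 0),
          facility_type = c(Academic = 0, Community = 0, Specialty = 0,
                            Teaching = 0)),
        seed = stage_seed(seed, 47L))
      patients <- simulate_patients(prof, tom, covs)
    }
    bd <- build_design(patients,
                       reference_profile = config$regression$reference_profile,
                       reference_levels = config$regression$reference_levels)
    fit <- fit_bayes_logistic(bd$design, bd$outcome,
                              prior_scale = config$regression$prior_scale,
                              mcmc = c(config$regression$mcmc,
                                       list(seed = stage_seed(seed, 53L))))
    utils::write.csv(fit$or_table, file.path(config$out_dir, "or_table.csv"),
                     row.names = FALSE)
    fit
  }, error = function(e) fail("regress", e))

  summ <- attr(res4$assignments, "summary")
  manifest <- list(
    status = "complete",
    config_hash = hash,
    seed = seed,
    n_tracts = nrow(X$values),
    k_map = res4$k_map,
    median_assignment_prob = summ$median_prob,
    iqr_assignment_prob = summ$iqr_prob,
    profile_shares = summ$shares,
    acceptance = samples$acceptance_report[c("block", "eject", "absorb", "swap")]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(out_dir = config$out_dir, manifest = manifest,
                 samples = samples, posterior = res4$post,
                 assignments = res4$assignments, regression = regression))
}
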