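# Yost-type one-dimensional socioeconomic comparator: first principal
# component of seven standardized SES variables, scored and cut into
# quintiles.

#' Default seven-variable Yost catalog
#'
#' The classic variable set: median household income, median house value,
#' median gross rent, proportion below 150% of the poverty line,
#' unemployment rate, working-class occupation, and no high-school diploma.
#' `reverse = TRUE` marks disadvantage-direction variables that are
#' sign-flipped before the PCA so that higher always means higher SES.
#'
#' @return Data frame with columns `name`, `reverse`.
#' @export
default_yost_catalog <- function() {
  data.frame(
    name = c("median_income", "median_house_value", "median_gross_rent",
             "pct_poverty_150", "pct_unemployed", "pct_working_class",
             "pct_no_hs_diploma"),
    reverse = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Yost-type SES index: first principal component, quintile-cut
#'
#' Standardizes each variable to mean 0 / variance 1 (after sign-flipping
#' disadvantage-direction variables), projects tracts on the leading
#' eigenvector of the correlation matrix, orients the score to correlate
#' positively with income, and cuts the score ranks into quintiles
#' (1 = lowest SES). Quintile ties break by stable tract order.
#'
#' @param raw Data frame containing every catalog variable; a `tract_id`
#'   column is used for identifiers when present.
#' @param catalog Variable catalog with `name` and `reverse` columns.
#' @param orient_by Variable whose positive correlation fixes the score sign.
#' @return A data frame (`tract_id`, `score`, `quintile`) with attributes
#'   `loadings` (named leading-eigenvector entries) and `eigenvalue`.
#' @export
yost_index <- function(raw, catalog = default_yost_catalog(),
                       orient_by = catalog$name[1]) {
  absent <- setdiff(catalog$name, names(raw))
  if (length(absent) > 0)
    stop("raw table is missing Yost variables: ", paste(absent, collapse = ", "))
  vals <- as.matrix(raw[, catalog$name, drop = FALSE])
  if (!is.numeric(vals)) stop("Yost variables must be numeric")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s) cannot be standardized: ",
         paste(catalog$name[sds == 0], collapse = ", "))
  flip <- ifelse(catalog$reverse, -1, 1)
  z <- scale(vals) * matrix(flip, nrow(vals), ncol(vals), byrow = TRUE)
  eg <- eigen(stats::cor(z), symmetric = TRUE)
  v <- eg$vectors[, 1]
  score <- as.vector(z %*% v)
  if (stats::cor(score, vals[, orient_by]) < 0) {
    v <- -v
    score <- -score
  }
  n <- length(score)
  ranks <- rank(score, ties.method = "first")  # stable: ties by row order
  quintile <- as.integer(ceiling(5 * ranks / n))
  ids <- if ("tract_id" %in% names(raw)) as.character(raw$tract_id)
         else as.character(seq_len(n))
  out <- data.frame(tract_id = ids, score = score, quintile = quintile,
                    stringsAsFactors = FALSE)
  attr(out, "loadings") <- stats::setNames(v, catalog$name)
  attr(out, "eigenvalue") <- eg$values[1]
  out
}

#' Cross-tabulate the SES quintiles against the mixture profiles
#'
#' Descriptive comparison of the one-dimensional comparator with the
#' model-based profiles: quintile-by-profile contingency table plus a
#' chi-square statistic (no continuity correction).
#'
#' @param ses Output of [yost_index()].
#' @param assignments Output of [assign_profiles()] (needs `tract_id` and
#'   `assigned_profile`).
#' @return A list: `table` (quintile x profile counts), `chisq`
#'   (`statistic`, `df`, `p_value`), `n_matched`, `n_unmatched`.
#' @export
compare_indices <- function(ses, assignments) {
  merged <- merge(ses[, c("tract_id", "quintile")],
                  assignments[, c("tract_id", "assigned_profile")],
                  by = "tract_id")
  n_unmatched <- nrow(ses) + nrow(assignments) - 2 * nrow(merged)
  if (n_unmatched > 0)
    message(sprintf("compare_indices: %d unmatched tract record(s) excluded",
                    n_unmatched))
  if (nrow(merged) == 0) stop("no tracts matched between the two tables")
  tab <- table(quintile = merged$quintile, profile = merged$assigned_profile)
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab,
       chisq = list(statistic = unname(cs$statistic),
                    df = unname(cs$parameter),
                    p_value = unname(cs$p.value)),
       n_matched = nrow(merged), n_unmatched = n_unmatched)
}
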