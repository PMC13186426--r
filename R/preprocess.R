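# Median-dichotomization of tract-level indicator tables into the binary
# design matrix the mixture model consumes.

#' Default catalog of the 14 neighbourhood SDoH indicators
#'
#' One row per indicator: its column name, the ACS source table it is drawn
#' from, its thematic domain (housing conditions and resources, economic
#' security, educational attainment, social and community context), and how
#' it is dichotomized. `standard` indicators code 1 when strictly above the
#' state median (greater disadvantage); `reversed` (median household income)
#' codes 0 when at or above the median, 1 below; `zero_threshold` (incomplete
#' plumbing, whose state median is 0) codes 0 only for exactly-zero values.
#'
#' @return A data frame with columns `name`, `acs_table`, `domain`,
#'   `direction`.
#' @export
default_variable_catalog <- function() {
  data.frame(
    name = c("pct_renter_occupied", "pct_no_vehicle", "pct_crowding",
             "pct_no_plumbing", "median_income", "pct_female_head",
             "pct_snap", "pct_unemployed", "pct_working_class",
             "pct_no_hs_diploma", "pct_limited_english", "pct_hispanic",
             "pct_nh_black", "pct_nh_asian"),
    acs_table = c("DP04", "DP04", "DP04", "DP04", "B19013", "DP02", "DP03",
                  "DP03", "C24010", "DP02", "DP02", "DP05", "DP05", "DP05"),
    domain = c(rep("housing conditions and resources", 4),
               "economic security",  # income
               rep("economic security", 4),
               "educational attainment",
               rep("social and community context", 4)),
    direction = c("standard", "standard", "standard", "zero_threshold",
                  "reversed", rep("standard", 9)),
    stringsAsFactors = FALSE
  )
}

validate_catalog <- function(catalog) {
  needed <- c("name", "acs_table", "domain", "direction")
  if (!all(needed %in% names(catalog)))
    stop("catalog must have columns: ", paste(needed, collapse = ", "))
  ok_dir <- c("standard", "reversed", "zero_threshold")
  if (!all(catalog$direction %in% ok_dir))
    stop("catalog directions must be one of: ", paste(ok_dir, collapse = ", "))
  if (anyDuplicated(catalog$name))
    stop("catalog variable names must be unique")
  invisible(catalog)
}

#' Per-variable state medians and IQRs
#'
#' Empirical medians (mean of central order statistics at even n) and
#' interquartile ranges of every catalog variable across tracts. Tracts with
#' any missing catalog value are dropped with a warning rather than imputed.
#'
#' @param raw Data frame of tract-level values containing every catalog
#'   variable (extra columns such as tract identifiers are ignored).
#' @param catalog A variable catalog; see [default_variable_catalog()].
#' @return A data frame with columns `name`, `median`, `iqr`, and attribute
#'   `n_dropped` (tracts removed for missingness).
#' @export
compute_state_medians <- function(raw, catalog = default_variable_catalog()) {
  validate_catalog(catalog)
  absent <- setdiff(catalog$name, names(raw))
  if (length(absent) > 0)
    stop("raw table is missing catalog variables: ",
         paste(absent, collapse = ", "))
  vals <- raw[, catalog$name, drop = FALSE]
  for (nm in catalog$name) {
    if (!is.numeric(vals[[nm]]))
      stop("catalog variable is not numeric: ", nm)
  }
  complete <- stats::complete.cases(vals)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    warning(sprintf("dropping %d tract(s) with missing indicator values",
                    n_dropped))
    vals <- vals[complete, , drop = FALSE]
  }
  out <- data.frame(
    name = catalog$name,
    median = vapply(vals, stats::median, numeric(1)),
    iqr = vapply(vals, stats::IQR, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Binary design matrix container
#'
#' @param values n x p matrix with entries in \{0, 1\}.
#' @param tract_ids Unique row identifiers.
#' @param variable_names Length-p column names.
#' @return An object of class `binary_design_matrix`.
#' @export
binary_design_matrix <- function(values, tract_ids = rownames(values),
                                 variable_names = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(tract_ids)) tract_ids <- as.character(seq_len(nrow(values)))
  if (is.null(variable_names))
    variable_names <- paste0("v", seq_len(ncol(values)))
  if (anyNA(values)) stop("binary design matrix must have no missing entries")
  if (any(values != 0 & values != 1))
    stop("binary design matrix entries must be 0 or 1")
  if (length(tract_ids) != nrow(values))
    stop("`tract_ids` must have one entry per row")
  if (anyDuplicated(tract_ids)) stop("`tract_ids` must be unique")
  if (length(variable_names) != ncol(values))
    stop("`variable_names` must have one entry per column")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(as.character(tract_ids), variable_names)
  structure(list(tract_ids = as.character(tract_ids),
                 variable_names = variable_names, values = values),
            class = "binary_design_matrix")
}

# Accept either a raw 0/1 matrix or the container.
design_values <- function(X) {
  if (inherits(X, "binary_design_matrix")) return(X$values)
  Xm <- as.matrix(X)
  if (any(Xm != 0 & Xm != 1)) stop("`X` must be a 0/1 matrix")
  storage.mode(Xm) <- "integer"
  Xm
}

#' Dichotomize raw tract indicators at the state medians
#'
#' Applies the disadvantage-direction recoding: `standard` variables code 1
#' iff strictly above their median; the `reversed` income variable codes 0
#' iff at or above its median (ties to the non-disadvantaged side); the
#' `zero_threshold` plumbing variable codes 0 iff exactly zero. Proportion
#' variables (all but income) must lie in [0, 1].
#'
#' @param raw Data frame of tract-level values; a `tract_id` column is used
#'   for row identifiers when present.
#' @param medians Output of [compute_state_medians()] on the same variables.
#' @param catalog A variable catalog.
#' @return A `binary_design_matrix`.
#' @export
binarize <- function(raw, medians = compute_state_medians(raw, catalog),
                     catalog = default_variable_catalog()) {
  validate_catalog(catalog)
  if (!setequal(medians$name, catalog$name))
    stop("`medians` were not computed for the catalog's variable set")
  absent <- setdiff(catalog$name, names(raw))
  if (length(absent) > 0)
    stop("raw table is missing catalog variables: ",
         paste(absent, collapse = ", "))
  vals <- raw[, catalog$name, drop = FALSE]
  complete <- stats::complete.cases(vals)
  if (any(!complete)) {
    warning(sprintf("dropping %d tract(s) with missing indicator values",
                    sum(!complete)))
    raw <- raw[complete, , drop = FALSE]
    vals <- vals[complete, , drop = FALSE]
  }
  med <- stats::setNames(medians$median, medians$name)
  out <- matrix(0L, nrow = nrow(vals), ncol = nrow(catalog))
  for (idx in seq_len(nrow(catalog))) {
    nm <- catalog$name[idx]
    v <- vals[[nm]]
    dir <- catalog$direction[idx]
    if (dir != "reversed" && any(v < 0 | v > 1))
      stop("proportion variable out of [0, 1]: ", nm)
    out[, idx] <- switch(
      dir,
      standard = as.integer(v > med[nm]),
      reversed = as.integer(v < med[nm]),
      zero_threshold = as.integer(v != 0)
    )
  }
  ids <- if ("tract_id" %in% names(raw)) raw$tract_id else seq_len(nrow(vals))
  binary_design_matrix(out, tract_ids = ids, variable_names = catalog$name)
}
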