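## Area-level exposure matrix: z-scoring (with optional log transform for
## skewed variables), Townsend deprivation and Congdon social-fragmentation
## composites, Spearman correlations and collinearity diagnostics.

#' Standardise a covariate to z-scores
#'
#' Centres and scales to unit *population* SD (denominator `n`, not
#' `n - 1`) across the areas, optionally after a log transform for skewed
#' variables (zeros handled by a configurable offset).
#'
#' @param values numeric vector over areas, >= 2 distinct values.
#' @param log_first log-transform before standardising.
#' @param offset added before the log when any value is zero (ignored
#'   otherwise); negative values under `log_first` are rejected.
#' @return numeric z-scores with mean 0 and population SD 1.
#' @export
standardise_z <- function(values, log_first = FALSE, offset = 0.5) {
  stop_if(anyNA(values), "missing values not allowed")
  x <- as.numeric(values)
  if (log_first) {
    stop_if(any(x < 0), "log transform requires non-negative values")
    if (any(x == 0)) x <- x + offset
    x <- log(x)
  }
  n <- length(x)
  s <- stats::sd(x) * sqrt((n - 1) / n)
  stop_if(!is.finite(s) || s == 0, "cannot standardise a constant column")
  (x - mean(x)) / s
}

## Sample skewness (method-of-moments); drives the automatic log rule.
sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean(((x - m) / s)^3)
}

sum_of_z <- function(components, log_first = FALSE) {
  stop_if(length(unique(vapply(components, length, integer(1)))) != 1L,
          "component columns must cover identical areas")
  rowSums(vapply(components, standardise_z, numeric(length(components[[1]])),
                 log_first = log_first))
}

#' Townsend material deprivation index
#'
#' Sum of the z-scores of four census variables: households without a car,
#' households not owner-occupied, unemployed population, and overcrowded
#' households.  Higher values indicate more deprivation.
#'
#' @param pct_no_car,pct_not_owner_occupied,pct_unemployed,pct_overcrowded
#'   numeric percentage vectors over identical areas.
#' @return numeric index per area.
#' @export
townsend_index <- function(pct_no_car, pct_not_owner_occupied,
                           pct_unemployed, pct_overcrowded) {
  sum_of_z(list(pct_no_car, pct_not_owner_occupied,
                pct_unemployed, pct_overcrowded))
}

#' Congdon social fragmentation score
#'
#' Sum of the z-scores of four census variables: population whose residence
#' changed within 1 year, single-person households, privately renting
#' households, and unmarried adults.  Higher values indicate more
#' fragmentation.
#'
#' @param pct_moved_within_1yr,pct_single_person_households,pct_private_renting,pct_unmarried_adults
#'   numeric percentage vectors over identical areas.
#' @return numeric score per area.
#' @export
fragmentation_index <- function(pct_moved_within_1yr,
                                pct_single_person_households,
                                pct_private_renting,
                                pct_unmarried_adults) {
  sum_of_z(list(pct_moved_within_1yr, pct_single_person_households,
                pct_private_renting, pct_unmarried_adults))
}

#' Pairwise Spearman rank correlations
#'
#' @param table data.frame or matrix of covariates over >= 3 areas (a
#'   character `area_id` column, if present, is dropped).  Ties are handled
#'   by mid-ranks.
#' @return symmetric correlation matrix with unit diagonal; rows/columns for
#'   constant covariates are `NA` with a warning.
#' @export
spearman_matrix <- function(table) {
  x <- as.data.frame(table)
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  stop_if(nrow(x) < 3L, "at least 3 areas required")
  const <- vapply(x, function(c) length(unique(c)) == 1L, logical(1))
  if (any(const))
    warning("constant column(s): ", paste(names(x)[const], collapse = ", "),
            " - correlations undefined")
  r <- suppressWarnings(stats::cor(as.matrix(x), method = "spearman"))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r) <- ifelse(const, NA_real_, 1)
  r
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` is from an ordinary least-squares
#' regression of covariate `k` on all the others.  Values above 10 flag a
#' high level of multicollinearity; exact collinearity reports `Inf`.
#'
#' @param table data.frame/matrix of numeric covariates; more areas than
#'   covariates required.
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(table) {
  x <- as.data.frame(table)
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  stop_if(ncol(x) < 2L, "need at least two covariates")
  stop_if(nrow(x) <= ncol(x), "need more areas than covariates")
  out <- stats::setNames(numeric(ncol(x)), names(x))
  for (k in seq_len(ncol(x))) {
    fit <- stats::lm(x[[k]] ~ ., data = x[, -k, drop = FALSE])
    y <- x[[k]]
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
    out[k] <- if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }
  if (any(is.infinite(out)))
    warning("exact collinearity: ", paste(names(out)[is.infinite(out)], collapse = ", "))
  out
}

#' Iteratively drop the covariate with the largest VIF
#'
#' Repeats until every remaining covariate has VIF below the threshold,
#' mirroring the sensitivity analysis of omitting highly collinear
#' variables.
#'
#' @param table covariate data.frame.
#' @param threshold VIF threshold (default 10).
#' @return list with `kept` (the reduced table), `dropped` (names in drop
#'   order) and `vif` (final VIFs).
#' @export
vif_prune <- function(table, threshold = 10) {
  x <- as.data.frame(table)
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  dropped <- character()
  repeat {
    if (ncol(x) < 2L) break
    v <- suppressWarnings(vif(x))
    if (max(v) < threshold) break
    worst <- names(which.max(v))
    dropped <- c(dropped, worst)
    x <- x[, setdiff(names(x), worst), drop = FALSE]
  }
  list(kept = x,
       vif = if (ncol(x) >= 2L) suppressWarnings(vif(x)) else stats::setNames(1, names(x)),
       dropped = dropped)
}

#' Build the standardised design matrix for ecological regression
#'
#' Applies the log-then-z-score rule: a covariate is log-transformed when its
#' sample skewness exceeds `skew_threshold` or when listed in `log_vars`,
#' then all columns are standardised to population-SD z-scores.
#'
#' @param table data.frame with `area_id` plus numeric covariates.
#' @param log_vars character names to force log transformation.
#' @param skew_threshold automatic log rule cut-off (default 1).
#' @param offset zero-handling offset passed to [standardise_z()].
#' @return list with `X` (numeric z-score matrix, areas in `area_id` order),
#'   `area_id`, and `logged` (names of log-transformed columns).
#' @export
build_design <- function(table, log_vars = character(), skew_threshold = 1,
                         offset = 0.5) {
  stopifnot("area_id" %in% names(table))
  num <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], "area_id")
  logged <- character()
  X <- matrix(NA_real_, nrow(table), length(num), dimnames = list(NULL, num))
  for (v in num) {
    lf <- v %in% log_vars ||
      (all(table[[v]] >= 0) && sample_skewness(table[[v]]) > skew_threshold)
    if (lf) logged <- c(logged, v)
    X[, v] <- standardise_z(table[[v]], log_first = lf, offset = offset)
  }
  list(X = X, area_id = as.character(table$area_id), logged = logged)
}
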