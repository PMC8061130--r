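## Spatial autocorrelation: Moran's I with binary contiguity weights and a
## permutation test, plus the empirical-Bayes rate standardisation that
## adjusts for unequal area population sizes before computing I.

## I = (N / S0) * (sum_ij w_ij z_i z_j) / (sum_i z_i^2), z centred.
## With binary symmetric weights the double sum is 2 * sum over unique
## edges of z_i z_j.
moran_stat <- function(z, edges, S0, n) {
  cross <- 2 * sum(z[edges[, 1]] * z[edges[, 2]])
  (n / S0) * cross / sum(z^2)
}

#' Moran's I with permutation inference
#'
#' Computes Moran's I over binary contiguity weights (unnormalised by row by
#' default) and a Monte-Carlo p-value from random relabellings of the areas,
#' using `(count + 1) / (n_perm + 1)`.  Zero indicates no spatial
#' autocorrelation; positive/negative values indicate positive/negative
#' autocorrelation.
#'
#' @param values numeric vector over the areas; must not be constant.
#' @param adjacency a [adjacency_structure()] with >= 4 areas.
#' @param n_perm number of random relabellings (default 999).
#' @param seed integer seed for the permutations.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param row_standardise use row-standardised weights.
#' @return list with `I`, `p_value`, `expectation` (`-1/(N-1)`), `n_perm`,
#'   `alternative`.
#' @export
moran_classic <- function(values, adjacency, n_perm = 999, seed = 1,
                          alternative = c("two.sided", "greater", "less"),
                          row_standardise = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(adjacency, "bymsir_adjacency"))
  n <- adjacency$n
  stop_if(n < 4L, "at least 4 areas required")
  stop_if(length(values) != n, "values must match the number of areas")
  stop_if(stats::sd(values) == 0, "values are constant; Moran's I undefined")
  z <- values - mean(values)
  if (row_standardise) {
    W <- adjacency_matrix(adjacency, row_standardise = TRUE)
    S0 <- sum(W)
    obs <- (n / S0) * as.numeric(z %*% W %*% z) / sum(z^2)
    statfun <- function(zz) (n / S0) * as.numeric(zz %*% W %*% zz) / sum(zz^2)
  } else {
    edges <- adjacency_edges(adjacency)
    S0 <- 2 * nrow(edges)
    obs <- moran_stat(z, edges, S0, n)
    statfun <- function(zz) moran_stat(zz, edges, S0, n)
  }
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) statfun(z[sample.int(n)]), numeric(1))
  })
  p_hi <- (sum(null >= obs) + 1) / (n_perm + 1)
  p_lo <- (sum(null <= obs) + 1) / (n_perm + 1)
  p <- switch(alternative,
              greater = p_hi, less = p_lo,
              two.sided = min(1, 2 * min(p_hi, p_lo)))
  list(I = obs, p_value = p, expectation = -1 / (n - 1),
       n_perm = n_perm, alternative = alternative)
}

#' Empirical-Bayes standardised rates for unequal populations
#'
#' Assuncao-Reis standardisation: with overall rate `b = sum(O)/sum(n)` and
#' population-weighted variance `s2` of the raw rates around `b`, each
#' area's rate is transformed to `z_i = (r_i - b) / sqrt(a + b / n_i)` where
#' `a = s2 - b / mean(n)` (floored at zero with a warning).  This stabilises
#' the variance of rates from areas of different population sizes.
#'
#' @param event_counts non-negative event counts `O_i`.
#' @param populations positive populations `n_i`.
#' @return numeric vector of standardised rates.
#' @export
eb_standardise <- function(event_counts, populations) {
  O <- as.numeric(event_counts); n <- as.numeric(populations)
  stop_if(any(n <= 0), "all populations must be positive")
  stop_if(sum(O) <= 0, "total event count must be positive")
  b <- sum(O) / sum(n)
  r <- O / n
  s2 <- sum(n * (r - b)^2) / sum(n)
  a <- s2 - b / mean(n)
  if (a < 0) {
    warning("empirical-Bayes variance component negative; floored at 0")
    a <- 0
  }
  (r - b) / sqrt(a + b / n)
}

#' Population-size-adjusted Moran's I for rates
#'
#' Applies [eb_standardise()] to the raw rates, then [moran_classic()] to
#' the standardised values, so areas with small populations (noisy rates)
#' do not inflate the apparent spatial autocorrelation.
#'
#' @inheritParams moran_classic
#' @param event_counts,populations per-area counts and populations.
#' @return as [moran_classic()], plus the `z` values used.
#' @export
moran_eb <- function(event_counts, populations, adjacency, n_perm = 999,
                     seed = 1, alternative = c("two.sided", "greater", "less"),
                     row_standardise = FALSE) {
  z <- eb_standardise(event_counts, populations)
  stop_if(stats::sd(z) == 0,
          "standardised rates are constant (all O_i exactly proportional to n_i)")
  out <- moran_classic(z, adjacency, n_perm = n_perm, seed = seed,
                       alternative = alternative,
                       row_standardise = row_standardise)
  out$z <- z
  out
}
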