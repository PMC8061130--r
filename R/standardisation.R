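## Indirect sex/age standardisation: expected counts from reference stratum
## rates, raw standardised incidence ratios, and the mid-90% spread ratio.

#' Expected counts by indirect standardisation
#'
#' For each area, `E_i = sum_s n_is * r_s` over sex x age-band strata.  With
#' the internal reference the stratum rates are the study-region totals,
#' `r_s = sum_i O_is / sum_i n_is`, which guarantees `sum(E) == sum(O)`; an
#' external reference is a supplied rate table.
#'
#' @param counts long data.frame `(area_id, sex, age_band, count)` of
#'   observed index episodes (method- or otherwise-collapsed; extra strata
#'   columns are ignored after aggregation).
#' @param populations data.frame `(area_id, sex, age_band, count)` of
#'   stratum populations.
#' @param reference `"internal"` or a data.frame `(sex, age_band, rate)`.
#' @return data.frame `(area_id, O, E)`; strata with zero total population
#'   contribute nothing to `E`.
#' @export
expected_counts <- function(counts, populations, reference = "internal") {
  o <- stats::aggregate(count ~ area_id + sex + age_band, counts, sum)
  names(o)[names(o) == "count"] <- "O_s"
  p <- stats::aggregate(count ~ area_id + sex + age_band, populations, sum)
  names(p)[names(p) == "count"] <- "n_s"
  m <- merge(p, o, by = c("area_id", "sex", "age_band"), all.x = TRUE)
  m$O_s[is.na(m$O_s)] <- 0L
  if (identical(reference, "internal")) {
    tot <- stats::aggregate(cbind(O_s, n_s) ~ sex + age_band, m, sum)
    tot$rate <- ifelse(tot$n_s > 0, tot$O_s / tot$n_s, 0)
    rates <- tot[, c("sex", "age_band", "rate")]
  } else {
    rates <- reference
    miss <- unique(m[, c("sex", "age_band")])
    found <- merge(miss, rates, by = c("sex", "age_band"))
    stop_if(nrow(found) < nrow(miss),
            "supplied reference rates missing a stratum present in populations")
  }
  m <- merge(m, rates, by = c("sex", "age_band"))
  m$E_s <- m$n_s * m$rate
  byA <- stats::aggregate(cbind(O = O_s, E = E_s) ~ area_id, m, sum)
  obs_extra <- sum(o$O_s) - sum(byA$O)
  stop_if(abs(obs_extra) > 0.5,
          "observed counts include strata absent from the population table")
  byA[order(byA$area_id), , drop = FALSE]
}

#' Raw standardised incidence ratios
#'
#' `SIR_i = O_i / E_i`; a value of 1 marks an area whose rate equals the
#' study-region average.  Areas with `E = 0` but `O > 0` get `NA` with a
#' warning (they cannot enter ratio summaries); `O = 0, E = 0` also gives
#' `NA`.
#'
#' @param panel data.frame with columns `O` and `E` (from
#'   [expected_counts()]).
#' @return the panel with an added `SIR` column.
#' @export
raw_sir <- function(panel) {
  sir <- ifelse(panel$E > 0, panel$O / panel$E, NA_real_)
  und <- panel$E == 0 & panel$O > 0
  if (any(und))
    warning(sprintf("%d area(s) with O > 0 but E = 0: SIR undefined", sum(und)))
  panel$SIR <- sir
  panel
}

#' Mid-90% ratio of a distribution of area values
#'
#' The ratio of the 95th to the 5th percentile (quantiles by linear
#' interpolation of order statistics, the type-7 plotting position), a
#' spread measure robust to the 10% most extreme areas.  Higher values mean
#' more geographical variation.
#'
#' @param values numeric vector, >= 20 finite values required.
#' @return scalar ratio `q95 / q5`.
#' @export
mid90_ratio <- function(values) {
  v <- values[is.finite(values)]
  stop_if(length(v) < 20L, "at least 20 finite values required")
  q <- stats::quantile(v, c(0.05, 0.95), type = 7, names = FALSE)
  stop_if(q[1] <= 0, "5th percentile must be positive for a ratio")
  q[2] / q[1]
}
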