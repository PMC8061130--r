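## Reduction of raw episode records to per-area index-episode counts:
## exclusion rules with an auditable ledger, one-index-episode-per-person
## deduplication, and method classification by lethality precedence.

#' Apply record-level exclusion rules with an auditable ledger
#'
#' Records are tested in a fixed order so that every dropped record carries
#' exactly one reason: outside the study window, then under the minimum age,
#' then missing area id (no fixed abode), then area id outside the study
#' region.
#'
#' @param records data.frame with at least `person_id`, `event_date` (Date),
#'   `age`, `area_id`.
#' @param region_area_ids character vector of area ids comprising the study
#'   region.
#' @param study_window Date vector of length 2, inclusive.
#' @param min_age minimum age in years (default 10).
#' @return list with `kept` (the surviving records) and `ledger`, a named
#'   integer vector of counts by reason (`outside_window`, `under_min_age`,
#'   `no_fixed_abode`, `outside_region`) plus `input` and `kept`.
#' @export
apply_exclusions <- function(records,
                             region_area_ids,
                             study_window = as.Date(c("2003-01-01", "2013-12-31")),
                             min_age = 10) {
  stop_if(length(region_area_ids) == 0L, "region_area_ids must be non-empty")
  d <- as.Date(records$event_date)
  reason <- rep(NA_character_, nrow(records))
  bad_win <- is.na(d) | d < study_window[1] | d > study_window[2]
  reason[bad_win] <- "outside_window"
  bad_age <- is.na(reason) & (is.na(records$age) | records$age < min_age)
  reason[bad_age] <- "under_min_age"
  no_area <- is.na(reason) & (is.na(records$area_id) | records$area_id == "")
  reason[no_area] <- "no_fixed_abode"
  out_reg <- is.na(reason) & !(records$area_id %in% region_area_ids)
  reason[out_reg] <- "outside_region"
  keep <- is.na(reason)
  ledger <- c(input = nrow(records),
              kept = sum(keep),
              outside_window = sum(bad_win),
              under_min_age = sum(bad_age),
              no_fixed_abode = sum(no_area),
              outside_region = sum(out_reg))
  list(kept = records[keep, , drop = FALSE], ledger = ledger)
}

#' Reduce records to one index episode per person
#'
#' Keeps each person's earliest episode within the (already filtered)
#' records; ties on the same date are broken by original record order.
#'
#' @param records data.frame with `person_id` and `event_date`.
#' @return data.frame with exactly one row per distinct `person_id`.
#' @export
dedup_index_episodes <- function(records) {
  if (nrow(records) == 0L) return(records)
  ord <- order(records$person_id, as.Date(records$event_date),
               seq_len(nrow(records)))
  r <- records[ord, , drop = FALSE]
  r[!duplicated(r$person_id), , drop = FALSE]
}

## Lethality precedence (lower rank = higher precedence). The ordering below
## poisoning > {hanging, traffic} > cutting > {hitting, head banging, other}
## is a configurable convention: only poisoning-over-cutting is canonical,
## the remainder is a documented default.
default_method_precedence <- function() {
  c(poisoning = 1L, hanging = 2L, traffic = 2L, cutting = 3L,
    hitting = 4L, head_banging = 4L, other = 5L)
}

#' Classify an episode's method labels into reporting bins
#'
#' The highest-precedence label under the lethality ordering determines the
#' episode's primary method, collapsed to the three reporting bins
#' `poisoning`, `cutting`, `other` (self-poisoning takes precedence over
#' self-cutting; high-lethality methods such as hanging outrank cutting but
#' are reported as "other").
#'
#' @param method_labels character vector of one or more raw labels for a
#'   single episode, or a single `";"`-separated string.
#' @param precedence named integer ranks (lower = higher precedence); see
#'   `default_method_precedence()`.
#' @return one of `"poisoning"`, `"cutting"`, `"other"`.
#' @export
classify_method <- function(method_labels, precedence = default_method_precedence()) {
  labels <- unlist(strsplit(as.character(method_labels), ";", fixed = TRUE))
  labels <- trimws(labels[nzchar(trimws(labels))])
  stop_if(length(labels) == 0L, "at least one method label required")
  unknown <- setdiff(labels, names(precedence))
  if (length(unknown)) {
    warning("unrecognised method label(s) treated as 'other': ",
            paste(unknown, collapse = ", "))
  }
  ranks <- precedence[labels]
  ranks[is.na(ranks)] <- max(precedence) + 1L
  winner <- labels[which.min(ranks)]
  if (identical(winner, "poisoning")) "poisoning"
  else if (identical(winner, "cutting")) "cutting"
  else "other"
}

## Vectorised wrapper over record method strings.
classify_methods <- function(method_strings, precedence = default_method_precedence()) {
  vapply(method_strings, classify_method, character(1),
         precedence = precedence, USE.NAMES = FALSE)
}

#' Broad reporting age groups
#'
#' @param age integer ages.
#' @return factor with levels `10-24`, `25-44`, `45-64`, `65+`.
#' @export
reporting_age_group <- function(age) {
  cut(age, breaks = c(10, 25, 45, 65, Inf), right = FALSE,
      labels = c("10-24", "25-44", "45-64", "65+"))
}

#' Stratified per-area index-episode counts
#'
#' Cross-tabulates index records by area, sex, 5-year age band and method
#' bin, and aggregates to per-area totals and broad reporting age groups.
#' Every record's area must already lie in the geography (run
#' [apply_exclusions()] first).
#'
#' @param records deduplicated index records (with `area_id`, `sex`, `age`,
#'   `method`).
#' @param area_ids all area ids of the geography (zero-count areas are
#'   retained).
#' @param age_bands 5-year band labels.
#' @return list with `counts` (long data.frame `area_id`, `sex`, `age_band`,
#'   `method`, `count`), `by_area` (data.frame `area_id`, `O`), and
#'   `by_group` (`area_id`, `sex`, `age_group`, `count`).
#' @export
stratify_counts <- function(records, area_ids, age_bands = age_bands_5yr()) {
  bad <- !(records$area_id %in% area_ids)
  stop_if(any(bad), sprintf("%d record(s) with area_id outside the geography; run apply_exclusions first",
                            sum(bad)))
  fa <- factor(records$area_id, levels = area_ids)
  fs <- factor(records$sex, levels = c("male", "female"))
  fb <- factor(age_to_band(records$age, age_bands), levels = age_bands)
  fm <- factor(classify_methods(records$method),
               levels = c("poisoning", "cutting", "other"))
  tab <- as.data.frame(table(area_id = fa, sex = fs, age_band = fb, method = fm),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "count"
  by_area <- as.data.frame(table(area_id = fa), stringsAsFactors = FALSE)
  names(by_area)[2] <- "O"
  fg <- reporting_age_group(records$age)
  by_group <- as.data.frame(table(area_id = fa, sex = fs, age_group = fg),
                            stringsAsFactors = FALSE)
  names(by_group)[names(by_group) == "Freq"] <- "count"
  stopifnot(sum(tab$count) == nrow(records))
  list(counts = tab, by_area = by_area, by_group = by_group)
}
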