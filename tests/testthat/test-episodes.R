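win <- as.Date(c("2003-01-01", "2013-12-31"))

rec <- function(person, date, age = 30, area = "A1", method = "poisoning") {
  data.frame(person_id = person, event_date = as.Date(date), sex = "male",
             age = age, area_id = area, method = method,
             stringsAsFactors = FALSE)
}

test_that("each dropped record carries exactly one reason, in the fixed order", {
  records <- rbind(
    rec("p1", "2002-12-31"),                 # outside window (would also fail age)
    rec("p2", "2005-01-01", age = 9),        # under min age
    rec("p3", "2005-01-01", area = NA),      # no fixed abode
    rec("p4", "2005-01-01", area = "ZZZ"),   # outside region
    rec("p5", "2005-01-01"))                 # kept
  records$age[1] <- 5                        # window tested before age
  out <- apply_exclusions(records, region_area_ids = c("A1", "A2"),
                          study_window = win)
  expect_equal(unname(out$ledger[c("outside_window", "under_min_age",
                                   "no_fixed_abode", "outside_region")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(out$ledger[["kept"]], 1L)
  expect_equal(out$ledger[["input"]],
               out$ledger[["kept"]] + sum(out$ledger[c("outside_window",
                                                       "under_min_age",
                                                       "no_fixed_abode",
                                                       "outside_region")]))
  expect_equal(out$kept$person_id, "p5")
})

test_that("all-valid input passes untouched with an all-zero ledger", {
  records <- rbind(rec("p1", "2004-05-01"), rec("p2", "2010-08-09"))
  out <- apply_exclusions(records, "A1", study_window = win)
  expect_equal(nrow(out$kept), 2L)
  expect_true(all(out$ledger[c("outside_window", "under_min_age",
                               "no_fixed_abode", "outside_region")] == 0L))
})

test_that("exclusion ledger equals generator bookkeeping on a synthetic fixture", {
  st <- make_study(6, 6, K = 0, betas = numeric(), sigma_u = 0, sigma_v = 0,
                   baseline = 0.05, mean_pop = 1500, seed = 17,
                   exclusion_fractions = c(0.02, 0.05))
  out <- apply_exclusions(st$records, st$adj$ids, study_window = win)
  bk <- st$truth$bookkeeping
  expect_identical(out$ledger[["no_fixed_abode"]], bk$records_no_fixed_abode)
  expect_identical(out$ledger[["outside_region"]], bk$records_out_of_region)
  expect_identical(out$ledger[["outside_window"]], 0L)
  expect_identical(out$ledger[["under_min_age"]], 0L)
})

test_that("deduplication keeps the earliest episode with a deterministic tie rule", {
  records <- rbind(
    rec("p1", "2004-02-01"), rec("p1", "2003-01-05"),
    rec("p2", "2005-06-06", method = "cutting"),
    rec("p2", "2005-06-06", method = "hanging"),
    rec("p3", "2007-01-01"))
  idx <- dedup_index_episodes(records)
  expect_equal(nrow(idx), 3L)  # 5 records over 3 persons
  expect_equal(idx$event_date[idx$person_id == "p1"], as.Date("2003-01-05"))
  ## same-date tie broken by original record order
  expect_equal(idx$method[idx$person_id == "p2"], "cutting")
  ## idempotence
  expect_identical(dedup_index_episodes(idx), idx)
})

test_that("method classification follows the lethality precedence", {
  expect_equal(classify_method(c("poisoning", "cutting")), "poisoning")
  expect_equal(classify_method("cutting"), "cutting")
  expect_equal(classify_method(c("hanging", "cutting")), "other")
  expect_equal(classify_method("poisoning;cutting"), "poisoning")
  ## order-invariance
  expect_equal(classify_method(c("cutting", "poisoning")),
               classify_method(c("poisoning", "cutting")))
  expect_warning(res <- classify_method("self-immolation"), "unrecognised")
  expect_equal(res, "other")
  expect_error(classify_method(""), "at least one")
})

test_that("stratified counts partition the index records", {
  st <- make_study(6, 6, K = 0, betas = numeric(), sigma_u = 0, sigma_v = 0,
                   baseline = 0.05, mean_pop = 1200, seed = 23)
  idx <- dedup_index_episodes(apply_exclusions(st$records, st$adj$ids)$kept)
  s <- suppressWarnings(stratify_counts(idx, st$adj$ids))
  expect_equal(sum(s$counts$count), nrow(idx))
  expect_equal(sum(s$by_area$O), nrow(idx))
  expect_equal(sum(s$by_group$count), nrow(idx))
  ## per-area tallies equal the generator oracle for in-region persons
  expect_equal(s$by_area$O,
               unname(st$truth$bookkeeping$index_events_by_area[s$by_area$area_id]))
  ## records outside the geography are fatal here
  bad <- idx; bad$area_id[1] <- "NOPE"
  expect_error(stratify_counts(bad, st$adj$ids), "apply_exclusions")
})

test_that("zero records give an all-zero panel over all areas", {
  ids <- paste0("A", 1:9)
  s <- stratify_counts(rec("x", "2004-01-01")[0, ], ids)
  expect_equal(nrow(s$by_area), 9L)
  expect_true(all(s$by_area$O == 0L))
})
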