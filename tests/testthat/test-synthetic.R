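test_that("lattice geometry and contiguity follow the grid structure", {
  g <- make_lattice(2, 2)
  expect_equal(nrow(g$areas), 4L)
  expect_true(all(lengths(g$adjacency$nb) == 2L))  # corner-only grid

  p <- make_lattice(1, 5)
  deg <- lengths(p$adjacency$nb)
  expect_equal(sort(unique(deg)), c(1L, 2L))       # path graph
  expect_equal(sum(deg == 1L), 2L)

  big <- make_lattice(16, 16)
  expect_equal(nrow(adjacency_edges(big$adjacency)), 2L * 16L * 15L)  # 480

  q <- make_lattice(3, 3, contiguity = "queen")
  expect_equal(length(q$adjacency$nb[[5]]), 8L)    # centre cell

  expect_error(make_lattice(0, 3), "positive")
  expect_error(make_lattice(1, 3), "at least 4")
})

test_that("simulated populations are plausible, stratified and reproducible", {
  g <- make_lattice(16, 16)
  pop <- simulate_population(g, mean_area_pop = 1470, seed = 7)
  expect_true(all(pop$count >= 0))
  expect_true(all(pop$count == round(pop$count)))
  totals <- aggregate(count ~ area_id, pop, sum)
  expect_gt(median(totals$count), 1100)
  expect_lt(median(totals$count), 1900)

  pop2 <- simulate_population(g, mean_area_pop = 1470, seed = 7)
  expect_identical(pop, pop2)

  one <- simulate_population(g, age_bands = "10-14", mean_area_pop = 100, seed = 1)
  expect_true(all(one$count >= 0))
  expect_error(simulate_population(g, age_bands = character(), seed = 1),
               "age band")
})

test_that("covariate fields carry the requested spatial structure", {
  adj <- make_lattice(16, 16)$adjacency
  iid <- simulate_covariates(adj, K = 1, spatial_mix = 0, seed = 11)
  m0 <- moran_classic(iid$cov1, adj, n_perm = 499, seed = 1)
  expect_gt(m0$p_value, 0.01)  # no autocorrelation beyond noise

  sm <- simulate_covariates(adj, K = 1, spatial_mix = 0.9, seed = 11)
  expect_gt(moran_classic(sm$cov1, adj, n_perm = 199, seed = 1)$I, 0.3)

  k3 <- simulate_covariates(adj, K = 3, seed = 5)
  expect_equal(ncol(k3), 4L)
  expect_false(anyNA(k3))
  expect_error(simulate_covariates(adj, K = 1, spatial_mix = 1.2), "spatial_mix")
})

test_that("null generator yields SIRs around 1 and exact determinism", {
  st <- make_study(8, 8, K = 0, betas = numeric(), sigma_u = 0, sigma_v = 0,
                   baseline = 0.05, mean_pop = 2000, seed = 3,
                   exclusion_fractions = c(0, 0))
  panel <- study_panel(st)
  ## with all effects zero, total O/E -> 1 within 3 Poisson SDs
  expect_equal(sum(panel$O), sum(panel$E), tolerance = 1e-9)
  expect_lt(abs(mean(panel$SIR) - 1), 3 * sqrt(1 / mean(panel$E) / nrow(panel)) * 3)

  st2 <- make_study(8, 8, K = 0, betas = numeric(), sigma_u = 0, sigma_v = 0,
                    baseline = 0.05, mean_pop = 2000, seed = 3,
                    exclusion_fractions = c(0, 0))
  expect_identical(st$records, st2$records)
})

test_that("exclusion flags respect their binomial rates and the bookkeeping recounts", {
  st <- make_study(10, 10, K = 0, betas = numeric(), sigma_u = 0, sigma_v = 0,
                   baseline = 0.05, mean_pop = 2000, seed = 9,
                   exclusion_fractions = c(0.02, 0.05))
  bk <- st$truth$bookkeeping
  n <- bk$n_persons
  ## 99% binomial bounds around n * f
  bounds <- function(f) qbinom(c(0.005, 0.995), n, f)
  expect_true(bk$persons_no_fixed_abode >= bounds(0.02)[1] &&
                bk$persons_no_fixed_abode <= bounds(0.02)[2])
  expect_true(bk$persons_out_of_region >= bounds(0.05)[1] &&
                bk$persons_out_of_region <= bounds(0.05)[2])

  ## bookkeeping equals a recount over the emitted records
  expect_equal(sum(is.na(st$records$area_id)), bk$records_no_fixed_abode)
  expect_equal(sum(grepl("^OUT", st$records$area_id)), bk$records_out_of_region)
  per_person <- table(st$records$person_id)
  expect_equal(as.integer(per_person[names(bk$episodes_per_person)]),
               unname(bk$episodes_per_person))
})

test_that("repeat_dispersion = 0 gives exactly one record per person", {
  st <- make_study(4, 4, K = 0, betas = numeric(), sigma_u = 0, sigma_v = 0,
                   baseline = 0.03, mean_pop = 500, seed = 2,
                   repeat_dispersion = 0)
  expect_true(all(table(st$records$person_id) == 1L))
})

test_that("generator rejects mismatched inputs", {
  g <- make_lattice(4, 4)
  pop <- simulate_population(g, seed = 1)
  other <- simulate_covariates(make_lattice(2, 3)$adjacency, K = 1, seed = 1)
  expect_error(
    simulate_episodes(pop, other, synthetic_truth(0, 0.1, 0, 0), g$adjacency),
    "area sets")
  expect_error(synthetic_truth(sigma_u = -1), "sigma")
})

test_that("structured-effect draws are centred with the stated conditional scale", {
  adj <- make_lattice(10, 10)$adjacency
  set.seed(31)
  v <- bymsir:::ricar(adj, 0.3)
  expect_lt(abs(sum(v)), 1e-9)
  ## centred ICAR: pairwise-difference quadratic form has E[S] = rank * sigma^2
  edges <- adjacency_edges(adj)
  S <- mean(replicate(50, {
    vv <- bymsir:::ricar(adj, 0.3)
    sum((vv[edges[, 1]] - vv[edges[, 2]])^2)
  }))
  expect_equal(S, (adj$n - 1) * 0.3^2, tolerance = 0.15)
})
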