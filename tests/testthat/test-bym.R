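## A single moderate fit shared across several blocks (computed once).
shared <- local({
  st <- make_study(8, 8, K = 2, betas = c(0.25, -0.15), sigma_u = 0.1,
                   sigma_v = 0.2, baseline = 0.04, mean_pop = 1500, seed = 101)
  panel <- study_panel(st)
  model <- build_model(panel, build_design(st$cov), st$adj)
  fit <- run_mcmc(model, n_chains = 3, n_iter = 12000, n_burnin = 6000,
                  thin = 3, seed = 55)
  list(st = st, panel = panel, model = model, fit = fit)
})

test_that("model construction validates and echoes its inputs", {
  m0 <- build_model(shared$panel, NULL, shared$st$adj)
  expect_equal(m0$K, 0L)
  expect_equal(length(m0$O), 64L)
  expect_equal(shared$model$K, 2L)
  expect_equal(shared$model$icar_rank, 63L)  # connected lattice: N - 1

  bad <- shared$panel; bad$E[1] <- 0
  expect_error(build_model(bad, NULL, shared$st$adj), "positive")
  expect_error(build_model(shared$panel[-1, ], NULL, shared$st$adj),
               "area sets")
})

test_that("chains converge and the sampler respects its constraints", {
  rh <- gelman_rubin_fit(shared$fit)
  expect_true(all(rh < 1.2))
  for (ch in shared$fit$chains) {
    ## identification: v sums to zero at every stored iteration
    expect_lt(max(abs(rowSums(ch$v))), 1e-9)
    ## prior support respected
    expect_true(all(ch$sigma_u > 0 & ch$sigma_u < 5))
    expect_true(all(ch$sigma_v > 0 & ch$sigma_v < 5))
    ## eta is the assembled linear predictor
    i <- nrow(ch$eta)
    eta_i <- ch$alpha[i] + as.vector(shared$model$X %*% ch$beta[i, ]) +
      ch$u[i, ] + ch$v[i, ]
    expect_equal(unname(ch$eta[i, ]), eta_i, tolerance = 1e-9)
  }
})

test_that("smoothing shrinks raw SIRs toward 1, hardest where E is smallest", {
  s <- summarize_fit(shared$fit)
  raw <- shared$panel$SIR[match(s$areas$area_id, shared$panel$area_id)]
  expect_lt(var(s$areas$SIR_smooth), var(raw))
  ## credible intervals bracket the point estimate
  expect_true(all(s$areas$CrI_lo <= s$areas$SIR_smooth + 1e-9))
  expect_true(all(s$areas$SIR_smooth <= s$areas$CrI_hi + 1e-9))
  expect_true(all(s$areas$prob_gt1 >= 0 & s$areas$prob_gt1 <= 1))
})

test_that("known covariate effects are recovered within credible bounds", {
  s <- summarize_fit(shared$fit)
  truth_rr <- exp(c(0.25, -0.15))
  expect_true(all(s$rr$CrI_lo <= truth_rr & truth_rr <= s$rr$CrI_hi))
})

test_that("draw export is a complete long-format table", {
  f <- tempfile(fileext = ".csv.gz")
  export_draws(shared$fit, f)
  d <- read.csv(f)
  S <- length(shared$fit$chains[[1]]$alpha)
  expect_equal(nrow(d), 3L * S * 5L)  # alpha, 2 sigmas, 2 betas
  expect_equal(sort(unique(d$parameter)),
               c("alpha", "beta1", "beta2", "sigma_u", "sigma_v"))
  a11 <- d$value[d$parameter == "alpha" & d$chain == 1]
  expect_equal(a11, unname(shared$fit$chains[[1]]$alpha))
})

test_that("Gelman-Rubin matches the textbook formula and flags non-mixing", {
  set.seed(66)
  draws <- matrix(rnorm(3000), 1000, 3)
  n <- nrow(draws)
  W <- mean(apply(draws, 2, var))
  B <- n * var(colMeans(draws))
  oracle <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(gelman_rubin(draws), oracle, tolerance = 1e-10)

  ## one chain's draws permuted: no between-chain spread
  c1 <- rnorm(500)
  expect_lt(gelman_rubin(cbind(c1, sample(c1))), 1 + 1e-6)

  ## two chains at disjoint plateaus
  expect_gt(gelman_rubin(cbind(rnorm(500), rnorm(500, 10))), 1.2)

  expect_warning(r <- gelman_rubin(cbind(rep(1, 50), rep(1, 50))), "undefined")
  expect_true(is.na(r))
  expect_error(gelman_rubin(matrix(1:20, ncol = 1)), "2 chains")
})

test_that("DIC components follow their definitions", {
  ## degenerate posterior: all draws identical -> pD = 0, DIC = D(theta)
  O <- c(3L, 7L); E <- c(2, 8)
  eta <- matrix(c(0.1, -0.2), nrow = 200, ncol = 2, byrow = TRUE)
  f <- fake_fit(list(eta, eta), O, E)
  d <- dic(f)
  expect_equal(d$pD, 0, tolerance = 1e-9)
  mu <- E * exp(c(0.1, -0.2))
  expect_equal(d$DIC, -2 * sum(O * log(mu) - mu - lgamma(O + 1)),
               tolerance = 1e-9)

  ## single area with O = 1, mu = 1: deviance contribution is exactly 2
  f1 <- fake_fit(list(matrix(0, 200, 1), matrix(0, 200, 1)), 1L, 1)
  expect_equal(dic(f1)$DIC, 2, tolerance = 1e-9)
})

test_that("posterior summaries match a sort-based percentile oracle", {
  set.seed(77)
  eta <- matrix(rnorm(600, 0, 0.3), 300, 2)
  f <- fake_fit(list(eta, eta + 0), c(5L, 5L), c(5, 5))
  s <- summarize_fit(f)
  th <- exp(rbind(eta, eta))
  for (a in 1:2) {
    srt <- sort(th[, a])
    expect_equal(s$areas$SIR_smooth[a], mean(th[, a]), tolerance = 1e-12)
    expect_equal(s$areas$CrI_lo[a],
                 as.numeric(quantile(srt, 0.025)), tolerance = 1e-12)
    expect_equal(s$areas$prob_gt1[a], mean(th[, a] > 1), tolerance = 1e-12)
  }
  ## symmetric draws around log theta = 0: Pr straddles 1/2
  expect_lt(abs(s$areas$prob_gt1[1] - 0.5), 0.1)
})

test_that("with variances pinned near zero the model collapses to the global ratio", {
  st <- make_study(6, 6, K = 0, betas = numeric(), sigma_u = 0, sigma_v = 0,
                   baseline = 0.04, mean_pop = 1000, seed = 202)
  panel <- study_panel(st)
  model <- build_model(panel, NULL, st$adj,
                       priors = list(sd_upper_u = 1e-3, sd_upper_v = 1e-3))
  fit <- run_mcmc(model, n_chains = 2, n_iter = 4000, n_burnin = 2000,
                  thin = 2, seed = 8)
  a <- c(fit$chains[[1]]$alpha, fit$chains[[2]]$alpha)
  target <- log(sum(panel$O) / sum(panel$E))
  expect_lt(abs(mean(a) - target), 3 * mcse_batch(a))
  ## posterior theta concentrates at the global O/E ratio (= 1 internally)
  s <- summarize_fit(fit)
  expect_lt(max(abs(s$areas$SIR_smooth - 1)), 0.02)
})

test_that("variance partitioning behaves at its limits", {
  expect_equal(variance_explained(shared$fit, shared$fit), 0)
  m0 <- build_model(shared$panel, NULL, shared$st$adj)
  f0 <- run_mcmc(m0, n_chains = 2, n_iter = 4000, n_burnin = 2000, thin = 2,
                 seed = 9)
  p <- variance_explained(f0, shared$fit)
  expect_true(p >= 0 && p <= 1)
  expect_gt(p, 0.2)  # covariates drive most of the simulated log-risk variance
})

test_that("quartile coding matches a sort-based oracle and the check runs", {
  x <- shared$st$cov$cov1
  res <- quartile_linearity_check(shared$panel, x, shared$st$adj,
                                  n_chains = 2, n_iter = 2000, n_burnin = 1000,
                                  thin = 2, seed = 4)
  qs <- quantile(x, c(0.25, 0.5, 0.75), type = 7)
  oracle <- 1L + (x > qs[1]) + (x > qs[2]) + (x > qs[3])
  expect_equal(res$quartile, as.integer(oracle))
  expect_true(is.finite(res$delta_dic))
  expect_error(quartile_linearity_check(shared$panel, rep(c(1, 1, 1, 2), 16),
                                        shared$st$adj),
               "tied|degenerate")
})
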