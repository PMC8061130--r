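## Shared fixtures: all synthetic, built in code at test time.

## A small simulated study: lattice, populations, covariates, episodes.
make_study <- function(nrows = 8, ncols = 8, K = 2,
                       betas = c(0.2, -0.1), sigma_u = 0.1, sigma_v = 0.2,
                       baseline = 0.03, mean_pop = 800, seed = 42, ...) {
  geo <- make_lattice(nrows, ncols)
  adj <- geo$adjacency
  pop <- simulate_population(geo, mean_area_pop = mean_pop, seed = seed)
  cov <- if (K > 0) simulate_covariates(adj, K = K, seed = seed) else NULL
  sim <- simulate_episodes(pop, cov, synthetic_truth(0, betas, sigma_u, sigma_v),
                           adj, baseline_rates = baseline, seed = seed, ...)
  list(geo = geo, adj = adj, pop = pop, cov = cov,
       records = sim$records, truth = sim$truth)
}

## Records -> (area_id, O, E, SIR) panel.
study_panel <- function(st) {
  exc <- apply_exclusions(st$records, st$adj$ids)
  idx <- dedup_index_episodes(exc$kept)
  strat <- stratify_counts(idx, st$adj$ids)
  raw_sir(expected_counts(strat$counts, st$pop))
}

## Naive O(N^2) double-loop Moran's I (independent oracle).
moran_bruteforce <- function(values, adj) {
  W <- adjacency_matrix(adj)
  z <- values - mean(values)
  n <- length(z)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

## Monte-Carlo standard error by batch means.
mcse_batch <- function(x, n_batches = 20) {
  m <- floor(length(x) / n_batches)
  means <- vapply(seq_len(n_batches), function(b)
    mean(x[((b - 1) * m + 1):(b * m)]), numeric(1))
  sd(means) / sqrt(n_batches)
}

## Hand-built minimal bym_fit (for testing dic/summaries in isolation).
fake_fit <- function(eta_draws_by_chain, O, E, X = matrix(0, length(O), 0)) {
  chains <- lapply(eta_draws_by_chain, function(eta) {
    mu <- sweep(exp(eta), 2, E, `*`)
    dev <- apply(mu, 1, function(m)
      -2 * sum(ifelse(O > 0, O * log(m), 0) - m - lgamma(O + 1)))
    list(alpha = rowMeans(eta), beta = matrix(0, nrow(eta), 0),
         sigma_u = rep(0.1, nrow(eta)), sigma_v = rep(0.1, nrow(eta)),
         u = eta * 0, v = eta * 0, eta = eta, deviance = dev,
         acceptance = c(alpha = 0.4, beta = NA, u = 0.4, v = 0.4))
  })
  structure(list(chains = chains,
                 model = list(area_id = paste0("A", seq_along(O)),
                              O = as.integer(O), E = E, X = X, K = ncol(X)),
                 n_chains = length(chains), n_iter = NA, n_burnin = NA,
                 thin = 1, seed = 1),
            class = "bym_fit")
}
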