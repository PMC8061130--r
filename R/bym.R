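## Besag-York-Mollie disease mapping: model construction, the multi-chain
## MCMC driver around the compiled sampler, convergence diagnostics, DIC,
## posterior summaries (smoothed SIRs, exceedance probabilities, rate
## ratios), variance partitioning and the quartile-vs-linear check.

#' Build a BYM Poisson model specification
#'
#' Assembles observed and expected counts, an optional standardised
#' covariate matrix and a symmetric contiguity structure into the model
#' `O_i ~ Poisson(E_i * theta_i)`,
#' `log theta_i = alpha + sum_k beta_k x_ik + u_i + v_i`,
#' with `u` exchangeable normal and `v` intrinsic CAR, identified by
#' sum-to-zero centring of `v` with a free intercept.  Omitting `X` gives
#' the constant-only model.
#'
#' @param panel data.frame `(area_id, O, E)` from [expected_counts()];
#'   `E > 0` required for every modelled area.
#' @param X numeric matrix of standardised covariates with rows matching
#'   `panel$area_id` (or `NULL`); a list as returned by [build_design()] is
#'   also accepted.
#' @param adjacency a [adjacency_structure()] over the same areas; islands
#'   get `v_i = 0`.
#' @param priors list: `sd_upper_u`, `sd_upper_v` (upper bounds of the
#'   Uniform(0, upper) priors on the random-effect SDs, default 5) and
#'   `beta_sd` (SD of the vague normal prior on `alpha` and `beta`,
#'   default 100).
#' @return object of class `bym_model`.
#' @export
build_model <- function(panel, X = NULL, adjacency,
                        priors = list()) {
  stopifnot(inherits(adjacency, "bymsir_adjacency"))
  stop_if(!setequal(panel$area_id, adjacency$ids),
          "panel and adjacency area sets differ")
  panel <- panel[match(adjacency$ids, panel$area_id), , drop = FALSE]
  stop_if(any(panel$E <= 0), "all expected counts must be positive")
  stop_if(any(panel$O < 0) || any(panel$O != round(panel$O)),
          "observed counts must be non-negative integers")
  if (is.list(X) && !is.null(X$X)) {
    stop_if(!setequal(X$area_id, adjacency$ids), "design area set mismatch")
    X <- X$X[match(adjacency$ids, X$area_id), , drop = FALSE]
  }
  if (!is.null(X)) {
    X <- as.matrix(X)
    stop_if(nrow(X) != adjacency$n, "X rows must match the number of areas")
    stop_if(anyNA(X), "X must not contain missing values")
    off <- apply(X, 2, function(c) abs(mean(c)) > 1e-6 || abs(stats::sd(c) - 1) > 0.1)
    if (any(off))
      warning("covariate column(s) not standardised: ",
              paste(colnames(X)[off], collapse = ", "))
  } else X <- matrix(0, adjacency$n, 0L)
  p <- list(sd_upper_u = 5, sd_upper_v = 5, beta_sd = 100)
  p[names(priors)] <- priors
  ## ICAR rank: non-island areas minus number of connected components
  comp <- icar_components(adjacency)
  rank <- sum(lengths(adjacency$nb) > 0L) - comp$n_components
  structure(list(area_id = adjacency$ids,
                 O = as.integer(panel$O), E = as.numeric(panel$E),
                 X = X, K = ncol(X), adjacency = adjacency,
                 icar_rank = rank, priors = p),
            class = "bym_model")
}

## connected components among non-island areas (for the ICAR rank)
icar_components <- function(adj) {
  n <- adj$n
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L || length(adj$nb[[s]]) == 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[i] != 0L) next
      comp[i] <- cur
      stack <- c(stack, adj$nb[[i]][comp[adj$nb[[i]]] == 0L])
    }
  }
  list(membership = comp, n_components = cur)
}

#' @export
print.bym_model <- function(x, ...) {
  cat(sprintf("BYM Poisson model: %d areas, %d covariate(s), ICAR rank %d\n",
              length(x$O), x$K, x$icar_rank))
  invisible(x)
}

#' Run the BYM MCMC sampler
#'
#' Runs `n_chains` independent chains of single-site adaptive random-walk
#' Metropolis (on the intercept, coefficients and both random-effect
#' vectors) with slice-sampled standard deviations; proposal scales adapt
#' toward 44% acceptance during burn-in only.  Chains start from
#' overdispersed seed-derived states.
#'
#' @param model a [build_model()] object.
#' @param n_chains number of chains (>= 2, needed for the Gelman-Rubin
#'   diagnostic).
#' @param n_iter,n_burnin,thin iterations per chain, burn-in, thinning
#'   (defaults 20000 / 10000 / 5).
#' @param seed integer master seed; chain seeds are derived from it.
#' @return object of class `bym_fit`: per-chain draw matrices for `alpha`,
#'   `beta`, `sigma_u`, `sigma_v`, `u`, `v`, `eta` (log relative risk) and
#'   `deviance`, plus acceptance rates and run metadata.
#' @export
run_mcmc <- function(model, n_chains = 3, n_iter = 20000, n_burnin = 10000,
                     thin = 5, seed = 1) {
  stopifnot(inherits(model, "bym_model"))
  stop_if(n_chains < 2, "at least 2 chains required for convergence checks")
  stop_if(n_iter <= n_burnin, "n_iter must exceed n_burnin")
  free <- lengths(model$adjacency$nb) > 0L
  alpha_hat <- log(sum(model$O) / sum(model$E))
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    chains[[ch]] <- with_seed(derive_seed(seed, 1000L * ch), {
      ## overdispersed initial state
      alpha0 <- alpha_hat + stats::rnorm(1, 0, 0.5)
      beta0 <- stats::rnorm(model$K, 0, 0.3)
      up_u <- min(1, model$priors$sd_upper_u)
      up_v <- min(1, model$priors$sd_upper_v)
      su0 <- stats::runif(1, 0.02 * up_u, up_u)
      sv0 <- stats::runif(1, 0.02 * up_v, up_v)
      u0 <- stats::rnorm(length(model$O), 0, su0)
      v0 <- stats::rnorm(length(model$O), 0, sv0)
      v0[!free] <- 0
      if (any(free)) v0[free] <- v0[free] - mean(v0[free])
      bym_chain_cpp(model$O, model$E, model$X, model$adjacency$nb,
                    adjacency_edges(model$adjacency), model$icar_rank,
                    as.integer(n_iter), as.integer(n_burnin), as.integer(thin),
                    model$priors$sd_upper_u, model$priors$sd_upper_v,
                    model$priors$beta_sd,
                    alpha0, beta0, u0, v0, su0, sv0)
    })
  }
  structure(list(chains = chains, model = model,
                 n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                 thin = thin, seed = seed),
            class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  cat(sprintf("BYM fit: %d chains x %d stored draws (%d areas, %d covariates)\n",
              x$n_chains, length(x$chains[[1]]$alpha),
              length(x$model$O), x$model$K))
  rh <- gelman_rubin_fit(x)
  cat(sprintf("max R-hat over monitored parameters: %.3f\n", max(rh)))
  invisible(x)
}

## pooled draws of a scalar/series across chains
pool <- function(fit, what, col = NULL) {
  do.call(c, lapply(fit$chains, function(ch)
    if (is.null(col)) ch[[what]] else ch[[what]][, col]))
}

#' Export posterior draws as a long-format CSV
#'
#' Writes the monitored scalar parameters (intercept, coefficients, both
#' SDs) one row per draw in `(parameter, chain, iter, value)` layout;
#' gzip-compressed when the path ends in `.gz`.
#'
#' @param fit a [run_mcmc()] result.
#' @param path output file (`.csv` or `.csv.gz`).
#' @export
export_draws <- function(fit, path) {
  stopifnot(inherits(fit, "bym_fit"))
  rows <- lapply(seq_len(fit$n_chains), function(ch) {
    cc <- fit$chains[[ch]]
    S <- length(cc$alpha)
    pars <- cbind(alpha = cc$alpha, sigma_u = cc$sigma_u, sigma_v = cc$sigma_v)
    if (fit$model$K > 0) {
      bet <- cc$beta
      colnames(bet) <- paste0("beta", seq_len(fit$model$K))
      pars <- cbind(pars, bet)
    }
    data.frame(parameter = rep(colnames(pars), each = S),
               chain = ch, iter = rep(seq_len(S), ncol(pars)),
               value = as.vector(pars))
  })
  out <- do.call(rbind, rows)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes `R-hat = sqrt(((n - 1)/n * W + B/n) / W)` from the
#' between-chain variance `B` (`n * var` of chain means) and the mean
#' within-chain variance `W`.  Values above 1.2 indicate poor convergence.
#'
#' @param draws numeric matrix, one column per chain (>= 2 columns, >= 10
#'   rows).
#' @return scalar R-hat (`NA` with a warning when all chains have zero
#'   within-chain variance).
#' @export
gelman_rubin <- function(draws) {
  draws <- as.matrix(draws)
  stop_if(ncol(draws) < 2L, "at least 2 chains required")
  stop_if(nrow(draws) < 10L, "chains too short")
  n <- nrow(draws)
  W <- mean(apply(draws, 2, stats::var))
  if (W == 0) {
    warning("zero within-chain variance in all chains; R-hat undefined")
    return(NA_real_)
  }
  B <- n * stats::var(colMeans(draws))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' R-hat for all monitored parameters of a fit
#'
#' Monitors the intercept, every coefficient and both standard deviations.
#'
#' @param fit a [run_mcmc()] result.
#' @return named numeric vector of R-hat values.
#' @export
gelman_rubin_fit <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  grab <- function(what, col = NULL)
    gelman_rubin(vapply(fit$chains, function(ch)
      if (is.null(col)) ch[[what]] else ch[[what]][, col],
      numeric(length(fit$chains[[1]]$alpha))))
  out <- c(alpha = grab("alpha"), sigma_u = grab("sigma_u"),
           sigma_v = grab("sigma_v"))
  if (fit$model$K > 0)
    out <- c(out, stats::setNames(
      vapply(seq_len(fit$model$K), function(k) grab("beta", k), numeric(1)),
      paste0("beta", seq_len(fit$model$K))))
  out
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance and
#' `pD = Dbar - D(plug-in)`, the plug-in evaluated at the posterior means of
#' the linear predictor terms.  The deviance includes the `log(O_i!)`
#' constant, so absolute values are reproducible while differences are
#' unaffected.  Lower DIC indicates better fit.
#'
#' @param fit a [run_mcmc()] result.
#' @return list `(Dbar, pD, DIC, n_dropped)`; draws with non-finite deviance
#'   are excluded and counted.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  dev <- pool(fit, "deviance")
  bad <- !is.finite(dev)
  if (any(bad)) warning(sprintf("%d draw(s) with non-finite deviance excluded", sum(bad)))
  dev <- dev[!bad]
  stop_if(length(dev) < 100L, "need at least 100 post-burn-in draws")
  Dbar <- mean(dev)
  eta_bar <- Reduce(`+`, lapply(fit$chains, function(ch) colMeans(ch$eta))) /
    fit$n_chains
  mu <- fit$model$E * exp(eta_bar)
  O <- fit$model$O
  Dhat <- -2 * sum(ifelse(O > 0, O * log(mu), 0) - mu - lgamma(O + 1))
  pD <- Dbar - Dhat
  list(Dbar = Dbar, pD = pD, DIC = Dbar + pD, n_dropped = sum(bad))
}

#' Posterior summaries: smoothed SIRs, exceedance probabilities, rate ratios
#'
#' Pools post-burn-in draws across chains.  Point estimates are posterior
#' means (medians by flag); 95% credible intervals are the 2.5/97.5
#' percentiles; `Pr(SIR > 1)` is the fraction of draws with relative risk
#' above one.  Rate ratios are `exp(beta_k)` per 1 SD of covariate `k`.
#'
#' @param fit a [run_mcmc()] result.
#' @param point `"mean"` (default) or `"median"`.
#' @return list with `areas` (data.frame `area_id`, `SIR_smooth`, `CrI_lo`,
#'   `CrI_hi`, `prob_gt1`), `rr` (data.frame `covariate`, `RR`, `CrI_lo`,
#'   `CrI_hi`), and `hyper` (posterior summaries of `alpha`, `sigma_u`,
#'   `sigma_v`).
#' @export
summarize_fit <- function(fit, point = c("mean", "median")) {
  stopifnot(inherits(fit, "bym_fit"))
  point <- match.arg(point)
  est <- if (point == "mean") mean else stats::median
  theta <- exp(do.call(rbind, lapply(fit$chains, function(ch) ch$eta)))
  areas <- data.frame(
    area_id = fit$model$area_id,
    SIR_smooth = apply(theta, 2, est),
    CrI_lo = apply(theta, 2, stats::quantile, probs = 0.025, names = FALSE),
    CrI_hi = apply(theta, 2, stats::quantile, probs = 0.975, names = FALSE),
    prob_gt1 = colMeans(theta > 1),
    stringsAsFactors = FALSE)
  rr <- NULL
  if (fit$model$K > 0) {
    B <- do.call(rbind, lapply(fit$chains, function(ch) ch$beta))
    rr <- data.frame(
      covariate = colnames(fit$model$X) %||% paste0("x", seq_len(fit$model$K)),
      RR = apply(exp(B), 2, est),
      CrI_lo = apply(exp(B), 2, stats::quantile, probs = 0.025, names = FALSE),
      CrI_hi = apply(exp(B), 2, stats::quantile, probs = 0.975, names = FALSE),
      stringsAsFactors = FALSE)
  }
  hyp <- function(x) c(est = est(x),
                       lo = stats::quantile(x, 0.025, names = FALSE),
                       hi = stats::quantile(x, 0.975, names = FALSE))
  hyper <- rbind(alpha = hyp(pool(fit, "alpha")),
                 sigma_u = hyp(pool(fit, "sigma_u")),
                 sigma_v = hyp(pool(fit, "sigma_v")))
  list(areas = areas, rr = rr, hyper = as.data.frame(hyper))
}

#' Proportion of geographical variability explained by covariates
#'
#' Geographical variability of a model is measured as the empirical variance
#' across areas of the posterior means of the total random effect
#' `u_i + v_i`.  The proportion explained by the covariates is
#' `1 - var(full) / var(constant-only)`, clipped to `[0, 1]` with a warning
#' when negative.
#'
#' @param null_fit,full_fit [run_mcmc()] results for the constant-only and
#'   covariate-adjusted models on identical `O`, `E` and adjacency.
#' @return scalar proportion in `[0, 1]`.
#' @export
variance_explained <- function(null_fit, full_fit) {
  stopifnot(inherits(null_fit, "bym_fit"), inherits(full_fit, "bym_fit"))
  stop_if(!identical(null_fit$model$O, full_fit$model$O) ||
            !identical(null_fit$model$E, full_fit$model$E),
          "models must be fitted to identical O and E")
  re_var <- function(fit) {
    uv <- Reduce(`+`, lapply(fit$chains, function(ch)
      colMeans(ch$u) + colMeans(ch$v))) / fit$n_chains
    stats::var(uv)
  }
  vn <- re_var(null_fit); vf <- re_var(full_fit)
  stop_if(vn < 1e-12, "constant-only model shows no geographical variability")
  p <- 1 - vf / vn
  if (p < 0) {
    warning("full model shows more residual variability than the null; clipped to 0")
    p <- 0
  }
  min(p, 1)
}

#' Compare quartile vs continuous coding of a single covariate by DIC
#'
#' Fits two single-covariate BYM models - one with the covariate as a
#' linear (z-score) term, one with its quartiles as three indicator terms -
#' and returns both DICs.  A negative `delta_dic` (continuous minus
#' quartile) favours the linear specification.
#'
#' @param panel data.frame `(area_id, O, E)`.
#' @param covariate numeric vector over the panel's areas (raw scale).
#' @param adjacency a [adjacency_structure()].
#' @param ... passed to [run_mcmc()] (e.g. `n_iter`, `seed`).
#' @return list `(dic_continuous, dic_quartile, delta_dic, quartile)` where
#'   `quartile` is the per-area quartile assignment (1-4).
#' @export
quartile_linearity_check <- function(panel, covariate, adjacency, ...) {
  stop_if(length(covariate) != nrow(panel), "covariate length must match panel")
  qs <- stats::quantile(covariate, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  stop_if(any(duplicated(qs)), "tied quartile breaks: quartile coding degenerate")
  quart <- findInterval(covariate, qs) + 1L
  Xc <- matrix(standardise_z(covariate), ncol = 1,
               dimnames = list(NULL, "linear"))
  Xq <- cbind(q2 = as.numeric(quart == 2L),
              q3 = as.numeric(quart == 3L),
              q4 = as.numeric(quart == 4L))
  fit_c <- run_mcmc(suppressWarnings(build_model(panel, Xc, adjacency)), ...)
  fit_q <- run_mcmc(suppressWarnings(build_model(panel, Xq, adjacency)), ...)
  dc <- dic(fit_c)$DIC; dq <- dic(fit_q)$DIC
  list(dic_continuous = dc, dic_quartile = dq, delta_dic = dc - dq,
       quartile = quart)
}
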