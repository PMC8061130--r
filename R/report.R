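## Map-ready exports: seven-class divergent choropleth classification,
## exceedance flagging, cartogram scaling weights, and the end-to-end
## pipeline driver.

#' Seven-class divergent classification of SIR values
#'
#' Assigns each value to one of seven classes defined by six break points,
#' using half-open intervals `[lo, hi)`.  The default breaks
#' `{0.50, 0.75, 0.90, 1.11, 1.33, 2.00}` are symmetric on the log scale
#' around 1, so reciprocal SIRs fall in mirrored classes; class 4 is the
#' "near-average" band.  Intended for a divergent red-blue colour ramp.
#'
#' @param values finite numeric values (SIRs or probabilities).
#' @param breaks strictly increasing numeric vector of six break points (a
#'   different length yields a different class count).
#' @param palette colour ramp identifier stored with the classification.
#' @return object of class `bymsir_classification`: data.frame `value`,
#'   `class` (1..7), plus attributes `breaks` and `palette`.
#' @export
classify_sir <- function(values, breaks = c(0.50, 0.75, 0.90, 1.11, 1.33, 2.00),
                         palette = "RdBu") {
  stop_if(any(!is.finite(values)), "all values must be finite")
  stop_if(is.unsorted(breaks, strictly = TRUE), "breaks must be strictly increasing")
  cls <- findInterval(values, breaks, left.open = FALSE) + 1L
  out <- data.frame(value = values, class = cls)
  structure(out, breaks = breaks, palette = palette,
            class = c("bymsir_classification", class(out)))
}

#' Areas with high posterior probability of above-average risk
#'
#' Flags the areas whose exceedance probability `Pr(SIR > 1)` is strictly
#' greater than the threshold (default 0.8).
#'
#' @param probs probabilities in `[0, 1]`.
#' @param threshold strict lower bound (default 0.8).
#' @param ids optional area ids to return instead of indices.
#' @return indices (or ids) of flagged areas.
#' @export
exceedance_map <- function(probs, threshold = 0.8, ids = NULL) {
  stop_if(any(probs < 0 | probs > 1, na.rm = TRUE), "probabilities must lie in [0, 1]")
  idx <- which(probs > threshold)
  if (is.null(ids)) idx else ids[idx]
}

#' Cartogram scaling weights from episode counts
#'
#' Per-area weights proportional to the index episode counts, normalised to
#' mean 1 (so they sum to the number of areas).  Only the weights are
#' produced; density-equalising geometry is left to external cartogram
#' tools.
#'
#' @param counts non-negative per-area episode counts, not all zero.
#' @return numeric weights with `mean(w) == 1`.
#' @export
cartogram_weights <- function(counts) {
  stop_if(any(counts < 0), "counts must be non-negative")
  stop_if(sum(counts) == 0, "all counts are zero; weights undefined")
  counts / mean(counts)
}

#' Run the full synthetic-to-results pipeline
#'
#' Executes simulate -> prepare -> standardise -> covariates -> spatial ->
#' fit -> report, writing every artefact (CSV tables, GeoJSON with joined
#' results, JSON diagnostics) plus a manifest with MD5 checksums into
#' `outdir`.  Re-running with the same config and seed reproduces the
#' checksums.
#'
#' @param config list (or path to a YAML file) with optional entries:
#'   `nrows`, `ncols` (lattice size), `K` (covariates), `betas`, `sigma_u`,
#'   `sigma_v`, `baseline_rate`, `mean_area_pop`, `repeat_dispersion`,
#'   `exclusion_fractions`, `n_chains`, `n_iter`, `n_burnin`, `thin`,
#'   `seed`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the manifest path and key in-memory
#'   results (`panel`, `summaries`, `diagnostics`).
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("bymsir_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- list(nrows = 8, ncols = 8, K = 2,
              betas = c(0.2, -0.1), sigma_u = 0.1, sigma_v = 0.2,
              baseline_rate = 0.015, mean_area_pop = 1470,
              repeat_dispersion = 0.3, exclusion_fractions = c(0.02, 0.05),
              n_chains = 3, n_iter = 4000, n_burnin = 2000, thin = 2,
              seed = 1)
  cfg[names(config)] <- config
  stop_if(length(cfg$betas) != cfg$K,
          "config error: `betas` must have length `K`")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(stage) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), stage))

  log_msg("simulate")
  geo <- make_lattice(cfg$nrows, cfg$ncols)
  adj <- geo$adjacency
  pop <- simulate_population(geo, mean_area_pop = cfg$mean_area_pop, seed = cfg$seed)
  cov <- simulate_covariates(adj, K = cfg$K, seed = cfg$seed)
  sim <- simulate_episodes(pop, cov,
                           synthetic_truth(0, cfg$betas, cfg$sigma_u, cfg$sigma_v),
                           adj, baseline_rates = cfg$baseline_rate,
                           repeat_dispersion = cfg$repeat_dispersion,
                           exclusion_fractions = cfg$exclusion_fractions,
                           seed = cfg$seed)
  utils::write.csv(sim$records, file.path(outdir, "episodes.csv"), row.names = FALSE)
  utils::write.csv(pop, file.path(outdir, "populations.csv"), row.names = FALSE)
  utils::write.csv(cov, file.path(outdir, "covariates.csv"), row.names = FALSE)
  write_geojson(geo$features, file.path(outdir, "geography.geojson"))

  log_msg("prepare")
  exc <- apply_exclusions(sim$records, adj$ids)
  idx <- dedup_index_episodes(exc$kept)
  strat <- stratify_counts(idx, adj$ids)
  utils::write.csv(strat$counts, file.path(outdir, "counts.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(exc$ledger), file.path(outdir, "exclusion_ledger.json"),
                       auto_unbox = TRUE)

  log_msg("standardise")
  panel <- raw_sir(expected_counts(strat$counts, pop))
  utils::write.csv(panel, file.path(outdir, "sir.csv"), row.names = FALSE)

  log_msg("covariates")
  design <- build_design(cov)
  utils::write.csv(data.frame(area_id = design$area_id, design$X),
                   file.path(outdir, "design.csv"), row.names = FALSE)
  vifs <- if (cfg$K >= 2) vif(as.data.frame(design$X)) else NULL

  log_msg("spatial")
  write_adjacency(adj, file.path(outdir, "adjacency.csv"))
  pop_tot <- stats::aggregate(count ~ area_id, pop, sum)
  pop_tot <- pop_tot[match(adj$ids, pop_tot$area_id), ]
  mi <- moran_eb(panel$O[match(adj$ids, panel$area_id)], pop_tot$count, adj,
                 seed = derive_seed(cfg$seed, 7L))

  log_msg("fit")
  fit <- run_mcmc(build_model(panel, design, adj),
                  n_chains = cfg$n_chains, n_iter = cfg$n_iter,
                  n_burnin = cfg$n_burnin, thin = cfg$thin, seed = cfg$seed)
  summ <- summarize_fit(fit)
  diag <- list(rhat = as.list(gelman_rubin_fit(fit)), dic = dic(fit),
               moran_I_eb = mi$I, moran_p = mi$p_value,
               acceptance = lapply(fit$chains, function(ch) as.list(ch$acceptance)))

  log_msg("report")
  utils::write.csv(summ$areas, file.path(outdir, "sir_smoothed.csv"), row.names = FALSE)
  if (!is.null(summ$rr))
    utils::write.csv(summ$rr, file.path(outdir, "rate_ratios.csv"), row.names = FALSE)
  cls <- classify_sir(summ$areas$SIR_smooth)
  flagged <- exceedance_map(summ$areas$prob_gt1, ids = summ$areas$area_id)
  cw <- cartogram_weights(panel$O[match(adj$ids, panel$area_id)])
  props <- data.frame(area_id = summ$areas$area_id,
                      O = panel$O[match(summ$areas$area_id, panel$area_id)],
                      SIR_raw = panel$SIR[match(summ$areas$area_id, panel$area_id)],
                      SIR_smooth = summ$areas$SIR_smooth,
                      prob_gt1 = summ$areas$prob_gt1,
                      class7 = cls$class,
                      cartogram_weight = cw)
  write_geojson(geo$features, file.path(outdir, "results.geojson"), props)
  jsonlite::write_json(c(diag, list(exceedance_areas = as.list(flagged),
                                    vif = as.list(vifs))),
                       file.path(outdir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- sort(setdiff(list.files(outdir), "manifest.txt"))
  sums <- tools::md5sum(file.path(outdir, files))
  writeLines(sprintf("%s  %s", sums, files), file.path(outdir, "manifest.txt"))
  invisible(list(outdir = outdir, manifest = file.path(outdir, "manifest.txt"),
                 panel = panel, summaries = summ, diagnostics = diag,
                 truth = sim$truth))
}
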