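# bymsir

Bayesian disease mapping of small-area self-harm incidence: from
episode-level records to smoothed standardised incidence ratios (SIRs),
exceedance probabilities, spatial autocorrelation statistics and ecological
regression rate ratios, via a from-scratch MCMC implementation of the
Besag–York–Mollié (BYM) Poisson model.

## Who it is for

Epidemiologists and health-geography analysts studying the spatial
distribution of rare events (here, hospital-presenting self-harm) across
small census areas of ~1500 residents, where raw rates are too noisy to map
directly and area-level correlates (deprivation, social fragmentation,
ethnicity, service access) are of substantive interest. Because such
episode-level records are confidential, the package includes a
synthetic-data generator with known ground truth that emulates the full
study design, so every stage is testable end to end.

## The model

For area *i* with observed index-episode count *O<sub>i</sub>* and expected
count *E<sub>i</sub>* (indirect sex/age standardisation over 5-year bands):

    O_i ~ Poisson(E_i * theta_i)
    log theta_i = alpha + sum_k beta_k * x_ik + u_i + v_i
    u_i ~ N(0, sigma_u^2)                       (unstructured)
    v   ~ ICAR(adjacency, sigma_v^2)            (structured, sum-to-zero)
    alpha, beta_k ~ N(0, 100^2);  sigma_u, sigma_v ~ Uniform(0, 5)

Smoothed SIRs are posterior means of *theta<sub>i</sub>*; `Pr(SIR > 1)` is
the exceedance probability; `exp(beta_k)` is the rate ratio per 1 SD of
covariate *k*. Inference is single-site adaptive Metropolis-within-Gibbs
(C++ core) with slice-sampled standard deviations, Gelman–Rubin R̂
diagnostics and DIC for model comparison. Spatial clustering of rates is
measured by Moran's I with the Assunção–Reis empirical-Bayes adjustment for
unequal population sizes and permutation p-values.

## A worked example

```r
library(bymsir)
res <- run_pipeline(list(nrows = 8, ncols = 8, K = 2, seed = 1,
                         n_iter = 4000, n_burnin = 2000))
res$diagnostics$moran_I_eb
#> [1] 0.5391202
head(subset(res$summaries$areas, prob_gt1 > 0.8), 4)
#>    area_id SIR_smooth    CrI_lo   CrI_hi  prob_gt1
#> 10    A010   1.155907 0.9534673 1.424440 0.9316667
#> 17    A017   1.171566 0.9336806 1.429657 0.9216667
#> 25    A025   1.294532 1.0696913 1.585477 0.9936667
#> 26    A026   1.268851 1.0285137 1.522259 0.9833333
res$summaries$rr
#>   covariate        RR    CrI_lo    CrI_hi
#> 1      cov1 1.2454511 1.1493587 1.3434197
#> 2      cov2 0.8854592 0.8208011 0.9809539
```

This simulates an 8×8-area municipality (true covariate log rate ratios
0.2 and −0.1 per SD), reduces the simulated episode records to index
episodes, standardises, fits the constant-only-and-covariate BYM model and
writes map-ready artefacts. The rate-ratio table shows both true effects
recovered inside their 95% credible intervals; `moran_I_eb` is the
population-adjusted Moran's I of the simulated SIR surface (positive, as
the generator embeds spatial structure); areas with `prob_gt1 > 0.8` are
the ones an exceedance map would flag as having above-average risk with
high posterior probability.

Key functions by stage: `make_lattice`, `simulate_population`,
`simulate_covariates`, `simulate_episodes` (synthetic data);
`apply_exclusions`, `dedup_index_episodes`, `classify_method`,
`stratify_counts` (episode reduction); `expected_counts`, `raw_sir`,
`mid90_ratio` (standardisation); `standardise_z`, `townsend_index`,
`fragmentation_index`, `spearman_matrix`, `vif`, `vif_prune` (covariates);
`adjacency_from_polygons`, `moran_classic`, `moran_eb` (spatial);
`build_model`, `run_mcmc`, `summarize_fit`, `dic`, `gelman_rubin_fit`,
`variance_explained`, `quartile_linearity_check` (BYM); `classify_sir`,
`exceedance_map`, `cartogram_weights`, `run_pipeline` (reporting). See the
vignette in `vignettes/` for the model, conventions and design choices.

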