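---
title: "Small-area disease mapping of self-harm incidence with bymsir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area disease mapping of self-harm incidence with bymsir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bymsir)
```

## The problem

Hospital presentations for self-harm cluster geographically, and identifying
small areas with genuinely elevated incidence matters for prevention and for
resource allocation. At the scale of census small areas (roughly 1500
residents each) the raw evidence is thin: over a decade a typical area
contributes a few dozen index episodes, so crude standardised incidence
ratios (SIRs) are dominated by Poisson noise, and the most extreme-looking
areas are usually just the smallest ones. `bymsir` implements the complete
analytical chain for this setting:

1. reduce episode-level records to one **index episode** per person, with an
   auditable ledger of exclusions (events outside the study window, ages
   below 10, no fixed abode, residence outside the study region);
2. compute **expected counts** by indirect sex/age standardisation over
   5-year bands and raw SIRs;
3. assemble area-level covariates: z-scores (log-transformed first where
   skewed), the **Townsend deprivation index** and **Congdon social
   fragmentation score** as sums of four component z-scores each, Spearman
   correlations and variance inflation factors;
4. quantify spatial clustering with **Moran's I**, including the
   empirical-Bayes variant that adjusts for unequal population sizes;
5. fit the **Besag–York–Mollié (BYM)** hierarchical Poisson model by MCMC to
   obtain smoothed SIRs, exceedance probabilities, covariate rate ratios,
   DIC and convergence diagnostics;
6. export map-ready classifications, exceedance flags and cartogram weights.

Because episode-level health records of this kind are confidential and not
publicly deposited, the package ships a synthetic-data generator that
emulates the study design — a municipality of a few hundred small areas with
stratified populations, spatially autocorrelated covariates, known covariate
effects and random-effect fields, repeat episodes, and records that trigger
each exclusion rule — so the whole chain is testable against known ground
truth.

## The model

For area $i = 1, \dots, N$ with observed index-episode count $O_i$ and
expected count $E_i$,

$$O_i \sim \text{Poisson}(E_i \theta_i), \qquad
\log \theta_i = \alpha + \sum_k \beta_k x_{ik} + u_i + v_i,$$

where $x_{ik}$ are covariates standardised to mean 0 and unit
(population-)SD, $u_i \sim N(0, \sigma_u^2)$ captures unstructured
heterogeneity, and $v$ follows the intrinsic conditional autoregressive
(ICAR) prior over the contiguity graph: conditionally,
$v_i \mid v_{-i} \sim N(\bar v_{\partial i},\, \sigma_v^2 / m_i)$ with
$m_i$ the number of neighbours. Neighbours are areas sharing a boundary
segment of positive length (rook contiguity on a lattice; polygons touching
only at a corner do not qualify). Priors are vague: $\alpha, \beta_k \sim
N(0, 100^2)$ and $\sigma_u, \sigma_v \sim \text{Uniform}(0, 5)$ on the
standard-deviation scale.

$\theta_i$ is the area's relative risk; its posterior mean is the smoothed
SIR, $\Pr(\theta_i > 1)$ the exceedance probability, and
$\exp(\beta_k)$ the rate ratio per 1 SD of covariate $k$.

### Identification of the ICAR field

The intrinsic prior is improper (invariant to adding a constant), so after
every sweep the sampler subtracts the mean of $v$ (over non-island areas)
and adds it to $\alpha$ — the linear predictor is unchanged, $v$ sums to
zero at every stored draw, and the intercept is free. Areas with no
neighbours keep $v_i = 0$ with a warning, the convention of the classic
BUGS `car.normal` implementation. The ICAR "density" used for
$\sigma_v$ has rank $N_{\text{connected}} - c$ (areas with neighbours minus
the number of connected components), which the model object computes from
the graph.

## The sampler and its numerical choices

Inference is a from-scratch Metropolis-within-Gibbs scheme, implemented in
C++ for speed:

* single-site adaptive random-walk Metropolis updates for $\alpha$, each
  $\beta_k$, each $u_i$ and each $v_i$ on the log-relative-risk scale. Each
  proposal scale adapts every 50 iterations toward an acceptance rate of
  0.44 (the univariate optimum), with step sizes shrinking as
  $\min(0.05, 1/\sqrt{b})$; adaptation is frozen at the end of burn-in so
  the post-burn-in chain satisfies detailed balance;
* joint scale moves $(u, \sigma_u) \to (c\,u, c\,\sigma_u)$ (and likewise
  for $v$), with $\log c$ a small adaptive Gaussian step. The Gaussian
  prior terms cancel against the Jacobian up to $\log c$, so the move
  leaves the posterior invariant while letting the whole random-effect
  field rescale in one step — without it, the SDs decorrelate from their
  fields only through a slow random walk, a well-known weakness of
  single-site BYM samplers;
* $\sigma_u$ and $\sigma_v$ are updated by shrinkage slice sampling of
  their full conditionals on $(0, 5)$, which is rejection-free and needs no
  tuning;
* chains start from overdispersed states (intercept jittered around
  $\log(\sum O / \sum E)$, random coefficients, random SDs), each derived
  deterministically from the master seed, so the Gelman–Rubin statistic is
  a meaningful convergence check;
* a non-finite Poisson mean aborts the chain with the offending area
  reported, rather than propagating NaNs.

Defaults are 3 chains of 20 000 iterations, 10 000 burn-in, thinning 5 —
enough that on the validation problems below every monitored parameter
(intercept, coefficients, both SDs) has $\hat R < 1.02$. The posterior
point estimate is the mean (the median is available), and 95% credible
intervals are 2.5/97.5 percentiles of the pooled draws.

DIC is computed as $\bar D + p_D$ with $p_D = \bar D - D(\hat\eta)$, the
plug-in deviance evaluated at the posterior mean of the linear predictor
(the standard choice for this model class, where the plug-in parameterisation
is a genuine convention decision). The deviance retains the $\log O_i!$
constant so absolute DIC values are reproducible; differences are
unaffected.

The proportion of geographical variability explained by covariates is
$1 - \mathrm{var}(\hat u + \hat v \mid \text{full}) /
\mathrm{var}(\hat u + \hat v \mid \text{constant-only})$, where
$\mathrm{var}$ is the empirical variance across areas of the posterior-mean
total random effect. The estimator behind the published "variance
explained" summaries of such models is rarely stated explicitly; this
definition is pinned here and in the tests.

## The synthetic generator

`make_lattice()` builds an $r \times c$ grid of unit squares (rook
contiguity by default, queen by flag) standing in for an irregular
small-area geography. `simulate_population()` draws area totals log-normally
around a mean of 1470 residents aged 10+ (coefficient of variation 0.15,
giving the narrow interquartile spread typical of census-designed areas)
and allocates them multinomially over sex and 5-year age bands with a
gently declining age profile. `simulate_covariates()` mixes a
neighbour-averaged smoothed white-noise field (a documented surrogate for a
structured Gaussian field) with independent noise; with mixing weight 0.7
the fields show the clear positive spatial autocorrelation census
covariates exhibit.

`simulate_episodes()` draws person-level index events Poisson per stratum
under the multiplier $\exp(\alpha + \sum\beta_k x_{ik} + u_i + v_i)$. The
structured field $v$ is an *exact* centred ICAR draw (via the
eigendecomposition of the graph Laplacian restricted to its positive
eigenspace), so recovery tests target exactly the prior the model assumes.
Repeat episodes per person are geometric with configurable mean — the
within-person distribution of repeats is not identified by any downstream
quantity (only their removal matters), so a simple stand-in is preferred
and flagged as such. A configurable fraction of persons is flagged no fixed
abode (missing area) or out of region (alien area code); the generator's
bookkeeping records flagged persons, flagged records, per-person episode
counts and per-area index tallies, which the exclusion ledger and count
tables must reproduce exactly. Method labels (possibly composite, e.g.
"poisoning;cutting") are multinomial; classification collapses them by a
lethality precedence — poisoning over hanging/traffic over cutting over
low-lethality methods — into the three reporting bins
poisoning/cutting/other. Only the poisoning-over-cutting rule is canonical;
the rest of the ordering is a configurable documented default.

What the generator does **not** emulate: realistic age–incidence curves
(rates are flat across strata by default), calendar-time trends, irregular
polygon geographies, or spatially varying data-quality artefacts. Passing
tests therefore demonstrate the correctness of the algorithms under the
stated generating model, not robustness to every feature of real surveillance
data.

## Validation problem sizes

The test-suite and the reproduction script use problem sizes chosen to make
Monte-Carlo properties checkable while each fit remains a few seconds:
parameter recovery runs 20 replicates on a 16×16 lattice (256 areas,
$E_i \approx 60$, truth $\beta = (\log 1.2,\, 0,\, -\log 1.15)$,
$\sigma_u = 0.1$, $\sigma_v = 0.3$) at the full default run length; DIC
model-selection and variance-partition checks use 8×8 lattices with
shorter, pre-converged runs. Across recovery replicates the 95% CrIs cover
each true coefficient at nominal-like frequency and all $\hat R < 1.2$.

## Other conventions worth knowing

* **Quantiles** everywhere (mid-90% ratio, credible intervals, quartile
  coding) use linear interpolation of order statistics, R's type-7 default;
  the mid-90% ratio is the 95th/5th percentile of area SIRs.
* **z-scores** divide by the population SD ($n$ denominator), pinned by
  tests; composite indices are insensitive to this up to a constant factor.
* The automatic log rule transforms a covariate when its sample skewness
  exceeds 1 (or when listed explicitly); zero values are shifted by a
  configurable offset (default 0.5) before the log.
* **Moran's I** uses binary, row-unnormalised contiguity weights by
  default (a row-standardised variant is a flag); permutation p-values are
  $(\text{count}+1)/(n_{\text{perm}}+1)$ with 999 permutations and a
  two-sided default — the neighbourhood convention is stated rather than
  inherited, since published analyses rarely spell it out. The
  empirical-Bayes adjustment is the Assunção–Reis standardisation
  $z_i = (r_i - b)/\sqrt{a + b/n_i}$ with $a = s^2 - b/\bar n$ floored at
  zero; note it is *not* exactly invariant to scaling counts and
  populations by a common factor — the $b/n_i$ term shrinks — but converges
  to classic Moran's I on the raw rates as populations grow, which the
  tests assert.
* **Choropleth classification** uses seven classes with default SIR breaks
  $\{0.50, 0.75, 0.90, 1.11, 1.33, 2.00\}$ — symmetric on the log scale
  around 1 so reciprocal risks fall in mirrored classes — with half-open
  $[lo, hi)$ intervals and a named divergent red–blue ramp; exceedance maps
  flag areas with $\Pr(\theta_i > 1)$ strictly above 0.8. Cartogram
  exports are per-area weights proportional to index-episode counts
  (mean 1); density-equalising geometry itself is out of scope.
* Subgroup SIRs (by sex, broad age group, or method) reuse the same
  standardisation machinery with the subgroup's own internal reference by
  default; whether published subgroup analyses used subgroup-internal or
  whole-population references is usually ambiguous, so the reference is an
  argument.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
res <- run_pipeline(list(nrows = 8, ncols = 8, K = 2, seed = 1,
                         n_iter = 4000, n_burnin = 2000))
head(res$summaries$areas)
res$summaries$rr
res$diagnostics$moran_I_eb
```

`run_pipeline()` executes simulate → prepare → standardise → covariates →
spatial → fit → report, writing every artefact (CSV tables, GeoJSON with
joined results, JSON diagnostics) and a checksum manifest; identical config
and seed reproduce the manifest bit-for-bit.

## Known limitations

* The MCMC is single-site; for very strong spatial confounding between a
  covariate and the ICAR field, mixing of the affected $\beta_k$ slows and
  longer runs are needed (watch $\hat R$).
* The ICAR variance is only weakly identified when the likelihood is flat
  ($E_i$ very small everywhere); the Uniform(0, 5) prior then matters.
* `variance_explained()` is a descriptive contrast of posterior-mean random
  effects, not a formal decomposition; when the constant-only model already
  shows almost no geographical variability, the proportion is undefined and
  reported as such.
* Exact-arithmetic contiguity suits synthetic lattices; real-world polygon
  sets need the length tolerance loosened to their coordinate precision.
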