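## Synthetic study generator: lattice geography, stratified populations,
## spatially correlated covariates and episode-level records with known
## ground truth.  Emulates the scale of a ~258-area municipality (small
## census areas of median population ~1470 aged 10+) so every downstream
## stage can be validated without confidential records.

#' Default 5-year age bands from 10-14 upward
#'
#' @param max_age lower bound of the open-ended top band (default 85+).
#' @return character vector of band labels, e.g. `"10-14"`, ..., `"85+"`.
#' @export
age_bands_5yr <- function(max_age = 85) {
  lo <- seq(10, max_age - 5, by = 5)
  c(paste(lo, lo + 4, sep = "-"), paste0(max_age, "+"))
}

## Map integer ages to band labels; ages below the first band give NA.
age_to_band <- function(age, bands = age_bands_5yr()) {
  lo <- as.integer(sub("[-+].*$", "", bands))
  idx <- findInterval(age, lo)
  out <- rep(NA_character_, length(age))
  out[idx >= 1L] <- bands[idx[idx >= 1L]]
  out
}

## Uniform age draw within a band (top band gets a 10-year span).
band_age_range <- function(band) {
  if (grepl("\\+$", band)) {
    lo <- as.integer(sub("\\+$", "", band)); c(lo, lo + 9L)
  } else {
    as.integer(strsplit(band, "-", fixed = TRUE)[[1]])
  }
}

#' Regular lattice geography of unit-square areas
#'
#' Builds an `nrows x ncols` grid of unit squares with rook (shared-edge)
#' contiguity by default, standing in for an irregular small-area geography.
#'
#' @param nrows,ncols positive grid dimensions with `nrows * ncols >= 4`.
#' @param contiguity `"rook"` (shared edge) or `"queen"` (edge or corner).
#' @return a `bymsir_geography` list: `areas` (data.frame with `area_id`,
#'   `row`, `col`), `features` (per-area closed polygon rings, GeoJSON-ready),
#'   and `adjacency` (a [adjacency_structure()]).
#' @examples
#' g <- make_lattice(4, 4)
#' lengths(g$adjacency$nb)[1]  # a corner cell has 2 rook neighbours
#' @export
make_lattice <- function(nrows, ncols, contiguity = c("rook", "queen")) {
  contiguity <- match.arg(contiguity)
  stop_if(!is.numeric(nrows) || !is.numeric(ncols) || nrows < 1 || ncols < 1 ||
            nrows != round(nrows) || ncols != round(ncols),
          "nrows and ncols must be positive integers")
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  stop_if(nrows * ncols < 4L, "lattice must contain at least 4 areas")
  idx <- function(r, c) (r - 1L) * ncols + c
  n <- nrows * ncols
  rr <- rep(seq_len(nrows), each = ncols)
  cc <- rep(seq_len(ncols), times = nrows)
  ids <- sprintf("A%03d", seq_len(n))
  areas <- data.frame(area_id = ids, row = rr, col = cc, stringsAsFactors = FALSE)
  features <- lapply(seq_len(n), function(i) {
    x0 <- cc[i] - 1; y0 <- rr[i] - 1
    list(area_id = ids[i],
         ring = cbind(c(x0, x0 + 1, x0 + 1, x0, x0),
                      c(y0, y0, y0 + 1, y0 + 1, y0)))
  })
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    r <- rr[i]; c <- cc[i]
    cand <- list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
    if (contiguity == "queen")
      cand <- c(cand, list(c(r - 1L, c - 1L), c(r - 1L, c + 1L),
                           c(r + 1L, c - 1L), c(r + 1L, c + 1L)))
    keep <- vapply(cand, function(p) p[1] >= 1L && p[1] <= nrows &&
                     p[2] >= 1L && p[2] <= ncols, logical(1))
    nb[[i]] <- vapply(cand[keep], function(p) idx(p[1], p[2]), integer(1))
  }
  structure(list(areas = areas, features = features,
                 adjacency = adjacency_structure(ids, nb)),
            class = "bymsir_geography")
}

#' @export
print.bymsir_geography <- function(x, ...) {
  cat(sprintf("Lattice geography: %d areas\n", nrow(x$areas)))
  invisible(x)
}

#' Simulate stratified area populations
#'
#' Area totals are drawn log-normally around `mean_area_pop` (coefficient of
#' variation ~0.15, matching the narrow interquartile range typical of
#' census-designed small areas), then allocated multinomially across
#' sex x age-band strata with a gently declining age profile.
#'
#' @param geography a `bymsir_geography` (or any object with
#'   `$areas$area_id`).
#' @param age_bands character vector of 5-year band labels (see
#'   [age_bands_5yr()]).
#' @param mean_area_pop mean area population aged 10+ (default 1470, a
#'   typical small-area median).
#' @param seed integer seed.
#' @param cv coefficient of variation of area totals.
#' @return data.frame with columns `area_id`, `sex` (`"male"`/`"female"`),
#'   `age_band`, `count` (non-negative integers).
#' @export
simulate_population <- function(geography, age_bands = age_bands_5yr(),
                                mean_area_pop = 1470, seed = 1, cv = 0.15) {
  stop_if(length(age_bands) < 1L, "at least one age band required")
  stop_if(mean_area_pop <= 0, "mean_area_pop must be positive")
  ids <- geography$areas$area_id
  nb_bands <- length(age_bands)
  ## mild monotone decline with age; both sexes equal a priori
  w_age <- exp(-0.08 * seq_len(nb_bands))
  w <- as.vector(outer(w_age, c(0.5, 0.5)))  # band x sex
  w <- w / sum(w)
  strata <- expand.grid(age_band = age_bands, sex = c("male", "female"),
                        stringsAsFactors = FALSE)
  with_seed(derive_seed(seed, 101L), {
    sdlog <- sqrt(log(1 + cv^2))
    totals <- round(stats::rlnorm(length(ids),
                                  meanlog = log(mean_area_pop) - sdlog^2 / 2,
                                  sdlog = sdlog))
    totals <- pmax(totals, length(w))
    counts <- vapply(totals, function(tt) as.integer(stats::rmultinom(1, tt, w)),
                     integer(length(w)))
    data.frame(area_id = rep(ids, each = nrow(strata)),
               sex = rep(strata$sex, times = length(ids)),
               age_band = rep(strata$age_band, times = length(ids)),
               count = as.integer(counts),
               stringsAsFactors = FALSE)
  })
}

## Smoothed white-noise field over an adjacency: s passes of
## neighbour-averaging, then centred and scaled to unit SD.  A surrogate for
## a spatially structured Gaussian field (not an exact ICAR draw); used for
## covariate fields.
smooth_field <- function(adj, smooth_iters = 10L) {
  x <- stats::rnorm(adj$n)
  for (s in seq_len(smooth_iters)) {
    xn <- x
    for (i in seq_len(adj$n)) {
      if (length(adj$nb[[i]]))
        xn[i] <- (x[i] + sum(x[adj$nb[[i]]])) / (1 + length(adj$nb[[i]]))
    }
    x <- xn
  }
  as.vector(scale(x))
}

## Exact draw from the centred intrinsic CAR prior with conditional SD
## sigma_v (conditional variance sigma_v^2 / m_i), via eigendecomposition of
## the graph Laplacian restricted to its non-null space.  Islands get 0.
ricar <- function(adj, sigma_v) {
  n <- adj$n
  if (sigma_v == 0) return(numeric(n))
  W <- adjacency_matrix(adj)
  Q <- diag(rowSums(W)) - W
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > 1e-8 * max(eg$values)
  z <- stats::rnorm(sum(pos))
  v <- as.vector(eg$vectors[, pos, drop = FALSE] %*% (z / sqrt(eg$values[pos]))) * sigma_v
  v[lengths(adj$nb) == 0L] <- 0
  keep <- lengths(adj$nb) > 0L
  v[keep] <- v[keep] - mean(v[keep])
  v
}

#' Simulate spatially correlated area covariates
#'
#' Each covariate is a mixture `spatial_mix * smooth_field +
#' (1 - spatial_mix) * white_noise`, rescaled to a plausible percentage-like
#' range.  With `spatial_mix > 0.5` the field shows clear positive spatial
#' autocorrelation, emulating census covariates such as deprivation
#' components.
#'
#' @param adjacency a [adjacency_structure()].
#' @param K number of covariates (>= 1).
#' @param spatial_mix weight in `[0, 1]` on the spatially smooth component.
#' @param seed integer seed.
#' @param smooth_iters neighbour-averaging passes for the smooth component.
#' @param centre,scale location and spread of the raw (percentage-like)
#'   values.
#' @return data.frame with `area_id` and columns `cov1..covK`; no missing
#'   values.
#' @export
simulate_covariates <- function(adjacency, K, spatial_mix = 0.7, seed = 1,
                                smooth_iters = 10L, centre = 30, scale = 10) {
  stop_if(K < 1, "K must be >= 1")
  stop_if(spatial_mix < 0 || spatial_mix > 1, "spatial_mix must lie in [0, 1]")
  with_seed(derive_seed(seed, 202L), {
    out <- data.frame(area_id = adjacency$ids, stringsAsFactors = FALSE)
    for (k in seq_len(K)) {
      sm <- if (spatial_mix > 0) smooth_field(adjacency, smooth_iters) else numeric(adjacency$n)
      eps <- stats::rnorm(adjacency$n)
      x <- spatial_mix * sm + (1 - spatial_mix) * eps
      x <- as.vector(scale(x)) * scale + centre
      out[[paste0("cov", k)]] <- x
    }
    out
  })
}

#' Ground-truth parameter set for the synthetic generator
#'
#' Bundles the log-scale intercept, per-covariate log rate ratios (per 1 SD),
#' and the standard deviations of the unstructured and structured
#' (intrinsic CAR) area random effects.  Realised effects and record-level
#' bookkeeping are filled in by [simulate_episodes()].
#'
#' @param intercept log-rate offset applied on top of the stratum baselines.
#' @param betas numeric vector of log rate ratios per 1 SD of each covariate.
#' @param sigma_u SD of the unstructured (exchangeable normal) effects, >= 0.
#' @param sigma_v conditional SD of the structured intrinsic-CAR effects,
#'   >= 0.
#' @return object of class `bymsir_truth`.
#' @export
synthetic_truth <- function(intercept = 0, betas = numeric(), sigma_u = 0,
                            sigma_v = 0) {
  stop_if(sigma_u < 0 || sigma_v < 0, "sigma_u and sigma_v must be >= 0")
  structure(list(intercept = intercept, betas = as.numeric(betas),
                 sigma_u = sigma_u, sigma_v = sigma_v,
                 u = NULL, v = NULL, bookkeeping = NULL),
            class = "bymsir_truth")
}

#' Simulate episode-level self-harm records with known ground truth
#'
#' Person-level index events are drawn Poisson per stratum with area rate
#' multiplier `exp(intercept + sum(beta_k x_ik) + u_i + v_i)` applied to the
#' supplied per-sex/band baseline rates; `u` is iid normal, `v` an exact
#' centred intrinsic-CAR draw over the adjacency.  Each person receives a
#' geometric number of extra repeat episodes (mean `repeat_dispersion`).
#' Independently, a person is flagged "no fixed abode" (area id missing) or
#' "out of region" (area id outside the geography) with the stated
#' probabilities; all the person's records carry the flag.
#'
#' @param populations stratum population table from [simulate_population()].
#' @param covariates covariate table from [simulate_covariates()] (or `NULL`
#'   for no covariate effects).
#' @param truth a [synthetic_truth()]; its `betas` length must match the
#'   covariate columns.
#' @param adjacency the [adjacency_structure()] used for the structured
#'   effects.
#' @param baseline_rates data.frame `(sex, age_band, rate)` of per-person
#'   event probabilities over the study window, or a single number applied to
#'   every stratum.
#' @param repeat_dispersion mean number of extra (repeat) episodes per
#'   person; 0 means exactly one record per person.
#' @param exclusion_fractions length-2 numeric `(no_fixed_abode,
#'   out_of_region)`, each in `[0, 1)` and summing to < 1.
#' @param study_window Date vector of length 2 (first/last event date).
#' @param method_probs named probabilities over raw method labels; names may
#'   be composite, `"+"`-separated label sets.
#' @param seed integer seed.
#' @return list with `records` (data.frame: `person_id`, `event_date`, `sex`,
#'   `age`, `area_id`, `method`) and `truth` (the completed `bymsir_truth`
#'   with realised `u`, `v` and `bookkeeping`: flagged person/record counts,
#'   per-person episode counts, and the per-area index-event tally for
#'   in-region persons).
#' @export
simulate_episodes <- function(populations, covariates, truth, adjacency,
                              baseline_rates = 0.015, repeat_dispersion = 0.3,
                              exclusion_fractions = c(0.02, 0.05),
                              study_window = as.Date(c("2003-01-01", "2013-12-31")),
                              method_probs = c(poisoning = 0.70, cutting = 0.15,
                                               hanging = 0.02, traffic = 0.01,
                                               hitting = 0.02, head_banging = 0.01,
                                               "poisoning+cutting" = 0.06,
                                               "cutting+hanging" = 0.03),
                              seed = 1) {
  stopifnot(inherits(truth, "bymsir_truth"))
  stop_if(any(exclusion_fractions < 0) || any(exclusion_fractions >= 1) ||
            sum(exclusion_fractions) >= 1,
          "exclusion fractions must lie in [0, 1) and sum to < 1")
  ids <- adjacency$ids
  stop_if(!setequal(unique(populations$area_id), ids),
          "population and adjacency area sets differ")
  K <- length(truth$betas)
  if (K > 0L) {
    stop_if(is.null(covariates), "truth has betas but no covariates supplied")
    stop_if(!setequal(covariates$area_id, ids),
            "covariate and adjacency area sets differ")
    covariates <- covariates[match(ids, covariates$area_id), , drop = FALSE]
    X <- as.matrix(covariates[, setdiff(names(covariates), "area_id"), drop = FALSE])
    stop_if(ncol(X) != K, "length(betas) must match covariate columns")
    X <- scale(X) * sqrt(nrow(X) / (nrow(X) - 1))  # population-SD z-scores
  } else X <- matrix(0, length(ids), 0L)

  if (is.numeric(baseline_rates) && is.null(dim(baseline_rates)) &&
      length(baseline_rates) == 1L) {
    strata <- unique(populations[, c("sex", "age_band")])
    baseline_rates <- data.frame(strata, rate = baseline_rates)
  }
  stop_if(any(baseline_rates$rate < 0), "baseline rates must be >= 0")

  with_seed(derive_seed(seed, 303L), {
    u <- stats::rnorm(length(ids), 0, truth$sigma_u)
    v <- ricar(adjacency, truth$sigma_v)
    eta <- truth$intercept + as.vector(X %*% truth$betas) + u + v
    mult <- exp(eta)

    pop <- merge(populations, baseline_rates, by = c("sex", "age_band"))
    stop_if(nrow(pop) != nrow(populations),
            "baseline_rates missing a stratum present in populations")
    pop$mult <- mult[match(pop$area_id, ids)]
    lambda <- pop$count * pop$rate * pop$mult
    n_persons <- stats::rpois(nrow(pop), lambda)
    tot <- sum(n_persons)

    area <- rep(pop$area_id, n_persons)
    sex <- rep(pop$sex, n_persons)
    band <- rep(pop$age_band, n_persons)
    person_id <- sprintf("P%06d", seq_len(tot))
    age <- vapply(band, function(b) {
      r <- band_age_range(b); sample(r[1]:r[2], 1L)
    }, integer(1))
    ndays <- as.integer(study_window[2] - study_window[1])
    date0 <- study_window[1] + sample.int(ndays + 1L, tot, replace = TRUE) - 1L

    ## exclusion flags at the person level
    flag <- sample(c("keep", "nfa", "oor"), tot, replace = TRUE,
                   prob = c(1 - sum(exclusion_fractions), exclusion_fractions))
    area[flag == "nfa"] <- NA_character_
    area[flag == "oor"] <- paste0("OUT", sprintf("%03d", seq_len(sum(flag == "oor"))))

    ## repeat episodes: geometric extra count with mean repeat_dispersion
    extra <- if (repeat_dispersion > 0)
      stats::rgeom(tot, prob = 1 / (1 + repeat_dispersion)) else integer(tot)
    reps <- extra + 1L
    take <- rep(seq_len(tot), reps)
    offs <- unlist(lapply(reps, function(r) c(0L, if (r > 1L)
      sort(sample.int(ndays, r - 1L, replace = TRUE)))), use.names = FALSE)
    dates <- pmin(date0[take] + offs, study_window[2])
    meth <- sample(names(method_probs), length(take), replace = TRUE,
                   prob = method_probs)
    records <- data.frame(person_id = person_id[take],
                          event_date = dates,
                          sex = sex[take], age = age[take],
                          area_id = area[take],
                          method = gsub("+", ";", meth, fixed = TRUE),
                          stringsAsFactors = FALSE)

    kept_person <- flag == "keep"
    index_tally <- table(factor(area[kept_person], levels = ids))
    truth$u <- u; truth$v <- v
    truth$bookkeeping <- list(
      n_persons = tot,
      n_records = nrow(records),
      persons_no_fixed_abode = sum(flag == "nfa"),
      persons_out_of_region = sum(flag == "oor"),
      records_no_fixed_abode = sum(reps[flag == "nfa"]),
      records_out_of_region = sum(reps[flag == "oor"]),
      episodes_per_person = stats::setNames(as.integer(reps), person_id),
      index_events_by_area = stats::setNames(as.integer(index_tally), ids))
    list(records = records, truth = truth)
  })
}
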