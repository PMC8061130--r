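test_that("z-scores use the population-SD convention and its invariances", {
  z <- standardise_z(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)  # +-1.2247

  set.seed(4)
  x <- runif(30)
  expect_equal(standardise_z(7 + 3 * x), standardise_z(x), tolerance = 1e-12)

  zl <- standardise_z(c(1, 10, 100), log_first = TRUE)
  expect_equal(zl, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)

  expect_error(standardise_z(rep(5, 10)), "constant")
  expect_error(standardise_z(c(-1, 2, 3), log_first = TRUE), "non-negative")
  ## zeros handled by the offset
  expect_length(standardise_z(c(0, 1, 4), log_first = TRUE), 3L)
})

test_that("composite indices equal the sum of component z-scores", {
  set.seed(12)
  n <- 40
  comp <- replicate(4, runif(n, 5, 60), simplify = FALSE)
  tw <- townsend_index(comp[[1]], comp[[2]], comp[[3]], comp[[4]])
  oracle <- Reduce(`+`, lapply(comp, standardise_z))
  expect_equal(tw, oracle, tolerance = 1e-10)
  expect_equal(fragmentation_index(comp[[1]], comp[[2]], comp[[3]], comp[[4]]),
               oracle, tolerance = 1e-10)
  expect_equal(mean(tw), 0, tolerance = 1e-9)

  ## percent vs proportion: affine rescaling of components leaves indices unchanged
  tw2 <- townsend_index(comp[[1]] / 100, comp[[2]] / 100,
                        comp[[3]] / 100, comp[[4]] / 100)
  expect_equal(tw2, tw, tolerance = 1e-10)

  ## with identical components, an area at the mean scores 0 and an area
  ## z SDs above scores 4z (so +1 SD on all four -> 4)
  x <- c(5, rep(c(4, 6), 5))  # area 1 sits exactly at the mean
  tw4 <- townsend_index(x, x, x, x)
  expect_equal(tw4[1], 0)
  expect_equal(tw4, 4 * standardise_z(x), tolerance = 1e-12)
})

test_that("spearman matrix is rank-based with mid-rank ties", {
  set.seed(3)
  x <- rnorm(20)
  tab <- data.frame(a = x, b = exp(x), c = -x)
  r <- spearman_matrix(tab)
  expect_equal(unname(r["a", "b"]), 1)
  expect_equal(unname(r["a", "c"]), -1)
  expect_true(isSymmetric(r))
  expect_true(all(diag(r) == 1))

  ## 5-point table with a tie: Pearson on mid-ranks oracle
  u <- c(1, 2, 2, 4, 5); w <- c(3, 1, 4, 2, 6)
  r2 <- spearman_matrix(data.frame(u = u, w = w))
  expect_equal(unname(r2["u", "w"]), cor(rank(u), rank(w)), tolerance = 1e-12)

  expect_warning(rc <- spearman_matrix(data.frame(a = x, k = rep(1, 20))),
                 "constant")
  expect_true(all(is.na(rc["k", ])))
})

test_that("VIF matches a brute-force OLS R-squared oracle", {
  set.seed(21)
  n <- 50
  ## mutually orthogonal centred columns -> all VIF = 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, -1]
  v1 <- vif(as.data.frame(q))
  expect_equal(unname(v1), rep(1, 3), tolerance = 1e-8)

  ## near-collinear pair
  x1 <- rnorm(n); x2 <- x1 + rnorm(n, 0, 0.01); x3 <- rnorm(n)
  v2 <- vif(data.frame(x1, x2, x3))
  expect_gt(v2["x1"], 10)

  ## random 3-covariate table vs explicit R^2 computation
  tab <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  tab$b <- tab$b + 0.5 * tab$a
  v3 <- vif(tab)
  for (k in names(tab)) {
    y <- tab[[k]]; X <- cbind(1, as.matrix(tab[setdiff(names(tab), k)]))
    res <- y - X %*% solve(crossprod(X), crossprod(X, y))
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    expect_equal(unname(v3[k]), 1 / (1 - r2), tolerance = 1e-8)
  }

  ## exact collinearity -> Inf with a flag
  expect_warning(v4 <- vif(data.frame(x1, twice = 2 * x1, x3)), "collinearity")
  expect_true(is.infinite(v4["x1"]) || is.infinite(v4["twice"]))
})

test_that("dropping the worst VIF never worsens the rest, and pruning terminates", {
  set.seed(33)
  n <- 60
  base <- matrix(rnorm(n * 3), n, 3)
  tab <- data.frame(base,
                    s1 = base[, 1] + base[, 2] + rnorm(n, 0, 0.05),
                    s2 = base[, 2] + base[, 3] + rnorm(n, 0, 0.05))
  v <- vif(tab)
  worst <- names(which.max(v))
  v_after <- vif(tab[, setdiff(names(tab), worst)])
  expect_true(all(v_after <= v[names(v_after)] + 1e-8))

  pr <- vif_prune(tab, threshold = 10)
  expect_true(all(pr$vif < 10))
  expect_true(length(pr$dropped) >= 1)
})

test_that("design builder applies the automatic log rule and standardises", {
  set.seed(44)
  tab <- data.frame(area_id = paste0("A", 1:50),
                    sym = rnorm(50, 20, 3),
                    skewed = rlnorm(50, 1, 1.2))
  d <- build_design(tab)
  expect_true("skewed" %in% d$logged)
  expect_false("sym" %in% d$logged)
  expect_lt(max(abs(colMeans(d$X))), 1e-9)
  expect_equal(unname(apply(d$X, 2, function(c) sqrt(mean(c^2)))), c(1, 1),
               tolerance = 1e-9)
})
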