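test_that("orientation applies the max(x) - x inversion and nothing else", {
  expect_equal(orient_variable(c(1, 4, 10), "inverse"), c(9, 6, 0))
  x <- c(2.5, 7, 0.1, 3)
  expect_identical(orient_variable(x, "direct"), x)
  # involution up to location: range is preserved, order restored
  twice <- orient_variable(orient_variable(x, "inverse"), "inverse")
  expect_equal(twice, x - min(x))
  expect_equal(cor(orient_variable(x, "inverse"), x, method = "spearman"), -1)
  expect_error(orient_variable(c(1, Inf), "inverse"), "finite")
})

test_that("decile scoring is uniform, monotone, and tie-safe", {
  d <- compute_deciles(1:10)
  expect_equal(d$q, 1:10)

  expect_warning(q_const <- compute_deciles(rep(5, 10))$q, "constant")
  expect_equal(q_const, rep(1L, 10))

  set.seed(7)
  x <- runif(100)
  q <- compute_deciles(x)$q
  expect_equal(as.integer(table(q)), rep(10L, 10))  # exact decile occupancy

  # monotonicity in the oriented variable
  ord <- order(x)
  expect_true(all(diff(q[ord]) >= 0))

  # permutation equivariance
  perm <- sample(100)
  expect_equal(compute_deciles(x[perm])$q, q[perm])

  # ties share the lowest admissible decile
  xt <- c(rep(1, 25), rep(2, 50), rep(3, 25))
  qt <- compute_deciles(xt)$q
  expect_length(unique(qt[xt == 2]), 1L)
})

test_that("expected counts use internal standardization exactly", {
  ec <- compute_expected_counts(cbind(c(2, 6)), c(100, 300))
  expect_equal(ec$rates, 0.02)
  expect_equal(as.numeric(ec$E), c(2, 6))

  ec2 <- compute_expected_counts(cbind(c(8, 0)), c(100, 300))
  expect_equal(ec2$rates, 0.02)
  expect_equal(as.numeric(ec2$E), c(2, 6))
  expect_equal(sum(ec2$E), 8)

  set.seed(3)
  y <- matrix(rpois(40, 4) + 1, 20, 2)
  p <- sample(50:900, 20)
  ec3 <- compute_expected_counts(y, p)
  expect_equal(colSums(ec3$E), colSums(y), tolerance = 1e-12)

  expect_error(compute_expected_counts(cbind(c(0, 0)), c(1, 2)), "zero total")
  expect_error(compute_expected_counts(cbind(c(1, 2)), c(0, 2)), "positive")
})

test_that("load_dataset drops zero-population and missing-covariate units", {
  dir <- tempfile()
  write_bundle(dir, 4, 5, zero_pop = c(1, 20), miss_cov = c(7, 10, 13))
  expect_message(
    ds <- load_dataset(file.path(dir, "units.csv"),
                       file.path(dir, "adjacency.gal")),
    "dropped 2 zero-population and 3 missing-covariate")
  expect_equal(ds$n, 15)
  expect_equal(unname(attr(ds, "exclusions")),
               c(2L, 3L))
  expect_true(is_connected(ds$adjacency))

  dir2 <- tempfile()
  write_bundle(dir2, 4, 5)
  ds2 <- load_dataset(file.path(dir2, "units.csv"),
                      file.path(dir2, "adjacency.gal"))
  expect_equal(ds2$n, 20)
})

test_that("decile design respects per-variable orientation", {
  ds <- tiny_dataset()
  dg <- decile_design(ds)
  expect_true(all(dg$q >= 1 & dg$q <= 10))
  # inverse-oriented column: deciles anticorrelated with the raw values
  j <- which(ds$orientation == "inverse")
  expect_true(cor(dg$q[, j], ds$covariates[, j], method = "spearman") < 0)
  # direct column: positively associated
  expect_true(cor(dg$q[, 1], ds$covariates[, 1], method = "spearman") > 0)
})
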