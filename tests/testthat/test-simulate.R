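test_that("covariates are right-skewed with the requested latent correlation", {
  x0 <- simulate_covariates(5000, 4, correlation = 0, seed = 1)
  c0 <- cor(log(x0))
  expect_true(max(abs(c0[upper.tri(c0)])) < 0.05)

  x5 <- simulate_covariates(5000, 4, correlation = 0.5, seed = 2)
  c5 <- cor(log(x5))
  expect_equal(mean(c5[upper.tri(c5)]), 0.5, tolerance = 0.05)

  # right-skewed nonnegative marginals, income column flagged inverse
  expect_true(all(x5 > 0))
  skew <- apply(x5, 2, function(v) mean(((v - mean(v)) / sd(v))^3))
  expect_true(all(skew > 0.5))
  expect_equal(attr(x5, "orientation"), c("direct", "direct", "direct", "inverse"))

  expect_identical(simulate_covariates(50, 3, 0.3, seed = 9),
                   simulate_covariates(50, 3, 0.3, seed = 9))
})

test_that("constrained MVCAR draws satisfy the sum-to-zero and flat limits", {
  adj <- make_lattice(5, 5)
  omega <- diag(1e6, 2)
  b <- simulate_mvcar_field(adj, omega, seed = 1)
  expect_true(all(abs(colSums(b)) < 1e-8))
  expect_true(all(apply(b, 2, sd) < 1e-2))   # precision -> infinity: flat field

  expect_error(simulate_mvcar_field(adj, matrix(c(1, 2, 2, 1), 2, 2)),
               "positive-definite")
})

test_that("K=1 path-graph MVCAR covariance equals the Laplacian pseudoinverse", {
  adj <- path_adjacency(3)
  L <- matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3)
  Lp <- MASS::ginv(L)   # independent oracle for the target covariance
  draws <- simulate_mvcar_field(adj, matrix(1, 1, 1), seed = 4, ndraws = 1e5)
  emp <- cov(t(draws[, 1, ]))
  expect_true(max(abs(emp - Lp)) < 0.05 * max(abs(Lp)))
})

test_that("MVCAR cross-component contrast covariance is proportional to Omega^-1", {
  adj <- make_lattice(3, 3)
  omega <- solve(matrix(c(1, 0.8, 0.8, 1), 2, 2))
  draws <- simulate_mvcar_field(adj, omega, seed = 5, ndraws = 1e4)
  d12 <- draws[1, , ] - draws[5, , ]       # fixed unit-pair contrast, 2 x ndraws
  emp <- cov(t(d12))
  expect_equal(emp[1, 2] / sqrt(emp[1, 1] * emp[2, 2]), 0.8, tolerance = 0.05)
})

test_that("Poisson counts have the composed mean structure", {
  n <- 1e4
  # alpha = 0, beta = 0, E = 5 everywhere -> mean 5
  y <- simulate_counts(alpha = 0, beta = matrix(0, n, 1), ndi = rep(2, n),
                       populations = rep(10, n), base_rates = 0.5, seed = 6)
  expect_equal(mean(y), 5, tolerance = 4 * sqrt(5 / n))

  # doubling via beta at the top of the index range
  ndi <- rep(c(1e-9, 4), each = n / 2)
  b <- matrix(log(2) / 4, n, 1)
  y2 <- simulate_counts(0, b, ndi, rep(10, n), 0.5, seed = 7)
  ratio <- mean(y2[ndi == 4]) / mean(y2[ndi < 1])
  expect_equal(ratio, 2, tolerance = 0.1)

  expect_error(simulate_counts(0, matrix(0, 2, 1), c(1, 1), c(0, 10), 1),
               "positive")
  expect_error(simulate_counts(40, matrix(0, 2, 1), c(1, 1), c(10, 10), 1),
               "1e12")
})

test_that("simulate_dataset is deterministic and satisfies dataset invariants", {
  cfg <- simulation_config(nrows = 5, ncols = 6, seed = 10)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(simulation_config(nrows = 5, ncols = 6, seed = 10))
  expect_identical(s1$dataset$counts, s2$dataset$counts)
  expect_identical(s1$truth$beta_true, s2$truth$beta_true)

  ds <- s1$dataset
  expect_s3_class(ds, "areal_dataset")
  expect_equal(s1$truth$ndi_true, as.numeric(s1$truth$q_true %*% s1$truth$w_true))
  expect_true(all(s1$truth$ndi_true >= 1 & s1$truth$ndi_true <= 10))
  expect_equal(sum(s1$truth$w_true), 1, tolerance = 1e-12)
})

test_that("dataset bundles round-trip through disk", {
  dir <- tempfile()
  sim <- simulate_dataset(simulation_config(nrows = 4, ncols = 5, seed = 3))
  write_dataset_bundle(sim, dir)
  ori <- setNames(sim$dataset$orientation, colnames(sim$dataset$covariates))
  ds <- load_dataset(file.path(dir, "units.csv"),
                     file.path(dir, "adjacency.gal"), orientation = ori)
  expect_equal(ds$counts, sim$dataset$counts, ignore_attr = TRUE)
  expect_equal(ds$populations, sim$dataset$populations)
  expect_equal(ds$adjacency$edges, sim$dataset$adjacency$edges)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(tr$w_true, sim$truth$w_true, tolerance = 1e-12)
})

test_that("simulation_config validates its invariants", {
  expect_error(simulation_config(true_weights = c(0.5, 0.6)), "length C")
  expect_error(simulation_config(true_weights = rep(1 / 9, 9) * 1.2), "sum to 1")
  expect_error(simulation_config(true_omega = matrix(c(1, 2, 2, 1), 2, 2)),
               "positive-definite")
  expect_error(simulation_config(covariate_correlation = 1), "\\[0, 1\\)")
})
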