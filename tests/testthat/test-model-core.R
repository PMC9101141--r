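test_that("the index is the weighted decile combination, bounded in [1, 10]", {
  q <- matrix(5, 3, 9)
  expect_equal(ndi_value(rep(1 / 9, 9), q), rep(5, 3))

  w <- c(0.5, 0.5, rep(1e-13, 7)); w <- w / sum(w)
  q2 <- matrix(c(2, 8, rep(5, 7)), 1, 9)
  expect_equal(ndi_value(w, q2), 5, tolerance = 1e-10)

  expect_error(ndi_value(c(1, rep(0, 8)), q), "open simplex")
  expect_error(ndi_value(rep(1 / 9, 9), matrix(11, 2, 9)), "1..10")
})

test_that("Poisson log-likelihood matches the textbook pmf", {
  one <- matrix(1); zero <- matrix(0)
  expect_equal(poisson_loglik(zero, one, 0, zero, 1), -1)
  expect_equal(poisson_loglik(one, one, 0, zero, 1), -1)

  set.seed(11)
  n <- 6; K <- 2
  y <- matrix(rpois(n * K, 3), n, K)
  E <- matrix(runif(n * K, 0.5, 2), n, K)
  alpha <- c(0.2, -0.1); beta <- matrix(rnorm(n * K, 0, 0.1), n, K)
  ndi <- runif(n, 1, 10)
  mu <- E * exp(sweep(beta * ndi, 2, alpha, `+`))
  expect_equal(poisson_loglik(y, E, alpha, beta, ndi),
               sum(dpois(y, mu, log = TRUE)), tolerance = 1e-12)
})

test_that("MVCAR kernel has the pairwise-difference form and shift invariance", {
  adj <- path_adjacency(3)
  omega <- matrix(2, 1, 1)
  beta <- matrix(c(0, 1, 3), 3, 1)
  k <- mvcar_logpdf_kernel(beta, omega, adj)
  expect_equal(k, (3 - 1) / 2 * log(2) - 5)   # quadratic term: -0.5*2*(1+4)

  expect_equal(mvcar_logpdf_kernel(beta + 7, omega, adj), k)
  expect_equal(mvcar_logpdf_kernel(matrix(4, 3, 1), omega, adj),
               (3 - 1) / 2 * log(2))
  expect_error(mvcar_logpdf_kernel(beta, matrix(-1, 1, 1), adj),
               "positive-definite")
})

test_that("intercept Gibbs draw targets the Gamma conditional", {
  # beta = 0, total y = 100, total E = 100 -> t ~ Gamma(100, 100)
  set.seed(2)
  n <- 50
  y <- matrix(rmultinom(1, 100, rep(1, n)), n, 1)
  E <- matrix(2, n, 1)
  draws <- replicate(4000, update_alpha(y, E, matrix(0, n, 1), rep(5, n)))
  expect_equal(mean(exp(draws)), 1, tolerance = 0.02)
  expect_equal(var(exp(draws)), 100 / 100^2, tolerance = 0.05)

  # doubling E shifts alpha by -log 2 in distribution
  set.seed(3); d1 <- replicate(2000, update_alpha(y, E, matrix(0, n, 1), rep(5, n)))
  set.seed(3); d2 <- replicate(2000, update_alpha(y, 2 * E, matrix(0, n, 1), rep(5, n)))
  expect_equal(d2, d1 - log(2), tolerance = 1e-12)

  expect_error(update_alpha(matrix(0, 3, 1), matrix(1, 3, 1),
                            matrix(0, 3, 1), rep(1, 3)), "zero total")
})

test_that("precision Gibbs draw matches the Wishart-mean oracle for a flat field", {
  adj <- make_lattice(4, 4)
  pr <- prior_spec(K = 2, C = 3, wishart_scale = diag(0.2, 2), wishart_df = 2)
  beta0 <- matrix(0, 16, 2)
  set.seed(4)
  draws <- replicate(3000, update_omega(beta0, adj, pr))
  emp_mean <- apply(draws, c(1, 2), mean)
  # beta = 0 => S = 0: Omega | . ~ Wishart(rate R, df nu + n - 1), mean df * R^-1
  theo <- (2 + 16 - 1) * solve(diag(0.2, 2))
  expect_equal(emp_mean, theo, tolerance = 0.02)
  expect_true(all(apply(draws, 3, function(m) all(eigen(m)$values > 0))))
})

test_that("the sampler is deterministic under fixed seeds and keeps invariants", {
  sim <- simulate_dataset(simulation_config(nrows = 4, ncols = 4, K = 2, C = 3,
                                            true_weights = c(0.5, 0.3, 0.2),
                                            true_omega = default_true_omega(2),
                                            mean_slopes = c(0.2, 0.2),
                                            base_rates = c(5e-3, 5e-3),
                                            seed = 8))
  ds <- sim$dataset
  dg <- decile_design(ds)
  ec <- compute_expected_counts(ds$counts, ds$populations)
  pr <- prior_spec(K = 2, C = 3)
  cfg <- mcmc_config(n_chains = 2, burn_in = 200, retained = 150, thin = 2,
                     seed = c(5, 5))
  post <- run_mcmc(ds$counts, ec$E, dg$q, ds$adjacency, pr, cfg)

  # identical seeds -> identical chains
  expect_identical(post$chains[[1]]$weights, post$chains[[2]]$weights)
  expect_identical(post$chains[[1]]$beta, post$chains[[2]]$beta)

  # bookkeeping: retained draws after thinning
  expect_equal(nrow(post$chains[[1]]$alpha), 150)

  # every stored state satisfies the invariants
  w <- post$chains[[1]]$weights
  expect_true(all(abs(rowSums(w) - 1) < 1e-9))
  expect_true(all(w > 0 & w < 1))
  expect_true(all(apply(post$chains[[1]]$omega, 1,
                        function(m) all(eigen(matrix(m, 2, 2))$values > 0))))

  # derived relative risk equals its definition, exactly
  ch <- post$chains[[1]]
  t5 <- exp(sweep(ch$beta[5, , ] * ch$ndi[5, ], 2, ch$alpha[5, ], `+`))
  expect_identical(ch$theta[5, , ], t5)

  # a different seed gives a different stream
  cfg2 <- mcmc_config(n_chains = 1, burn_in = 200, retained = 150, thin = 2,
                      seed = 6)
  post2 <- run_mcmc(ds$counts, ec$E, dg$q, ds$adjacency, pr, cfg2)
  expect_false(identical(post2$chains[[1]]$weights, post$chains[[1]]$weights))
})

test_that("a zero-width proposal leaves the coefficient field at its start", {
  ds <- tiny_dataset()
  dg <- decile_design(ds)
  ec <- compute_expected_counts(ds$counts, ds$populations)
  cfg <- mcmc_config(n_chains = 1, burn_in = 0, retained = 50, seed = 1,
                     beta_scale = 0, adapt_window = 1e9,
                     mode = "unconstrained", sample_alpha = FALSE,
                     sample_omega = FALSE, sample_weights = FALSE)
  post <- run_mcmc(ds$counts, ec$E, dg$q, ds$adjacency,
                   prior_spec(K = ds$K, C = ds$C), cfg)
  expect_true(all(post$chains[[1]]$beta == 0))
})

test_that("likelihood-weight growth concentrates the weight posterior", {
  spread <- sapply(c(1, 10, 100), function(mult) {
    cfg <- simulation_config(nrows = 5, ncols = 5, K = 1, C = 3,
                             true_weights = c(0.6, 0.3, 0.1),
                             dirichlet_alpha = rep(1, 3),
                             true_omega = default_true_omega(1),
                             intercepts = 0, mean_slopes = 0.3,
                             base_rates = 2e-3 * mult, seed = 21)
    sim <- simulate_dataset(cfg)
    dg <- decile_design(sim$dataset)
    ec <- compute_expected_counts(sim$dataset$counts, sim$dataset$populations)
    post <- run_mcmc(sim$dataset$counts, ec$E, dg$q, sim$dataset$adjacency,
                     prior_spec(K = 1, C = 3),
                     mcmc_config(n_chains = 1, burn_in = 1500, retained = 1500,
                                 seed = 31))
    mean(apply(pool_draws_test(post, "weights"), 2, sd))
  })
  expect_true(spread[2] < spread[1])
  expect_true(spread[3] < spread[2])
})
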