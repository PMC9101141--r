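test_that("Gelman-Rubin matches the classical formula", {
  # identical non-constant chains: B = 0, Rhat = sqrt((T-1)/T) < 1
  x <- sin(1:100)
  gr <- gelman_rubin(rbind(x, x))
  expect_equal(gr$B, 0)
  expect_equal(gr$rhat, sqrt(99 / 100))
  expect_true(gr$converged)

  # far-separated chains are flagged
  set.seed(1)
  far <- rbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_false(gelman_rubin(far)$converged)
  expect_true(gelman_rubin(far)$rhat > 5)

  # brute-force recomputation of the same formula on arbitrary arrays
  set.seed(2)
  ch <- matrix(rnorm(3 * 40, mean = rep(c(0, 0.3, -0.2), each = 40)), 3, 40,
               byrow = FALSE)
  ch <- rbind(rnorm(40), rnorm(40, 0.4), rnorm(40, -0.1))
  m <- nrow(ch); Tn <- ncol(ch)
  W <- mean(apply(ch, 1, var))
  B <- Tn * var(rowMeans(ch))
  rhat_oracle <- sqrt(((Tn - 1) / Tn * W + B / Tn) / W)
  expect_equal(gelman_rubin(ch)$rhat, rhat_oracle, tolerance = 1e-12)

  expect_error(gelman_rubin(rbind(rep(1, 10), rep(1, 10))), "degenerate")
  expect_error(gelman_rubin(matrix(rnorm(10), 1)), "2 chains")

  # monotone in the offset between two chains
  rh <- sapply(c(0.1, 0.5, 1, 2), function(d) gelman_rubin(rbind(x, x + d))$rhat)
  expect_true(all(diff(rh) > 0))
})

test_that("Welch t-tests match the hand formula and handle edge groups", {
  # textbook case: n1 = n2 = 10, means 10 vs 12, sd 2
  g1 <- as.numeric(scale(rnorm(10))) * 2 + 10
  g2 <- as.numeric(scale(rnorm(10))) * 2 + 12
  tt <- t.test(g1, g2, var.equal = FALSE)
  t_oracle <- (mean(g1) - mean(g2)) / sqrt(var(g1) / 10 + var(g2) / 10)
  df_oracle <- (var(g1) / 10 + var(g2) / 10)^2 /
    ((var(g1) / 10)^2 / 9 + (var(g2) / 10)^2 / 9)
  expect_equal(unname(tt$statistic), t_oracle, tolerance = 1e-6)
  expect_equal(unname(tt$statistic), -sqrt(5), tolerance = 1e-6)
  expect_equal(unname(tt$parameter), df_oracle, tolerance = 1e-6)
  expect_equal(unname(tt$parameter), 18, tolerance = 1e-6)
  expect_equal(tt$p.value,
               2 * pt(-abs(t_oracle), df_oracle), tolerance = 1e-10)

  # via the table builder: groups with identical value multisets give
  # t = 0, p = 1; separated groups give tiny p
  qcol <- c(rep(1L, 9), 2L, rep(9L, 9), 8L)
  design <- structure(list(q = matrix(qcol, 20, 1,
                                      dimnames = list(NULL, "q_1")),
                           cutpoints = matrix(0, 9, 1),
                           orientation = "direct"),
                      class = "decile_design")
  eff <- data.frame(unit = paste0("u", 1:20), outcome = 1,
                    rr_median = 1, rr_lower = 0.9, rr_upper = 1.1,
                    significant = rep(c(TRUE, FALSE), each = 10))
  ndi <- rep(rep(c(5.1, 5.9), 5), 2)   # same multiset in both groups
  out <- welch_tests(eff, design, ndi)
  expect_equal(out$t[out$variable == "NDI"], 0)
  expect_equal(out$p[out$variable == "NDI"], 1)
  expect_lt(out$p[out$variable == "q_1"], 1e-6)

  eff$significant <- c(TRUE, rep(FALSE, 19))
  expect_message(out2 <- welch_tests(eff, design, ndi), "fewer than 2")
  expect_equal(nrow(out2), 0)
})

test_that("effect summaries exponentiate and flag by the credible bound", {
  # synthetic posterior: beta draws around 1 with sd 0.1 -> RR ~ e, significant
  set.seed(5)
  Tn <- 2000; n <- 3; K <- 1
  mk_chain <- function(b) {
    list(alpha = matrix(0, Tn, K),
         beta = array(rep(b, each = Tn) + rnorm(Tn * n * K, 0, 0.1), c(Tn, n, K)),
         omega = array(1, c(Tn, K, K)),
         weights = matrix(0.5, Tn, 2),
         ndi = matrix(5, Tn, n),
         theta = array(1, c(Tn, n, K)))
  }
  post <- structure(list(chains = list(mk_chain(c(1, 0, -0.5))),
                         n = n, K = K, C = 2,
                         deciles = matrix(5, n, 2),
                         unit_ids = paste0("u", 1:n)),
                    class = "svc_posterior")
  eff <- summarize_effects(post)
  expect_equal(eff$rr_median[1], exp(1), tolerance = 0.02)
  expect_true(eff$significant[1])
  # point mass at the null: median 1, not significant
  post$chains[[1]]$beta[, 2, 1] <- 0
  eff2 <- summarize_effects(post)
  expect_equal(eff2$rr_median[2], 1)
  expect_false(eff2$significant[2])
  # flag equivariance under the monotone exp map
  b3 <- post$chains[[1]]$beta[, 3, 1]
  expect_equal(unname(quantile(b3, 0.025, type = 7) > 0),
               eff2$significant[3])
})

test_that("conditional correlations invert the precision per draw", {
  Tn <- 50
  om_eye <- array(rep(diag(2), each = Tn), c(Tn, 2, 2))
  cc <- conditional_correlations(om_eye)
  expect_equal(cc$median, 0)
  expect_equal(cc$lower, 0)

  om <- array(rep(matrix(c(2, -1, -1, 2), 2, 2), each = Tn), c(Tn, 2, 2))
  cc2 <- conditional_correlations(om)
  expect_equal(cc2$median, 0.5)   # Sigma proportional to [[2,1],[1,2]]
  expect_true(all(cc2$lower >= -1 & cc2$upper <= 1))
})

test_that("weight and NDI summaries reduce to their definitions", {
  Tn <- 120
  w <- matrix(rep(c(0.2, 0.3, 0.5), each = Tn), Tn, 3)
  ws <- summarize_weights(w)
  expect_equal(ws$median[ws$variable == "w_3"], 0.5)
  expect_equal(ws$rank[ws$variable == "w_3"], 1L)
  expect_equal(sum(ws$median), 1)

  ch <- list(alpha = matrix(0, Tn, 1),
             beta = array(0, c(Tn, 2, 1)),
             omega = array(1, c(Tn, 1, 1)),
             weights = w,
             ndi = matrix(rep(c(4, 7), each = Tn), Tn, 2),
             theta = array(1, c(Tn, 2, 1)))
  post <- structure(list(chains = list(ch), n = 2, K = 1, C = 3,
                         deciles = matrix(5, 2, 3),
                         unit_ids = c("a", "b")),
                    class = "svc_posterior")
  nd <- summarize_ndi(post)
  expect_equal(nd$ndi_median, c(4, 7))
})

test_that("prior-only weight medians match the Beta marginal oracle", {
  # uniform Dirichlet, C = 9: each weight ~ Beta(1, 8); median 1 - 0.5^(1/8)
  ds <- tiny_dataset()
  dg <- decile_design(ds)
  q9 <- cbind(dg$q, dg$q, dg$q)[, 1:9]
  ec <- compute_expected_counts(ds$counts, ds$populations)
  cfg <- mcmc_config(n_chains = 2, burn_in = 500, retained = 6000, seed = 17,
                     use_likelihood = FALSE, sample_alpha = FALSE,
                     sample_beta = FALSE, sample_omega = FALSE,
                     store_theta = FALSE)
  post <- run_mcmc(ds$counts, ec$E, q9, ds$adjacency,
                   prior_spec(K = ds$K, C = 9), cfg)
  ws <- summarize_weights(post)
  beta_median <- 1 - 0.5^(1 / 8)   # qbeta(0.5, 1, 8)
  expect_equal(unname(ws$median), rep(beta_median, 9), tolerance = 0.08)
  expect_equal(mean(ws$median), qbeta(0.5, 1, 8), tolerance = 0.03)
})
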