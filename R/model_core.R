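#' Prior specification
#'
#' Priors of the SVC index model: improper flat priors on the intercepts, a
#' Wishart prior on the MVCAR precision `Omega`, and a Dirichlet prior on the
#' index weights. The Wishart uses the BUGS rate-matrix convention
#' `f(Omega) \propto |Omega|^((df-K-1)/2) exp(-tr(R Omega)/2)`, with prior
#' mean `df * R^(-1)`; conventions differ across ecosystems, so this one is
#' fixed here and translated internally where base R expects a scale matrix.
#'
#' @param K number of outcome types.
#' @param C number of index variables.
#' @param wishart_scale K-by-K rate matrix `R` (default diagonal 0.2).
#' @param wishart_df degrees of freedom (default `K`, the minimum proper).
#' @param dirichlet_alpha positive C-vector (default all 1: uniform on the
#'   simplex, i.e. a priori equal weight `1/C` per variable).
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(K = 3, C = 9,
                       wishart_scale = diag(0.2, K),
                       wishart_df = K,
                       dirichlet_alpha = rep(1, C)) {
  if (!is_pd(wishart_scale)) stop("wishart_scale must be symmetric positive-definite")
  if (wishart_df < K) stop("wishart_df must be at least K")
  if (any(dirichlet_alpha <= 0)) stop("dirichlet_alpha must be positive")
  structure(list(K = K, C = C, wishart_scale = wishart_scale,
                 wishart_df = wishart_df, dirichlet_alpha = dirichlet_alpha),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' @param n_chains number of chains (default 2).
#' @param burn_in burn-in iterations per chain (default 50000, the
#'   full-scale protocol; use [mcmc_config_test()] for desk-scale runs).
#' @param retained retained draws per chain (default 10000).
#' @param thin thinning interval (default 1).
#' @param seed master seed, or vector of per-chain seeds.
#' @param beta_scale,weight_scale,slope_scale initial random-walk proposal
#'   standard deviations.
#' @param adapt_window iterations per Robbins-Monro adaptation batch during
#'   burn-in; proposal scales are frozen after burn-in so retained draws come
#'   from a fixed kernel.
#' @param mode `"centered"` (default): the coefficient field is the sum of a
#'   flat-prior mean slope per outcome and a sum-to-zero MVCAR deviation,
#'   sampled via single-site moves plus a global column-shift move.
#'   `"unconstrained"`: single-site moves only (same posterior, provided for
#'   sensitivity analysis; mixes more slowly in the column means).
#' @param sample_alpha,sample_beta,sample_omega,sample_weights block toggles
#'   (fixing blocks is used by oracle and prior-sampling checks).
#' @param use_likelihood set `FALSE` to sample from the priors alone.
#' @param store_theta store the derived relative-risk surface per draw.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, burn_in = 50000L, retained = 10000L,
                        thin = 1L, seed = 1L,
                        beta_scale = 0.1, weight_scale = 0.1,
                        slope_scale = 0.05, adapt_window = 50L,
                        mode = c("centered", "unconstrained"),
                        sample_alpha = TRUE, sample_beta = TRUE,
                        sample_omega = TRUE, sample_weights = TRUE,
                        use_likelihood = TRUE, store_theta = TRUE) {
  mode <- match.arg(mode)
  stopifnot(burn_in >= 0, retained >= 1, thin >= 1, n_chains >= 1)
  if (length(seed) == 1L) {
    seed <- vapply(seq_len(n_chains), function(c) derive_seed(seed, c), 1L)
  }
  stopifnot(length(seed) == n_chains)
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 retained = as.integer(retained), thin = as.integer(thin),
                 seed = as.integer(seed), beta_scale = beta_scale,
                 weight_scale = weight_scale, slope_scale = slope_scale,
                 adapt_window = as.integer(adapt_window), mode = mode,
                 sample_alpha = sample_alpha, sample_beta = sample_beta,
                 sample_omega = sample_omega, sample_weights = sample_weights,
                 use_likelihood = use_likelihood, store_theta = store_theta),
            class = "mcmc_config")
}

#' Desk-scale MCMC settings
#'
#' Burn-in 5000 / retained 5000, two chains: the short protocol used for
#' simulation experiments and tests; the full-scale settings remain the
#' [mcmc_config()] defaults.
#'
#' @param ... overrides passed to [mcmc_config()].
#' @export
mcmc_config_test <- function(...) {
  args <- list(...)
  defaults <- list(burn_in = 5000L, retained = 5000L)
  do.call(mcmc_config, utils::modifyList(defaults, args))
}

#' Neighborhood disadvantage index values
#'
#' `NDI_i = sum_j w_j q_ij`: the weighted combination of decile scores. With
#' weights on the simplex and deciles in 1..10, every value lies in
#' \[1, 10\].
#'
#' @param weights open-simplex C-vector.
#' @param deciles n-by-C integer matrix with entries in 1..10.
#' @return n-vector of index values.
#' @export
ndi_value <- function(weights, deciles) {
  check_simplex(weights)
  if (any(deciles < 1 | deciles > 10)) stop("deciles must lie in 1..10")
  as.numeric(as.matrix(deciles) %*% weights)
}

#' Poisson log-likelihood of the SVC index model
#'
#' `sum_ik [ y_ik log(mu_ik) - mu_ik - log(y_ik!) ]` with
#' `mu_ik = E_ik exp(alpha_k + beta_ik ndi_i)`. The factorial constant is
#' included so values are comparable across calls.
#'
#' @param y,E n-by-K count and expected-count matrices (`E > 0`).
#' @param alpha K-vector; `beta` n-by-K; `ndi` n-vector.
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(y, E, alpha, beta, ndi) {
  y <- as.matrix(y); E <- as.matrix(E); beta <- as.matrix(beta)
  if (any(E <= 0)) stop("expected counts must be strictly positive")
  ll <- poisson_loglik_cpp(y, E, as.numeric(alpha), beta, as.numeric(ndi))
  if (!is.finite(ll)) stop("nonfinite Poisson mean in log-likelihood")
  ll
}

#' Intrinsic MVCAR log-density kernel
#'
#' `(n-1)/2 log|Omega| - 1/2 sum_(i~j) (beta_i - beta_j)' Omega (beta_i - beta_j)`
#' over unordered neighbor pairs. The pairwise-difference form makes the
#' kernel invariant to adding a constant to any column (the intrinsic
#' improperness); the `(n-1)` exponent is the rank of the graph Laplacian of
#' a connected graph.
#'
#' @param beta n-by-K matrix.
#' @param omega K-by-K symmetric positive-definite precision.
#' @param adjacency connected `svc_adjacency`.
#' @return scalar log-kernel.
#' @export
mvcar_logpdf_kernel <- function(beta, omega, adjacency) {
  if (!is_pd(omega)) stop("omega must be symmetric positive-definite")
  beta <- as.matrix(beta)
  e <- adjacency$edges
  D <- beta[e[, 1L], , drop = FALSE] - beta[e[, 2L], , drop = FALSE]
  quad <- sum((D %*% omega) * D)
  (adjacency$n - 1) / 2 * determinant(omega, logarithm = TRUE)$modulus[1] -
    0.5 * quad
}

# --- full-conditional updates ------------------------------------------------

#' Gibbs update of the intercepts
#'
#' Under the flat prior, `t_k = exp(alpha_k)` has the conjugate conditional
#' `Gamma(shape = sum_i y_ik, rate = sum_i E_ik exp(beta_ik ndi_i))`; the
#' update draws `t_k` and returns `log t_k`.
#'
#' @param y,E n-by-K matrices; `beta` n-by-K; `ndi` n-vector.
#' @return K-vector of new intercepts.
#' @export
update_alpha <- function(y, E, beta, ndi) {
  shape <- colSums(y)
  if (any(shape == 0)) stop("outcome with zero total count: intercept conditional degenerate")
  rate <- colSums(E * exp(beta * ndi))
  log(stats::rgamma(length(shape), shape = shape, rate = rate))
}

#' Conjugate Wishart update of the MVCAR precision
#'
#' `Omega | beta ~ Wishart(rate = R + S, df = wishart_df + n - 1)` in the
#' rate-matrix convention, where `S = sum_(i~j) (beta_i - beta_j)(beta_i -
#' beta_j)'`. Internally translated to `stats::rWishart`'s scale-matrix
#' convention (`scale = solve(rate)`).
#'
#' @param beta n-by-K matrix; `adjacency` connected; `prior` a [prior_spec()].
#' @return K-by-K symmetric positive-definite draw.
#' @export
update_omega <- function(beta, adjacency, prior) {
  e <- adjacency$edges
  D <- as.matrix(beta)[e[, 1L], , drop = FALSE] -
       as.matrix(beta)[e[, 2L], , drop = FALSE]
  S <- crossprod(D)
  if (any(!is.finite(S))) stop("nonfinite pairwise-difference scatter matrix")
  rate <- prior$wishart_scale + S
  df <- prior$wishart_df + adjacency$n - 1
  draw <- stats::rWishart(1L, df = df, Sigma = solve(rate))[, , 1L]
  (draw + t(draw)) / 2
}

# Metropolis sweep over the index weights on the additive-log-ratio scale
# z_j = log(w_j / w_C), one scalar random-walk move per coordinate.
# Target: Poisson log-likelihood (through the NDI) + Dirichlet log prior +
# log-Jacobian sum_j log w_j of the ALR transform. Proposals reaching
# w_j <= 1e-12 are rejected outright (open-simplex support).
# Returns list(weights, ndi, accepted, attempts).
update_weights_step <- function(w, ndi, y, E, alpha, beta, deciles, prior,
                                scale, use_likelihood = TRUE,
                                mv_chol = NULL, mv_scale = 1) {
  C <- length(w)
  a <- prior$dirichlet_alpha
  accepted <- 0L
  logtarget <- function(w_vec, ndi_vec) {
    lt <- sum((a - 1) * log(w_vec)) + sum(log(w_vec))
    if (use_likelihood) {
      lt <- lt + sum(y * (beta * ndi_vec)) -
        sum(E * exp(sweep(beta * ndi_vec, 2L, alpha, `+`)))
    }
    lt
  }
  lt_cur <- logtarget(w, ndi)
  z <- log(w[-C] / w[C])
  try_move <- function(z_new) {
    expz <- exp(c(z_new, 0))
    w_new <- expz / sum(expz)
    if (any(!is.finite(w_new)) || any(w_new <= 1e-12)) return(FALSE)
    ndi_new <- as.numeric(deciles %*% w_new)
    lt_new <- logtarget(w_new, ndi_new)
    if (is.finite(lt_new) && log(stats::runif(1)) < lt_new - lt_cur) {
      z <<- z_new; w <<- w_new; ndi <<- ndi_new; lt_cur <<- lt_new
      TRUE
    } else FALSE
  }
  # scale-mixture proposals: mostly local steps, occasionally 4x jumps so
  # chains can hop between near-equivalent weight allocations
  jump <- function() scale * sample(c(1, 4), 1L, prob = c(0.8, 0.2)) * stats::rnorm(1)
  attempts <- 0L
  for (j in seq_len(C - 1L)) {
    z_new <- z
    z_new[j] <- z[j] + jump()
    accepted <- accepted + try_move(z_new)
    attempts <- attempts + 1L
  }
  # global shift of all log-ratios: the only direction that moves the
  # reference weight w_C against everything else in one step
  accepted <- accepted + try_move(z + jump())
  attempts <- attempts + 1L
  # antithetic pair moves: transfer mass between two variables, leaving the
  # rest nearly untouched; helps when correlated decile columns compete for
  # the same weight mass
  if (C > 2L) {
    for (r in seq_len(C - 1L)) {
      jl <- sample.int(C - 1L, 2L)
      d <- jump()
      z_new <- z
      z_new[jl[1L]] <- z[jl[1L]] + d
      z_new[jl[2L]] <- z[jl[2L]] - d
      accepted <- accepted + try_move(z_new)
      attempts <- attempts + 1L
    }
  }
  # adaptive-covariance move: multivariate step shaped by the estimated
  # posterior covariance of z (learned during burn-in, frozen afterwards)
  mv_accepted <- NA
  if (!is.null(mv_chol)) {
    mv_accepted <- try_move(z + mv_scale * as.numeric(mv_chol %*% stats::rnorm(C - 1L)))
    accepted <- accepted + mv_accepted
    attempts <- attempts + 1L
  }
  list(weights = w, ndi = ndi, accepted = accepted, attempts = attempts,
       mv_accepted = mv_accepted)
}

# Global column-shift Metropolis move for outcome k (centered mode): proposes
# beta[, k] + c together with the compensating intercept shift
# alpha_k - c * mean(ndi), i.e. a move along the intercept/mean-slope ridge.
# The MVCAR kernel is shift-invariant and both alpha_k and the column mean
# carry flat priors, so only the likelihood change enters; the compensation
# keeps that change small and the ridge mixes quickly.
update_slope_step <- function(beta, k, y, E, alpha, ndi, scale) {
  cshift <- scale * stats::rnorm(1)
  m <- mean(ndi)
  dll <- sum(y[, k] * cshift * (ndi - m)) -
    sum(E[, k] * (exp(alpha[k] - cshift * m + (beta[, k] + cshift) * ndi) -
                  exp(alpha[k] + beta[, k] * ndi)))
  if (is.finite(dll) && log(stats::runif(1)) < dll) {
    beta[, k] <- beta[, k] + cshift
    alpha[k] <- alpha[k] - cshift * m
    list(beta = beta, alpha = alpha, accepted = TRUE)
  } else {
    list(beta = beta, alpha = alpha, accepted = FALSE)
  }
}

# Likelihood-preserving joint move on (weights, field): propose new
# log-ratios z', set beta'_ik = beta_ik * ndi_i / ndi'_i so every Poisson
# mean is unchanged, and accept on the prior terms alone — the MVCAR kernel
# change, the Dirichlet prior and ALR Jacobian for z, and the log-Jacobian
# K * sum_i log(ndi_i / ndi'_i) of the deterministic field map. This lets
# the weights traverse allocations that a fixed field would veto.
weight_field_swap_step <- function(w, ndi, beta, omega, deciles, edges, prior,
                                   scale) {
  C <- length(w); K <- ncol(beta)
  z <- log(w[-C] / w[C])
  kind <- sample.int(3L, 1L)
  z_new <- z
  if (kind == 1L) {
    j <- sample.int(C - 1L, 1L)
    z_new[j] <- z[j] + scale * stats::rnorm(1)
  } else if (kind == 2L && C > 2L) {
    jl <- sample.int(C - 1L, 2L)
    d <- scale * stats::rnorm(1)
    z_new[jl[1L]] <- z[jl[1L]] + d
    z_new[jl[2L]] <- z[jl[2L]] - d
  } else {
    z_new <- z + scale * stats::rnorm(1)
  }
  expz <- exp(c(z_new, 0))
  w_new <- expz / sum(expz)
  if (any(!is.finite(w_new)) || any(w_new <= 1e-12)) {
    return(list(weights = w, ndi = ndi, beta = beta, accepted = FALSE))
  }
  ndi_new <- as.numeric(deciles %*% w_new)
  beta_new <- beta * (ndi / ndi_new)
  quad <- function(b) {
    D <- b[edges[, 1L], , drop = FALSE] - b[edges[, 2L], , drop = FALSE]
    sum((D %*% omega) * D)
  }
  a <- prior$dirichlet_alpha
  logr <- -0.5 * (quad(beta_new) - quad(beta)) +
    sum(a * (log(w_new) - log(w))) +            # Dirichlet prior + ALR Jacobian
    K * sum(log(ndi) - log(ndi_new))            # field-map Jacobian
  if (is.finite(logr) && log(stats::runif(1)) < logr) {
    list(weights = w_new, ndi = ndi_new, beta = beta_new, accepted = TRUE)
  } else {
    list(weights = w, ndi = ndi, beta = beta, accepted = FALSE)
  }
}

# Likelihood-invariant trade between the intercept and the field: proposes
# alpha_k + c together with beta_ik - c / ndi_i, which leaves every linear
# predictor unchanged, so acceptance rests on the MVCAR kernel alone (the
# map has unit Jacobian and alpha is flat). This is the weakly identified
# direction of the model — the intercept is pinned down only by the field's
# smoothness prior — and dedicated moves are needed to traverse it.
alpha_field_trade_step <- function(alpha, beta, k, ndi, omega, edges, scale) {
  cshift <- scale * stats::rnorm(1)
  bk_new <- beta[, k] - cshift / ndi
  quadk <- function(bk) {
    b <- beta; b[, k] <- bk
    D <- b[edges[, 1L], , drop = FALSE] - b[edges[, 2L], , drop = FALSE]
    sum((D %*% omega) * D)
  }
  logr <- -0.5 * (quadk(bk_new) - quadk(beta[, k]))
  if (is.finite(logr) && log(stats::runif(1)) < logr) {
    alpha[k] <- alpha[k] + cshift
    beta[, k] <- bk_new
    list(alpha = alpha, beta = beta, accepted = TRUE)
  } else {
    list(alpha = alpha, beta = beta, accepted = FALSE)
  }
}

# CSR neighbor representation for the C++ sweep (0-based).
adjacency_csr <- function(adj) {
  deg <- degrees(adj)
  list(nbr = as.integer(unlist(adj$nbr, use.names = FALSE) - 1L),
       ptr = as.integer(c(0L, cumsum(deg))))
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Fits the Bayesian spatially varying coefficient index model
#' `y_ik ~ Poisson(E_ik exp(alpha_k + beta_ik NDI_i))`,
#' `NDI_i = sum_j w_j q_ij`, with a flat prior on `alpha`, an intrinsic MVCAR
#' prior on the coefficient field, a Wishart prior on its precision, and a
#' Dirichlet prior on the index weights. Update blocks per iteration:
#' single-site Metropolis on the coefficient field (plus a column-shift move
#' in centered mode), exact Gibbs for the intercepts, conjugate Wishart for
#' the precision, and an additive-log-ratio Metropolis step for the weights.
#' Proposal scales adapt toward standard acceptance targets (0.44 scalar /
#' 0.234 multivariate) during burn-in only.
#'
#' @param y n-by-K count matrix.
#' @param E n-by-K positive expected counts (see
#'   [compute_expected_counts()]).
#' @param deciles n-by-C integer decile design (see [decile_design()]).
#' @param adjacency connected `svc_adjacency`.
#' @param prior a [prior_spec()].
#' @param config an [mcmc_config()].
#' @param init optional named list overriding initial values (`alpha`,
#'   `beta`, `omega`, `weights`); combined with the `sample_*` toggles this
#'   fixes a block at a chosen value.
#' @return object of class `svc_posterior`: per chain the retained draws of
#'   `alpha` (T x K), `beta` (T x n x K), `omega` (T x K x K), `weights`
#'   (T x C), derived `ndi` (T x n) and `theta` (T x n x K), plus acceptance
#'   rates and frozen proposal scales; the decile design and dimensions ride
#'   along for the diagnostic stage.
#' @export
run_mcmc <- function(y, E, deciles, adjacency, prior = NULL, config = NULL,
                     init = NULL) {
  y <- as.matrix(y); E <- as.matrix(E)
  deciles <- as.matrix(deciles)
  storage.mode(deciles) <- "double"
  n <- nrow(y); K <- ncol(y); C <- ncol(deciles)
  if (is.null(prior)) prior <- prior_spec(K = K, C = C)
  if (is.null(config)) config <- mcmc_config()
  stopifnot(inherits(prior, "prior_spec"), inherits(config, "mcmc_config"),
            prior$K == K, prior$C == C, nrow(E) == n, ncol(E) == K,
            nrow(deciles) == n, adjacency$n == n)
  if (any(E <= 0)) stop("expected counts must be strictly positive")
  validate_adjacency(adjacency)
  csr <- adjacency_csr(adjacency)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed[ch])
    chains[[ch]] <- run_one_chain(y, E, deciles, adjacency, csr, prior, config,
                                  init = init)
  }
  structure(list(chains = chains, prior = prior, config = config,
                 deciles = deciles, n = n, K = K, C = C,
                 unit_ids = adjacency$ids),
            class = "svc_posterior")
}

run_one_chain <- function(y, E, deciles, adjacency, csr, prior, config, init) {
  n <- nrow(y); K <- ncol(y); C <- ncol(deciles)
  use_lik <- config$use_likelihood

  # moment-matched deterministic initialization
  alpha <- if (use_lik) log(colSums(y) / colSums(E)) else rep(0, K)
  beta <- matrix(0, n, K)
  weights <- rep(1 / C, C)
  omega <- prior$wishart_df * solve(prior$wishart_scale)   # Wishart prior mean
  if (!is.null(init)) {
    for (nm in names(init)) assign(nm, init[[nm]])
  }
  ndi <- as.numeric(deciles %*% weights)

  if (use_lik) {
    lp0 <- poisson_loglik(y, E, alpha, beta, ndi)
    if (!is.finite(lp0)) {
      stop("nonfinite log-posterior at initialization; alpha = ",
           paste(signif(alpha, 4), collapse = ", "))
    }
  }

  s_beta <- config$beta_scale
  s_w <- config$weight_scale
  s_slope <- rep(config$slope_scale, K)
  target_beta <- if (K > 1) 0.234 else 0.44
  target_w <- 0.44                 # component-wise scalar moves

  total <- config$burn_in + config$retained * config$thin
  Tkeep <- config$retained
  draws <- list(alpha = matrix(NA_real_, Tkeep, K),
                beta = array(NA_real_, c(Tkeep, n, K)),
                omega = array(NA_real_, c(Tkeep, K, K)),
                weights = matrix(NA_real_, Tkeep, C),
                ndi = matrix(NA_real_, Tkeep, n),
                theta = if (config$store_theta) array(NA_real_, c(Tkeep, n, K)) else NULL)

  acc <- c(beta = 0, weights = 0, slope = 0)
  att <- c(beta = 0, weights = 0, slope = 0)
  win <- c(beta = 0, weights = 0, slope = 0)       # window accept counters
  win_att <- c(beta = 0, weights = 0, slope = 0)
  batch <- 0L
  stored <- 0L
  # adaptive-covariance bookkeeping for the weight log-ratios
  z_hist <- if (C > 2L) matrix(NA_real_, config$burn_in, C - 1L) else NULL
  mv_chol <- NULL
  s_mv <- 2.38 / sqrt(max(C - 1L, 1L))
  mv_from <- min(1000L, floor(config$burn_in / 2))
  win_mv <- 0; win_mv_att <- 0
  s_swap <- 0.1
  win_swap <- 0; win_swap_att <- 0
  s_trade <- rep(0.05, K)
  win_trade <- rep(0, K); win_trade_att <- rep(0, K)

  for (it in seq_len(total)) {
    burning <- it <= config$burn_in

    if (config$sample_beta) {
      # proposal increments shaped by the current coefficient covariance;
      # several sweeps per iteration (site updates are cheap relative to the
      # other blocks and field autocorrelation dominates otherwise)
      prop_chol <- t(chol(solve(omega)))
      for (sweep_rep in 1:3) {
        a <- beta_sweep_cpp(beta, y, E, alpha, ndi, csr$nbr, csr$ptr, omega,
                            s_beta, prop_chol, as.integer(use_lik))
        acc["beta"] <- acc["beta"] + a; att["beta"] <- att["beta"] + n
        win["beta"] <- win["beta"] + a; win_att["beta"] <- win_att["beta"] + n
      }
      if (use_lik && config$mode == "centered") {
        for (k in rep(seq_len(K), 3L)) {
          st <- update_slope_step(beta, k, y, E, alpha, ndi, s_slope[k])
          beta <- st$beta; alpha <- st$alpha
          acc["slope"] <- acc["slope"] + st$accepted
          att["slope"] <- att["slope"] + 1
          win["slope"] <- win["slope"] + st$accepted
          win_att["slope"] <- win_att["slope"] + 1
        }
      }
      if (!use_lik) {
        # prior-only runs: project onto the sum-to-zero orbit for stability
        beta <- sweep(beta, 2L, colMeans(beta))
      }
    }

    if (config$sample_alpha && use_lik) {
      alpha <- update_alpha(y, E, beta, ndi)
      if (config$sample_beta) {
        for (k in rep(seq_len(K), 3L)) {
          tr <- alpha_field_trade_step(alpha, beta, k, ndi, omega,
                                       adjacency$edges, s_trade[k])
          alpha <- tr$alpha; beta <- tr$beta
          win_trade[k] <- win_trade[k] + tr$accepted
          win_trade_att[k] <- win_trade_att[k] + 1
        }
      }
    }

    if (config$sample_omega) {
      omega <- update_omega(beta, adjacency, prior)
    }

    if (config$sample_weights) {
      st <- update_weights_step(weights, ndi, y, E, alpha, beta, deciles,
                                prior, s_w, use_lik,
                                mv_chol = mv_chol, mv_scale = s_mv)
      weights <- st$weights; ndi <- st$ndi
      acc["weights"] <- acc["weights"] + st$accepted
      att["weights"] <- att["weights"] + st$attempts
      win["weights"] <- win["weights"] + st$accepted
      win_att["weights"] <- win_att["weights"] + st$attempts
      if (!is.na(st$mv_accepted)) {
        win_mv <- win_mv + st$mv_accepted; win_mv_att <- win_mv_att + 1
      }
      if (use_lik && config$sample_beta) {
        for (r in seq_len(C - 1L)) {
          sw <- weight_field_swap_step(weights, ndi, beta, omega, deciles,
                                       adjacency$edges, prior, s_swap)
          weights <- sw$weights; ndi <- sw$ndi; beta <- sw$beta
          win_swap <- win_swap + sw$accepted
          win_swap_att <- win_swap_att + 1
        }
      }
      if (!is.null(z_hist) && burning) {
        z_hist[it, ] <- log(weights[-C] / weights[C])
        if (it >= mv_from && it %% 200L == 0L) {
          zc <- stats::cov(z_hist[seq_len(it), , drop = FALSE])
          mv_chol <- tryCatch(t(chol(zc + diag(1e-8, C - 1L))),
                              error = function(e) NULL)
        }
      }
    }

    # Robbins-Monro adaptation, burn-in only
    if (burning && it %% config$adapt_window == 0L) {
      batch <- batch + 1L
      step <- 1 / sqrt(batch)
      if (win_att["beta"] > 0) {
        s_beta <- s_beta * exp(step * (win["beta"] / win_att["beta"] - target_beta))
      }
      if (win_att["weights"] > 0) {
        s_w <- s_w * exp(step * (win["weights"] / win_att["weights"] - target_w))
      }
      if (win_att["slope"] > 0) {
        rate <- win["slope"] / win_att["slope"]
        s_slope <- s_slope * exp(step * (rate - 0.44))
      }
      if (win_mv_att > 0) {
        s_mv <- s_mv * exp(step * (win_mv / win_mv_att - 0.234))
        win_mv <- 0; win_mv_att <- 0
      }
      if (win_swap_att > 0) {
        s_swap <- s_swap * exp(step * (win_swap / win_swap_att - 0.234))
        win_swap <- 0; win_swap_att <- 0
      }
      if (any(win_trade_att > 0)) {
        s_trade <- s_trade * exp(step * (win_trade / pmax(win_trade_att, 1) - 0.44))
        win_trade[] <- 0; win_trade_att[] <- 0
      }
      win[] <- 0; win_att[] <- 0
    }

    if (!burning && (it - config$burn_in) %% config$thin == 0L) {
      stored <- stored + 1L
      draws$alpha[stored, ] <- alpha
      draws$beta[stored, , ] <- beta
      draws$omega[stored, , ] <- omega
      draws$weights[stored, ] <- weights
      draws$ndi[stored, ] <- ndi
      if (config$store_theta) {
        draws$theta[stored, , ] <- exp(sweep(beta * ndi, 2L, alpha, `+`))
      }
    }
  }

  draws$accept <- ifelse(att > 0, acc / att, NA_real_)
  draws$scales <- list(beta = s_beta, weights = s_w, slope = s_slope,
                       weights_mv = s_mv, weight_field_swap = s_swap,
                       alpha_field_trade = s_trade)
  draws
}

#' @export
print.svc_posterior <- function(x, ...) {
  cat(sprintf("svc_posterior: %d chains x %d draws, n=%d units, K=%d outcomes, C=%d weights\n",
              length(x$chains), nrow(x$chains[[1]]$alpha), x$n, x$K, x$C))
  for (ch in seq_along(x$chains)) {
    a <- x$chains[[ch]]$accept
    cat(sprintf("  chain %d acceptance: beta %.2f, weights %.2f, slope %.2f\n",
                ch, a["beta"], a["weights"], a["slope"]))
  }
  invisible(x)
}

# Pool a component across chains: matrices rbind, 3-d arrays abind on dim 1.
pool_draws <- function(post, what) {
  parts <- lapply(post$chains, `[[`, what)
  if (length(dim(parts[[1]])) == 3L) {
    d <- dim(parts[[1]])
    out <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1], 1)), d[2], d[3]))
    at <- 0L
    for (p in parts) {
      out[at + seq_len(dim(p)[1]), , ] <- p
      at <- at + dim(p)[1]
    }
    out
  } else {
    do.call(rbind, parts)
  }
}
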