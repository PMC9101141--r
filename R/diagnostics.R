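#' Gelman-Rubin potential scale reduction factor
#'
#' Classical split-free R-hat for m >= 2 chains of equal length T:
#' `W` = mean of the within-chain variances, `B` = T times the variance of
#' the chain means, `Vhat = (T-1)/T * W + B/T`, `Rhat = sqrt(Vhat / W)`.
#' Values near 1 indicate the chains have mixed; the conventional
#' convergence call here is `Rhat < 1.2`.
#'
#' @param chains m-by-T matrix (or list of equal-length numeric vectors),
#'   one row/element per chain.
#' @param threshold convergence threshold (default 1.2).
#' @return list with `rhat`, `W`, `B`, `converged`.
#' @export
gelman_rubin <- function(chains, threshold = 1.2) {
  if (is.list(chains)) chains <- do.call(rbind, chains)
  chains <- as.matrix(chains)
  m <- nrow(chains); Tn <- ncol(chains)
  if (m < 2L) stop("gelman_rubin needs at least 2 chains")
  if (Tn < 4L) stop("gelman_rubin needs at least 4 draws per chain")
  W <- mean(apply(chains, 1L, stats::var))
  if (W == 0) stop("zero within-chain variance: degenerate chain")
  B <- Tn * stats::var(rowMeans(chains))
  Vhat <- (Tn - 1) / Tn * W + B / Tn
  rhat <- sqrt(Vhat / W)
  list(rhat = rhat, W = W, B = B, converged = rhat < threshold)
}

#' Convergence table for a fitted posterior
#'
#' Computes R-hat for the monitored scalars: each intercept, each index
#' weight, the unique elements of the precision matrix, and an evenly spaced
#' subsample of up to `n_beta_monitor` coefficient-field entries (monitoring
#' all n*K entries is wasteful at realistic problem sizes; the subsample is
#' deterministic so reruns agree).
#'
#' @param post an `svc_posterior` with >= 2 chains.
#' @param threshold convergence threshold (default 1.2).
#' @param n_beta_monitor number of beta entries to monitor.
#' @return data.frame: `parameter`, `rhat`, `converged`.
#' @export
convergence_table <- function(post, threshold = 1.2, n_beta_monitor = 100L) {
  stopifnot(inherits(post, "svc_posterior"))
  m <- length(post$chains)
  if (m < 2L) stop("convergence assessment needs at least 2 chains")
  K <- post$K; C <- post$C; n <- post$n

  grab <- function(f) do.call(rbind, lapply(post$chains, function(ch) f(ch)))
  rows <- list()
  add <- function(name, mat) {
    gr <- gelman_rubin(mat, threshold)
    rows[[length(rows) + 1L]] <<- data.frame(parameter = name, rhat = gr$rhat,
                                             converged = gr$converged)
  }
  for (k in seq_len(K)) add(paste0("alpha_", k), grab(function(ch) ch$alpha[, k]))
  for (j in seq_len(C)) add(paste0("w_", j), grab(function(ch) ch$weights[, j]))
  for (k in seq_len(K)) for (l in k:K) {
    add(paste0("omega_", k, l), grab(function(ch) ch$omega[, k, l]))
  }
  nmon <- min(n_beta_monitor, n * K)
  flat <- round(seq(1L, n * K, length.out = nmon))
  for (idx in flat) {
    i <- ((idx - 1L) %% n) + 1L
    k <- ((idx - 1L) %/% n) + 1L
    add(sprintf("beta_%d_%d", i, k), grab(function(ch) ch$beta[, i, k]))
  }
  do.call(rbind, rows)
}

#' Posterior relative-risk summaries per unit and outcome
#'
#' Exponentiates the coefficient-field draws to the relative-risk scale and
#' summarizes pooled chains with the posterior median and equal-tailed 95%
#' credible interval. A unit has a significant positive index effect when
#' the interval's lower bound exceeds 1.
#'
#' @param post an `svc_posterior`.
#' @param level credible level (default 0.95).
#' @return data.frame: `unit`, `outcome`, `rr_median`, `rr_lower`,
#'   `rr_upper`, `significant`.
#' @export
summarize_effects <- function(post, level = 0.95) {
  stopifnot(inherits(post, "svc_posterior"))
  beta <- pool_draws(post, "beta")
  if (dim(beta)[1] < 100L) stop("need at least 100 pooled draws")
  out <- vector("list", post$K)
  a <- (1 - level) / 2
  for (k in seq_len(post$K)) {
    qs <- apply(exp(beta[, , k, drop = FALSE]), 2L, stats::quantile,
                probs = c(a, 0.5, 1 - a), names = FALSE, type = 7)
    out[[k]] <- data.frame(unit = post$unit_ids, outcome = k,
                           rr_median = qs[2L, ], rr_lower = qs[1L, ],
                           rr_upper = qs[3L, ],
                           significant = qs[1L, ] > 1)
  }
  do.call(rbind, out)
}

#' Conditional correlations between outcome types
#'
#' Inverts each precision draw to the coefficient covariance `Sigma =
#' Omega^(-1)` and converts to correlations
#' `rho_kl = Sigma_kl / sqrt(Sigma_kk Sigma_ll)`, summarized by posterior
#' median and equal-tailed 95% interval per outcome pair.
#'
#' @param post an `svc_posterior`, or a T-by-K-by-K array of precision draws.
#' @param level credible level.
#' @return data.frame: `pair`, `k`, `l`, `median`, `lower`, `upper`.
#' @export
conditional_correlations <- function(post, level = 0.95) {
  omega <- if (inherits(post, "svc_posterior")) pool_draws(post, "omega") else post
  Tn <- dim(omega)[1]; K <- dim(omega)[2]
  if (K < 2L) stop("conditional correlations need K >= 2 outcomes")
  pairs <- utils::combn(K, 2L)
  rho <- matrix(NA_real_, Tn, ncol(pairs))
  for (t in seq_len(Tn)) {
    Sig <- tryCatch(solve(omega[t, , ]), error = function(e) {
      stop("numerically singular precision draw at index ", t)
    })
    s <- sqrt(diag(Sig))
    for (p in seq_len(ncol(pairs))) {
      k <- pairs[1L, p]; l <- pairs[2L, p]
      rho[t, p] <- Sig[k, l] / (s[k] * s[l])
    }
  }
  out <- data.frame(pair = apply(pairs, 2L, paste, collapse = "-"),
                    k = pairs[1L, ], l = pairs[2L, ])
  cs <- t(apply(rho, 2L, cri_summary, level = level))
  out$median <- cs[, "median"]; out$lower <- cs[, "lower"]; out$upper <- cs[, "upper"]
  out
}

#' Posterior summaries of the index weights
#'
#' Pooled-chain median and equal-tailed credible interval per weight,
#' returned ranked by median (raw medians; they need not sum to exactly 1
#' and are deliberately not renormalized).
#'
#' @param post an `svc_posterior`, or a draws-by-C weight matrix.
#' @param level credible level.
#' @return data.frame: `variable`, `median`, `lower`, `upper`, `rank`.
#' @export
summarize_weights <- function(post, level = 0.95) {
  w <- if (inherits(post, "svc_posterior")) pool_draws(post, "weights") else as.matrix(post)
  cs <- t(apply(w, 2L, cri_summary, level = level))
  out <- data.frame(variable = paste0("w_", seq_len(ncol(w))),
                    median = cs[, "median"], lower = cs[, "lower"],
                    upper = cs[, "upper"])
  out$rank <- rank(-out$median, ties.method = "first")
  out[order(out$rank), ]
}

#' Per-unit posterior median of the disadvantage index
#'
#' The per-draw index is `NDI_i = sum_j w_j q_ij` (exactly the values stored
#' during sampling); the per-unit posterior median over pooled chains is
#' reported. Values necessarily lie in \[1, 10\].
#'
#' @param post an `svc_posterior`.
#' @return data.frame: `unit`, `ndi_median`.
#' @export
summarize_ndi <- function(post) {
  stopifnot(inherits(post, "svc_posterior"))
  ndi <- pool_draws(post, "ndi")
  data.frame(unit = post$unit_ids,
             ndi_median = apply(ndi, 2L, stats::median))
}

#' Welch t-test comparisons of significant vs nonsignificant areas
#'
#' For each outcome, units are split by the significant-positive-effect flag
#' and the two groups are compared — on the posterior-median disadvantage
#' index and on each decile column — with Welch's unequal-variance t-test
#' (Welch-Satterthwaite degrees of freedom, two-sided p). Raw p-values are
#' reported without multiplicity correction.
#'
#' @param effects output of [summarize_effects()].
#' @param design a `decile_design`.
#' @param ndi_medians output of [summarize_ndi()] (or a numeric n-vector).
#' @return data.frame: `outcome`, `variable`, `mean_sig`, `mean_nonsig`,
#'   `t`, `df`, `p`; comparisons with a group smaller than 2 are skipped
#'   with a message.
#' @export
welch_tests <- function(effects, design, ndi_medians) {
  stopifnot(inherits(design, "decile_design"))
  ndi <- if (is.data.frame(ndi_medians)) ndi_medians$ndi_median else as.numeric(ndi_medians)
  vars <- cbind(NDI = ndi, design$q)
  vn <- c("NDI", colnames(design$q))
  if (is.null(colnames(design$q))) vn <- c("NDI", paste0("q_", seq_len(ncol(design$q))))
  rows <- list()
  for (k in sort(unique(effects$outcome))) {
    flag <- effects$significant[effects$outcome == k]
    if (sum(flag) < 2L || sum(!flag) < 2L) {
      message(sprintf("welch_tests: outcome %s has a group with fewer than 2 units; skipped", k))
      next
    }
    for (v in seq_along(vn)) {
      g1 <- vars[flag, v]; g0 <- vars[!flag, v]
      tt <- stats::t.test(g1, g0, var.equal = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = k, variable = vn[v],
        mean_sig = mean(g1), mean_nonsig = mean(g0),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value)
    }
  }
  if (!length(rows)) return(data.frame(outcome = integer(0), variable = character(0),
                                       mean_sig = numeric(0), mean_nonsig = numeric(0),
                                       t = numeric(0), df = numeric(0), p = numeric(0)))
  do.call(rbind, rows)
}
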