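# Shared numerical helpers.

is_pd <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) return(FALSE)
  ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
  ok && all(diag(m) > tol)
}

check_simplex <- function(w, tol = 1e-12) {
  if (any(!is.finite(w)) || any(w <= 0) || any(w >= 1)) {
    stop("weights must lie in the open simplex (each w_j in (0,1))")
  }
  if (abs(sum(w) - 1) > tol * length(w) * 10) stop("weights must sum to 1")
  invisible(w)
}

#' Draw from a Dirichlet distribution
#'
#' Gamma-ratio construction: independent Gamma(alpha_j, 1) draws normalized
#' by their sum.
#'
#' @param n number of draws.
#' @param alpha positive concentration vector.
#' @return n-by-length(alpha) matrix, rows on the simplex.
#' @export
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

# Equal-tailed credible interval + median from pooled draws
# (empirical quantiles, linear interpolation).
cri_summary <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  q <- stats::quantile(x, probs = c(a, 0.5, 1 - a), names = FALSE, type = 7)
  c(lower = q[1L], median = q[2L], upper = q[3L])
}

# Deterministic integer-vector hash mix for deriving per-chain seeds from a
# master seed; keeps results below 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 7919L + as.integer(stream) * 104729L) %% 2147483647L
}
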