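# Dense numerical-integration oracle for the joint posterior on a 4-unit
# path lattice with K = 1 outcome and C = 2 index variables, the intercept
# marginalized analytically. Independent of the sampler: plain grid
# integration of the unnormalized posterior
#   p(beta, w | y) ~ prod_i (e^{b_i d_i})^{y_i} * A^{-S_y}
#                    * exp(-omega/2 * sum_edges (b_i - b_j)^2),  w1 ~ U(0,1),
# where d_i = ndi_i(w) and A = sum_i E_i e^{b_i d_i} (flat prior on alpha
# integrated out; t = e^alpha | beta, w ~ Gamma(S_y, A), so
# E[alpha | beta, w] = digamma(S_y) - log A).

# broadcast a length-nb vector along dimension i of an nb^4 array
bcast4 <- function(v, i, nb) {
  array(rep(rep(v, each = nb^(i - 1)), times = nb^(4 - i)), rep(nb, 4))
}

joint_posterior_oracle <- function(y, E, q, omega, nb = 41, nw = 121,
                                   centers = rep(0, 4),
                                   halfwidth = rep(1.5, 4)) {
  Sy <- sum(y)
  wseq <- seq(0.002, 0.998, length.out = nw)
  bseq <- lapply(1:4, function(i) {
    seq(centers[i] - halfwidth[i], centers[i] + halfwidth[i], length.out = nb)
  })
  B <- lapply(1:4, function(i) bcast4(bseq[[i]], i, nb))
  mass_w <- numeric(nw)
  acc_b <- matrix(0, nw, 4)
  acc_b2 <- matrix(0, nw, 4)
  acc_a <- numeric(nw)
  lmx <- numeric(nw)   # per-slice log maximum, for overflow-safe rescaling
  for (m in seq_len(nw)) {
    d <- as.numeric(q %*% c(wseq[m], 1 - wseq[m]))
    lik <- y[1] * d[1] * B[[1]] + y[2] * d[2] * B[[2]] +
           y[3] * d[3] * B[[3]] + y[4] * d[4] * B[[4]]
    A <- E[1] * exp(B[[1]] * d[1]) + E[2] * exp(B[[2]] * d[2]) +
         E[3] * exp(B[[3]] * d[3]) + E[4] * exp(B[[4]] * d[4])
    car <- -0.5 * omega * ((B[[1]] - B[[2]])^2 + (B[[2]] - B[[3]])^2 +
                           (B[[3]] - B[[4]])^2)
    logpost <- lik - Sy * log(A) + car
    lmx[m] <- max(logpost)
    p <- exp(logpost - lmx[m])
    mass_w[m] <- sum(p)
    for (i in 1:4) {
      acc_b[m, i] <- sum(p * B[[i]])
      acc_b2[m, i] <- sum(p * B[[i]]^2)
    }
    acc_a[m] <- sum(p * (digamma(Sy) - log(A)))
  }
  rescale <- exp(lmx - max(lmx))
  mass <- mass_w * rescale
  Z <- sum(mass)
  mean_b <- colSums(acc_b * rescale) / Z
  var_b <- colSums(acc_b2 * rescale) / Z - mean_b^2
  list(w1 = sum(mass * wseq) / Z,
       beta = mean_b,
       beta_sd = sqrt(pmax(var_b, 0)),
       alpha = sum(acc_a * rescale) / Z)
}

# two-pass wrapper: coarse wide box to locate the posterior, then a refined
# box spanning mean +/- 7 posterior standard deviations per dimension
joint_posterior_oracle2 <- function(y, E, q, omega) {
  pass1 <- joint_posterior_oracle(y, E, q, omega, nb = 25, nw = 41,
                                  centers = rep(0, 4),
                                  halfwidth = rep(2.5, 4))
  joint_posterior_oracle(y, E, q, omega, nb = 41, nw = 121,
                         centers = pass1$beta,
                         halfwidth = pmax(7 * pass1$beta_sd, 0.3))
}
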