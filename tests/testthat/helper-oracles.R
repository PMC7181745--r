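# Independent oracles used to cross-check package computations.

# Beta-binomial pmf by numerical integration of the binomial pmf against
# the beta density (the compound-distribution definition). The integral is
# split at p = 1/2 and each half is integrated after the substitutions
# u = p^alpha and v = (1 - p)^beta, which absorb the endpoint
# singularities of the beta density exactly.
bb_pmf_quadrature <- function(k, n, mu, rho) {
  sh <- tribekit::bb_shape(mu, rho)
  a <- sh$alpha
  b <- sh$beta
  lB <- lbeta(a, b)
  qu <- function(f, lo, hi) {
    stats::integrate(f, lo, hi, rel.tol = 1e-11, abs.tol = 1e-13,
                     subdivisions = 2000L)$value
  }
  # scaled integrand of the compound integral, split at the beta mean so
  # adaptive quadrature resolves peaked shapes
  g <- function(p) {
    exp(stats::dbinom(k, n, p, log = TRUE) + (a - 1) * log(p) +
          (b - 1) * log1p(-p) - lB)
  }
  left <- if (a < 1) {
    # u = p^a absorbs the p^(a-1) endpoint singularity exactly
    qu(function(u) {
      p <- u^(1 / a)
      exp(stats::dbinom(k, n, p, log = TRUE) + (b - 1) * log1p(-p) - lB) / a
    }, 0, mu^a)
  } else {
    qu(g, 0, mu)
  }
  right <- if (b < 1) {
    qu(function(v) {
      p <- 1 - v^(1 / b)
      exp(stats::dbinom(k, n, p, log = TRUE) + (a - 1) * log(p) - lB) / b
    }, 0, (1 - mu)^b)
  } else {
    qu(g, mu, 1)
  }
  left + right
}

# Textbook step-up Benjamini-Hochberg: sort, p * m / rank, cumulative
# minimum from the largest rank down, cap at 1, restore input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Fisher's exact p by full enumeration of the hypergeometric support with
# binomial coefficients (no distribution functions).
fisher_enumeration_oracle <- function(tab, alternative = "two.sided") {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  prob <- choose(r1, support) * choose(n - r1, c1 - support) / choose(n, c1)
  obs <- prob[support == a]
  switch(alternative,
         two.sided = sum(prob[prob <= obs * (1 + 1e-7)]),
         greater = sum(prob[support >= a]),
         less = sum(prob[support <= a]))
}

# WPGMA (McQuitty) agglomeration computed directly on a distance matrix:
# after each merge, the new cluster's distance to any other cluster is the
# unweighted mean of its two members' distances.
wpgma_heights_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  diag(d) <- Inf
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    sub <- d[active, active, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[ij[1]]; j <- active[ij[2]]
    heights <- c(heights, d[i, j])
    new_d <- (d[i, ] + d[j, ]) / 2
    d[i, ] <- new_d; d[, i] <- new_d
    d[i, i] <- Inf
    active <- setdiff(active, j)
  }
  sort(heights)
}
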