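# Independent numerical oracles used across the test files.

# Beta-Bernoulli marginal by adaptive quadrature of the mixing integral.
quad_beta_marginal <- function(k, n, alpha, beta) {
  stats::integrate(function(th) th^k * (1 - th)^(n - k) *
                     stats::dbeta(th, alpha, beta),
                   0, 1, rel.tol = 1e-12)$value
}

dinvgamma <- function(x, shape, rate) {
  exp(shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x)
}

# NIG marginal density of one observation by nested 2-D quadrature:
# integrate the normal likelihood against N(mu0, theta/kappa) x IG prior.
quad_nig_marginal <- function(d, mu0, kappa, nu, sigma2) {
  inner <- function(theta) {
    vapply(theta, function(th) {
      stats::integrate(function(mu) {
        stats::dnorm(d, mu, sqrt(th)) * stats::dnorm(mu, mu0, sqrt(th / kappa))
      }, -Inf, Inf, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  stats::integrate(function(th) inner(th) * dinvgamma(th, nu / 2,
                                                      nu * sigma2 / 2),
                   0, Inf, rel.tol = 1e-9)$value
}

# Mann-Whitney AUC by brute-force pairwise counting.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (x in pos) for (y in neg) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# Two-sided Fisher p by direct hypergeometric enumeration over the table
# with fixed margins (all tables as extreme as observed).
hyper_two_sided_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k1 <- a + c
  xs <- max(0, k1 - n):min(k1, m)
  dens <- stats::dhyper(xs, m, n, k1)
  obs <- stats::dhyper(a, m, n, k1)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# SI by an explicit double loop over genes and conditions.
brute_si <- function(E, target, pseudocount = 1e-8) {
  m <- ncol(E); G <- nrow(E)
  others <- setdiff(seq_len(m), target)
  si <- numeric(G)
  for (g in seq_len(G)) {
    acc <- 0
    for (k in others) {
      fc <- (E[, target] + pseudocount) / (E[, k] + pseudocount)
      acc <- acc + rank(-fc, ties.method = "average")[g]
    }
    si[g] <- acc / (m - 1)
  }
  stats::setNames(si, rownames(E))
}

# tiny deterministic toy network shared by several tests
toy_triangle <- function() {
  gene_network(data.frame(gene1 = c("A", "A", "B"),
                          gene2 = c("B", "C", "C"),
                          weight = c(1, 1, 1)))
}
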