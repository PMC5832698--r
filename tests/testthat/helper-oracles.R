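# Independent oracles used across the suite. All are deliberately naive
# (explicit inversion, closed forms, exhaustive enumeration) and never share
# code with the package internals they check.

# Closed-form Jukes-Cantor pairwise log-likelihood for an alignment with
# n_same identical and n_diff differing sites at total separation t.
jc_pair_loglik <- function(t, n_same, n_diff) {
  p_same <- 0.25 + 0.75 * exp(-4 * t / 3)
  p_diff <- 0.25 - 0.25 * exp(-4 * t / 3)   # to one specific other base
  n_same * log(0.25 * p_same) + n_diff * log(0.25 * p_diff)
}

# Closed-form JC distance from a proportion of differing sites.
jc_distance <- function(p) -0.75 * log(1 - 4 * p / 3)

# Brute-force GLS Brownian-motion fit: explicit matrix inversion and
# determinant, no factorisations.
gls_bm_oracle <- function(tree, x) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  n <- length(x)
  Ci <- solve(C)
  ones <- rep(1, n)
  theta <- as.numeric((ones %*% Ci %*% x) / (ones %*% Ci %*% ones))
  r <- x - theta
  s2 <- as.numeric(r %*% Ci %*% r) / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + log(det(C)) + n)
  list(theta = theta, sigma2 = s2, loglik = ll)
}

# Exhaustive two-sided Fisher exact p for a 2x2 table, by hypergeometric
# enumeration over all tables with the observed margins.
fisher_p_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k) dhyper(k, r1, r2, c1), numeric(1))
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A small random ultrametric tree in Myr.
random_time_tree <- function(n, seed, crown = 1) {
  tr <- evoscales::simulate_coalescent_tree(n, seed = seed)
  evoscales::calibrate_relative_tree(tr, crown)
}

# Shared small fixture for the expensive integration tests (built once).
small_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- evoscales::make_study_fixture(master_seed = 7)
    fx
  }
})
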