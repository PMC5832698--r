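#' Phylogenetic covariance matrix under Brownian motion
#'
#' `C[i, j]` is the shared root-to-MRCA path length (in the tree's time
#' units) of tips i and j; the diagonal holds tip depths. Symmetric and
#' positive semi-definite by construction.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param order optional tip ordering for the rows/columns.
#' @return numeric matrix with tip-label dimnames.
#' @export
phylo_covariance <- function(tree, order = NULL) {
  .validate_tree(tree, "phylo_covariance")
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  C <- ape::vcv(tree)
  if (!is.null(order)) {
    if (!setequal(order, rownames(C)))
      stop("'order' must be a permutation of the tip labels", call. = FALSE)
    C <- C[order, order]
  }
  C
}

#' Fitted trait-model objects
#'
#' Container for a maximum-likelihood fit of a Brownian-motion (BM) or
#' Ornstein-Uhlenbeck (OU) model: the rate `sigma2` (trait^2/Myr), the OU
#' pull strength `alpha` (/Myr, `NA` for BM), the root/optimum `theta`
#' (trait units), the log-likelihood, the parameter count `k` and the AICc.
#'
#' @param model `"BM"` or `"OU"`.
#' @param sigma2,alpha,theta,loglik,k,n fitted quantities; see Description.
#' @return an object of class `model_fit`.
#' @export
model_fit <- function(model, sigma2, alpha = NA_real_, theta, loglik, k, n) {
  stopifnot(model %in% c("BM", "OU"), sigma2 >= 0, k >= 1, n >= 1)
  if (model == "OU" && (!is.finite(alpha) || alpha <= 0))
    stop("OU fit requires alpha > 0", call. = FALSE)
  structure(list(model = model, sigma2 = sigma2, alpha = alpha, theta = theta,
                 loglik = loglik, k = k, n = n,
                 aicc = if (n > k + 1) aicc(loglik, k, n) else NA_real_),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: sigma2 = %.6g", x$model, x$sigma2))
  if (x$model == "OU") cat(sprintf(", alpha = %.6g", x$alpha))
  cat(sprintf(", theta = %.6g, logL = %.4f, AICc = %.4f (k = %d, n = %d)\n",
              x$theta, x$loglik, x$aicc, x$k, x$n))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik log-likelihood.
#' @param k number of parameters.
#' @param n number of observations (tips); must exceed `k + 1`.
#' @return scalar AICc.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# GLS machinery shared by the BM and OU fits: for covariance structure V0
# (V = sigma2 * V0), profile out theta and sigma2 analytically.
# Returns theta-hat, sigma2-hat (ML divisor n) and the exact log-likelihood.
.gls_profile <- function(V0, x) {
  n <- length(x)
  L <- tryCatch(chol(V0), error = function(e)
    stop("covariance matrix is singular", call. = FALSE))
  logdet <- 2 * sum(log(diag(L)))
  ones <- rep(1, n)
  iv_x <- backsolve(L, forwardsolve(t(L), x))
  iv_1 <- backsolve(L, forwardsolve(t(L), ones))
  theta <- sum(iv_x) / sum(iv_1)
  r <- x - theta
  q <- sum(r * backsolve(L, forwardsolve(t(L), r)))
  sigma2 <- q / n
  loglik <- if (sigma2 > 0) {
    -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  } else {
    Inf  # degenerate: identical tip values; sigma2 -> 0, density unbounded
  }
  list(theta = theta, sigma2 = sigma2, loglik = loglik)
}

#' Maximum-likelihood Brownian-motion fit
#'
#' Fits BM by generalised least squares on the phylogenetic covariance:
#' `theta = (1' C^-1 x) / (1' C^-1 1)`, `sigma2 = (x - theta)' C^-1
#' (x - theta) / n` (ML divisor `n`), with the exact multivariate-normal
#' log-likelihood; `k = 2` parameters.
#'
#' @param tree dated `phylo` (Myr).
#' @param traits trait values: named vector or `trait_table` (individual
#'   values are averaged per species).
#' @return a [model_fit()].
#' @export
fit_bm <- function(tree, traits) {
  x <- .trait_vector(traits, tree$tip.label)
  C <- phylo_covariance(tree, order = names(x))
  .fit_bm_C(C, x)
}

.fit_bm_C <- function(C, x) {
  g <- .gls_profile(C, x)
  if (!is.finite(g$loglik)) {       # constant traits
    return(model_fit("BM", sigma2 = 0, theta = g$theta,
                     loglik = Inf, k = 2, n = length(x)))
  }
  model_fit("BM", sigma2 = g$sigma2, theta = g$theta, loglik = g$loglik,
            k = 2, n = length(x))
}

# OU covariance structure (unit sigma2), root fixed at theta:
# V0_ij = exp(-2 a (T - C_ij)) * (1 - exp(-2 a C_ij)) / (2 a).
.ou_V0 <- function(C, alpha, T) {
  if (alpha < 1e-12) return(C)
  exp(-2 * alpha * (T - C)) * (-expm1(-2 * alpha * C)) / (2 * alpha)
}

#' Maximum-likelihood Ornstein-Uhlenbeck fit
#'
#' Fits an OU model with the root state fixed at the optimum `theta` (the
#' identifiable choice on ultrametric trees): `V_ij = sigma2/(2 alpha) *
#' exp(-2 alpha (T - C_ij)) * (1 - exp(-2 alpha C_ij))`. For each candidate
#' `alpha`, `theta` and `sigma2` are profiled analytically by GLS; `alpha`
#' is searched on a 40-point log grid spanning `[1e-6, 50] / T` and refined
#' by bounded 1-D optimisation around the grid optimum. `k = 3`.
#'
#' @param tree dated `phylo`; a warning is issued for non-ultrametric trees
#'   (the OU covariance form assumes ultrametricity).
#' @param traits trait values (named vector or `trait_table`).
#' @return a [model_fit()] with `alpha` filled.
#' @export
fit_ou <- function(tree, traits) {
  x <- .trait_vector(traits, tree$tip.label)
  if (!is_ultrametric_tree(tree))
    warning("tree is not ultrametric; OU covariance form assumes ultrametricity")
  C <- phylo_covariance(tree, order = names(x))
  .fit_ou_C(C, x)
}

.fit_ou_C <- function(C, x) {
  n <- length(x)
  T <- max(diag(C))
  grid <- exp(seq(log(1e-6 / T), log(50 / T), length.out = 40))
  prof <- function(a) {
    g <- .gls_profile(.ou_V0(C, a, T), x)
    g$loglik
  }
  ll <- vapply(grid, prof, numeric(1))
  if (all(!is.finite(ll))) {        # constant traits
    return(model_fit("OU", sigma2 = 0, alpha = grid[1], theta = x[1],
                     loglik = Inf, k = 3, n = n))
  }
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(u) prof(exp(u)), interval = log(c(lo, hi)),
                  maximum = TRUE, tol = 1e-8)
  a_hat <- exp(opt$maximum)
  if (opt$objective < ll[i]) a_hat <- grid[i]
  g <- .gls_profile(.ou_V0(C, a_hat, T), x)
  model_fit("OU", sigma2 = g$sigma2, alpha = a_hat, theta = unname(g$theta),
            loglik = g$loglik, k = 3, n = n)
}

#' Select the best model by AICc
#'
#' Recomputes each fit's AICc at the stated `n` and returns the fit with the
#' smallest value; ties (difference < 1e-6) go to the model with fewer
#' parameters.
#'
#' @param fits list of [model_fit()] objects.
#' @param n number of tips.
#' @return the selected `model_fit` (with an `aicc_table` attribute).
#' @export
aicc_select <- function(fits, n) {
  stopifnot(length(fits) >= 1L)
  tab <- data.frame(
    model = vapply(fits, function(f) f$model, ""),
    k = vapply(fits, function(f) f$k, 0),
    loglik = vapply(fits, function(f) f$loglik, 0),
    aicc = vapply(fits, function(f) aicc(f$loglik, f$k, n), 0)
  )
  best <- which(tab$aicc <= min(tab$aicc) + 1e-6)
  best <- best[which.min(tab$k[best])]
  out <- fits[[best]]
  out$aicc <- tab$aicc[best]
  attr(out, "aicc_table") <- tab
  out
}

#' Probability that simulated rates predict the empirical rate
#'
#' The fraction of simulated rates that fall inside the empirical 95%
#' equal-tailed percentile interval. The predicted and empirical rate
#' distributions are declared not significantly different when the fraction
#' is at least 0.05.
#'
#' @param sim_rates simulated sigma^2 sample (non-empty).
#' @param emp_rates empirical sigma^2 sample (non-empty).
#' @return the in-interval fraction `p`, with attribute `significant`
#'   (`TRUE` when `p < 0.05`).
#' @export
prediction_probability <- function(sim_rates, emp_rates) {
  if (length(sim_rates) == 0L || length(emp_rates) == 0L)
    stop("empty rate sample", call. = FALSE)
  ci <- quantile(emp_rates, c(0.025, 0.975), type = 7)
  p <- mean(sim_rates >= ci[1] & sim_rates <= ci[2])
  attr(p, "significant") <- p < 0.05
  p
}

# Simulate one MVN dataset x ~ N(theta, sigma2 * V0) given chol(V0).
.sim_mvn <- function(theta, sigma2, cholV0) {
  n <- ncol(cholV0)
  theta + sqrt(sigma2) * as.vector(crossprod(cholV0, rnorm(n)))
}

# Fit the named model from a precomputed covariance (fast path for loops).
.fit_model_C <- function(model, C, x) {
  if (model == "BM") .fit_bm_C(C, x) else .fit_ou_C(C, x)
}

#' Drift-based prediction test for trait rates
#'
#' The core prediction loop: simulate species-mean trait evolution from the
#' intraspecific drift parameters along the tree, fit the trait model
#' selected on the empirical data, and ask how often the simulated rates
#' fall inside the empirical 95% rate interval. The empirical rate
#' distribution is obtained by parametric bootstrap of the selected
#' empirical fit (refitting data simulated under that fit), standing in for
#' a posterior tree distribution.
#'
#' @param tree dated `phylo` (Myr).
#' @param traits empirical species trait values.
#' @param p a [drift_params()] object.
#' @param n_sim simulations per sample (drift and bootstrap).
#' @param seed integer seed.
#' @param mode drift mode, `"exact"` or `"diffusion"`.
#' @return list with the selected empirical fit, the empirical and simulated
#'   sigma^2 samples, and the prediction probability `p`.
#' @export
drift_prediction_test <- function(tree, traits, p, n_sim = 100, seed = 1L,
                                  mode = c("exact", "diffusion")) {
  mode <- match.arg(mode)
  x <- .trait_vector(traits, tree$tip.label)
  C <- phylo_covariance(tree, order = names(x))
  emp <- aicc_select(list(.fit_bm_C(C, x), .fit_ou_C(C, x)), n = length(x))
  local_seed(seed, {
    T <- max(diag(C))
    V0 <- if (emp$model == "BM") C else .ou_V0(C, emp$alpha, T)
    cholV0 <- chol(V0)
    emp_rates <- vapply(seq_len(n_sim), function(i)
      .fit_model_C(emp$model, C, .sim_mvn(emp$theta, emp$sigma2, cholV0))$sigma2,
      numeric(1))
    sims <- simulate_trait_replicates(tree, p, n_sim, root_value = mean(x),
                                      mode = mode,
                                      master_seed = sample.int(2^30, 1))
    sim_rates <- apply(sims, 2, function(v)
      .fit_model_C(emp$model, C, v[rownames(C)])$sigma2)
    pp <- prediction_probability(sim_rates, emp_rates)
    list(empirical_fit = emp, emp_rates = emp_rates, sim_rates = sim_rates,
         p = as.numeric(pp), significant = attr(pp, "significant"))
  })
}

#' Specificity of the drift prediction to the effective population size
#'
#' Reruns the full drift-to-fit prediction pipeline with the effective
#' population size multiplied by each scale factor, reporting the
#' prediction probability against the empirical rate distribution each
#' time. A prediction that only matches at the true Ne (small p at
#' strongly mis-scaled Ne) shows the micro-to-macro link is specific, not a
#' statistical-power artefact.
#'
#' @param tree dated `phylo` (Myr).
#' @param traits empirical species trait values.
#' @param p a [drift_params()] object (the reference parameters).
#' @param scales positive multipliers applied to `Ne`.
#' @param n_sim simulations per scale.
#' @param seed integer seed.
#' @param mode drift mode passed to [drift_prediction_test()].
#' @return data.frame with columns `scale`, `Ne`, `p`, `significant`.
#' @export
specificity_test <- function(tree, traits, p, scales = c(0.01, 0.1, 1, 10, 100),
                             n_sim = 100, seed = 1L,
                             mode = c("exact", "diffusion")) {
  mode <- match.arg(mode)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("scales must be positive", call. = FALSE)
  rows <- lapply(seq_along(scales), function(k) {
    Ne_k <- max(2L, as.integer(round(p$Ne * scales[k])))
    pk <- drift_params(p$s2, Ne_k, p$tau)
    res <- drift_prediction_test(tree, traits, pk, n_sim = n_sim,
                                 seed = seed + k, mode = mode)
    data.frame(scale = scales[k], Ne = Ne_k, p = res$p,
               significant = res$significant)
  })
  do.call(rbind, rows)
}

#' Parametric-bootstrap power analysis for BM vs OU
#'
#' Phylogenetic Monte Carlo: both models are fitted to the data; `B`
#' datasets are simulated under each fitted model and both models refitted
#' to every one, giving null (BM-generated) and alternative (OU-generated)
#' distributions of the likelihood-ratio statistic
#' `delta = 2 (logL_OU - logL_BM)`. BM is rejected when `delta` exceeds the
#' 95th percentile of the null distribution; the power is the fraction of
#' alternative-simulated datasets that reject.
#'
#' The type-I summary is estimated from a second, independent batch of `B`
#' datasets simulated under the fitted BM model: the fraction rejected at
#' the first batch's critical value, expected near the nominal 5%.
#'
#' @param tree dated `phylo` (Myr).
#' @param traits species trait values.
#' @param B number of bootstrap replicates per model (>= 50).
#' @param seed integer seed.
#' @return list with both fits, the observed `delta` and its bootstrap
#'   p-value, the critical value, the power, the independent-batch `type1`
#'   rate, and the `delta` samples.
#' @export
pmc_power <- function(tree, traits, B = 200, seed = 1L) {
  if (B < 50) stop("B must be at least 50", call. = FALSE)
  x <- .trait_vector(traits, tree$tip.label)
  C <- phylo_covariance(tree, order = names(x))
  T <- max(diag(C))
  fit0 <- .fit_bm_C(C, x)
  fit1 <- .fit_ou_C(C, x)
  delta_obs <- 2 * (fit1$loglik - fit0$loglik)
  local_seed(seed, {
    cholC <- chol(C)
    cholV1 <- chol(.ou_V0(C, fit1$alpha, T))
    delta_of <- function(v) {
      2 * (.fit_ou_C(C, v)$loglik - .fit_bm_C(C, v)$loglik)
    }
    delta_null <- vapply(seq_len(B), function(b)
      delta_of(.sim_mvn(fit0$theta, fit0$sigma2, cholC)), numeric(1))
    delta_alt <- vapply(seq_len(B), function(b)
      delta_of(.sim_mvn(fit1$theta, fit1$sigma2, cholV1)), numeric(1))
    crit <- quantile(delta_null, 0.95, type = 7)
    delta_null2 <- vapply(seq_len(B), function(b)
      delta_of(.sim_mvn(fit0$theta, fit0$sigma2, cholC)), numeric(1))
    list(fit_bm = fit0, fit_ou = fit1,
         delta_obs = delta_obs,
         p_value = mean(delta_null >= delta_obs),
         critical = unname(crit),
         power = mean(delta_alt > crit),
         type1 = mean(delta_null2 > crit),
         delta_null = delta_null, delta_alt = delta_alt)
  })
}
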