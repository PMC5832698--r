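test_that("phylogenetic covariance has shared-path entries and is PSD", {
  two <- read_newick("(A:1,B:1);")
  expect_equal(phylo_covariance(two), matrix(c(1, 0, 0, 1), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B"))))
  comb <- read_newick("((A:1,B:1):1,C:2);")
  C <- phylo_covariance(comb)
  expect_equal(unname(diag(C)), c(2, 2, 2))
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  for (i in 1:20) {
    Ci <- phylo_covariance(random_time_tree(sample(3:12, 1), seed = 200 + i))
    expect_true(isSymmetric(Ci))
    expect_gte(min(eigen(Ci, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  }
})

test_that("BM fit equals the brute-force GLS oracle", {
  # closed-form two-tip case
  two <- read_newick("(A:1,B:1);")
  f <- fit_bm(two, c(A = 0, B = 2))
  expect_equal(f$theta, 1)
  expect_equal(f$sigma2, 1)
  expect_equal(f$k, 2)

  # identical tip values: zero rate
  expect_equal(fit_bm(two, c(A = 1, B = 1))$sigma2, 0)

  set.seed(31)
  for (i in 1:20) {
    tr <- random_time_tree(sample(4:8, 1), seed = 300 + i)
    x <- setNames(rnorm(ape::Ntip(tr), sd = 2), tr$tip.label)
    mine <- fit_bm(tr, x)
    oracle <- gls_bm_oracle(tr, x)
    expect_equal(mine$theta, oracle$theta, tolerance = 1e-8)
    expect_equal(mine$sigma2, oracle$sigma2, tolerance = 1e-8)
    expect_equal(mine$loglik, oracle$loglik, tolerance = 1e-8)
  }
})

test_that("BM rate is recovered from simulated data", {
  tr <- simulate_bd_tree(26, 0.3, 0.1, 10, seed = 33)
  p <- drift_params(1, 1000, 10)     # sigma2_pred = 100
  reps <- simulate_trait_replicates(tr, p, 500, mode = "diffusion",
                                    master_seed = 34)
  s2 <- apply(reps, 2, function(v) fit_bm(tr, v)$sigma2)
  expect_lt(abs(mean(s2) - 100) / 100, 0.1)
})

test_that("OU fit: BM limit, recovery and profile continuity", {
  tr <- simulate_bd_tree(26, 0.3, 0.1, 10, seed = 35)
  x <- simulate_trait_replicates(tr, drift_params(1, 1000, 5), 1,
                                 mode = "diffusion", master_seed = 36)[, 1]
  fb <- fit_bm(tr, x)
  fo <- fit_ou(tr, x)
  expect_gte(fo$loglik, fb$loglik - 1e-4)  # BM nested in OU (alpha -> 0 limit)
  C <- phylo_covariance(tr, order = names(x))
  ll_tiny_alpha <- evoscales:::.gls_profile(
    evoscales:::.ou_V0(C, 1e-8, max(diag(C))), x)$loglik
  expect_equal(ll_tiny_alpha, fb$loglik, tolerance = 1e-4)

  # profile log-likelihood is continuous in alpha near the optimum
  T <- max(diag(C))
  prof <- function(a) evoscales:::.gls_profile(evoscales:::.ou_V0(C, a, T), x)$loglik
  a0 <- max(fo$alpha, 1e-3 / T)
  grid <- seq(a0 * 0.9, a0 * 1.1, length.out = 100)
  lls <- vapply(grid, prof, numeric(1))
  expect_lt(max(abs(diff(lls))), 1e-3)

  # constant traits: zero rate
  expect_equal(fit_ou(tr, setNames(rep(1, 26), tr$tip.label))$sigma2, 0)

  # strong-pull recovery: median alpha within a factor of 2
  tr50 <- simulate_bd_tree(50, 0.5, 0.1, 5, seed = 37)
  C50 <- phylo_covariance(tr50)
  T50 <- max(diag(C50))
  V <- evoscales:::.ou_V0(C50, 2, T50)
  set.seed(38)
  L <- chol(V)
  a_hat <- replicate(15, {
    xs <- setNames(3 + as.vector(crossprod(L, rnorm(50))), rownames(C50))
    fit_ou(tr50, xs)$alpha
  })
  expect_gt(median(a_hat), 1)
  expect_lt(median(a_hat), 4)
})

test_that("AICc selection uses the small-sample formula and tie rule", {
  expect_equal(aicc(-10, 2, 26), 24 + 12 / 23)
  expect_error(aicc(-10, 3, 4), "undefined")

  f_bm <- model_fit("BM", sigma2 = 1, theta = 0, loglik = -10, k = 2, n = 26)
  f_ou <- model_fit("OU", sigma2 = 1, alpha = 0.5, theta = 0,
                    loglik = -10 + (aicc(-10, 3, 26) - aicc(-10, 2, 26)) / 2,
                    k = 3, n = 26)
  # engineered exact AICc tie: the model with fewer parameters wins
  expect_equal(aicc(f_ou$loglik, 3, 26), aicc(f_bm$loglik, 2, 26))
  expect_equal(aicc_select(list(f_ou, f_bm), 26)$model, "BM")
  # clear winner
  f_ou2 <- model_fit("OU", 1, 0.5, 0, loglik = -2, k = 3, n = 26)
  expect_equal(aicc_select(list(f_bm, f_ou2), 26)$model, "OU")
  expect_error(aicc_select(list(f_ou), 4), "undefined")
})

test_that("prediction probability counts the in-interval fraction", {
  emp <- 1:1000
  expect_equal(as.numeric(prediction_probability(c(300, 500, 700), emp)), 1)
  expect_equal(as.numeric(prediction_probability(c(2000, 3000), emp)), 0)
  sims <- c(runif(30, 100, 900), runif(970, 2000, 3000))
  p <- prediction_probability(sims, emp)
  expect_equal(as.numeric(p), 0.03)
  expect_true(attr(p, "significant"))
  # invariant to a common positive rescaling of both samples
  expect_equal(as.numeric(prediction_probability(sims * 1e-6, emp * 1e-6)),
               as.numeric(p))
  expect_error(prediction_probability(numeric(0), emp), "empty")
})

test_that("specificity test flags strongly mis-scaled population sizes", {
  tr <- simulate_bd_tree(20, 0.4, 0.1, 5, seed = 40)
  p <- drift_params(1, 800, 100)
  x <- simulate_trait_replicates(tr, p, 1, mode = "diffusion",
                                 master_seed = 41)[, 1]
  expect_error(specificity_test(tr, x, p, scales = 0), "positive")
  res <- specificity_test(tr, x, p, scales = c(0.01, 1, 100), n_sim = 60,
                          seed = 42, mode = "diffusion")
  expect_equal(res$scale, c(0.01, 1, 100))
  expect_true(all(res$p[res$scale != 1] < 0.05))
  expect_gte(res$p[res$scale == 1], 0.05)
})

test_that("pmc power analysis validates input and detects strong OU", {
  tr <- simulate_bd_tree(30, 0.5, 0.1, 5, seed = 43)
  expect_error(pmc_power(tr, setNames(rnorm(30), tr$tip.label), B = 10),
               "at least 50")
  # strongly OU data (alpha * T = 5): power above one half
  C <- phylo_covariance(tr)
  T <- max(diag(C))
  V <- evoscales:::.ou_V0(C, 5 / T, T)
  set.seed(44)
  x <- setNames(as.vector(crossprod(chol(V), rnorm(30))), rownames(C))
  res <- pmc_power(tr, x, B = 60, seed = 45)
  expect_gt(res$power, 0.5)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_equal(res$delta_obs, 2 * (res$fit_ou$loglik - res$fit_bm$loglik))
})

test_that("drift prediction test composes simulation, fit and probability", {
  tr <- simulate_bd_tree(15, 0.4, 0.1, 5, seed = 46)
  p <- drift_params(1, 500, 100)
  x <- simulate_trait_replicates(tr, p, 1, mode = "diffusion",
                                 master_seed = 47)[, 1]
  res <- drift_prediction_test(tr, x, p, n_sim = 60, seed = 48,
                               mode = "diffusion")
  expect_true(res$empirical_fit$model %in% c("BM", "OU"))
  expect_length(res$sim_rates, 60)
  expect_gte(res$p, 0.05)    # matched parameters should predict the rate
})
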