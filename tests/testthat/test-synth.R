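test_that("birth-death species trees are ultrametric, sized and seeded", {
  tr <- simulate_bd_tree(26, 0.3, 0.1, 10, seed = 60)
  expect_equal(ape::Ntip(tr), 26)
  expect_true(is_ultrametric_tree(tr))
  expect_equal(tree_height(tr), 10, tolerance = 1e-9)
  expect_identical(write_newick(simulate_bd_tree(10, 0.3, 0, 5, seed = 61)),
                   write_newick(simulate_bd_tree(10, 0.3, 0, 5, seed = 61)))
  expect_error(simulate_bd_tree(10, 0.1, 0.3, 5, seed = 1), "birth_rate")
  expect_error(simulate_bd_tree(1, 0.3, 0.1, 5, seed = 1), "n_tips")
})

test_that("coalescent trees match Kingman expectations", {
  expect_error(simulate_coalescent_tree(1), "n must be")
  expect_identical(write_newick(simulate_coalescent_tree(8, seed = 62)),
                   write_newick(simulate_coalescent_tree(8, seed = 62)))
  set.seed(63)
  h2 <- replicate(4000, tree_height(simulate_coalescent_tree(2)))
  expect_lt(abs(mean(h2) - 1), 0.05)          # Exp(1) waiting time
  h10 <- replicate(4000, tree_height(simulate_coalescent_tree(10)))
  expect_lt(abs(mean(h10) - 1.8) / 1.8, 0.03) # 2 (1 - 1/10)
  # unit conversion: one coalescent unit = Ne * tau * 1e-6 Myr
  tr <- simulate_coalescent_tree(5, seed = 64)
  myr <- coalescent_units_to_myr(tr, Ne = 1000, tau = 5)
  expect_equal(myr$edge.length, tr$edge.length * 0.005)
  expect_equal(tree_units(myr), "Myr")
})

test_that("sequence simulation is clock-consistent and codon-safe", {
  m <- subst_model("JC")
  tr <- read_newick("(A:5,B:5);", units = "Myr")
  same <- simulate_sequences(tr, m, rate = 0, n_sites = 60, seed = 65)
  expect_identical(same["A", ], same["B", ])
  expect_error(simulate_sequences(tr, m, rate = 1e-3, n_sites = 0, seed = 1),
               "n_sites")

  # expected JC p-distance at separation 2 * 5 * 0.01 = 0.1 subs/site
  big <- simulate_sequences(tr, m, rate = 0.01, n_sites = 6000, seed = 66)
  p_obs <- mean(big["A", ] != big["B", ])
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 6000))

  # codon-safe simulation never produces internal stops
  stops <- c("TAA", "TAG", "TGA")
  tr2 <- random_time_tree(6, seed = 67, crown = 5)
  cs <- simulate_sequences(tr2, m, rate = 0.05, n_sites = 300, seed = 68,
                           codon_safe = TRUE)
  for (i in seq_len(nrow(cs))) {
    cods <- apply(matrix(cs[i, ], nrow = 3), 2, paste, collapse = "")
    expect_false(any(cods %in% stops))
  }
})

test_that("intraspecific traits scatter around species means with variance s2", {
  means <- c(spA = 2, spB = -1)
  t0 <- simulate_intraspecific_traits(means, s2 = 0, n_per_species = 3, seed = 69)
  expect_equal(t0$value, rep(c(2, -1), each = 3))
  t1 <- simulate_intraspecific_traits(means, s2 = 4, n_per_species = 1000,
                                      seed = 70)
  resid <- t1$value - rep(means, each = 1000)
  expect_lt(abs(var(resid) - 4) / 4, 0.1)    # pooled over both species
  expect_identical(t1, simulate_intraspecific_traits(means, 4, 1000, seed = 70))
})

test_that("depth/genotype simulation is balanced, truncated and calibrated", {
  d <- simulate_depth_genotype(53, effect_m = 8, seed = 71)
  expect_equal(nrow(d), 53)
  expect_true(all(d$depth >= 0.5))
  expect_equal(sort(unique(d$state)), c("I", "L"))
  expect_lte(abs(diff(table(d$state))), 1)
  expect_error(simulate_depth_genotype(3, 8), "n must be")
  # a large effect is detected essentially always
  set.seed(72)
  ps <- replicate(40, depth_association(
    simulate_depth_genotype(40, effect_m = 30, sd_m = 3))$p)
  expect_gte(mean(ps < 0.01), 0.95)
})

test_that("the study fixture composes all simulators with known truth", {
  fx <- small_fixture()
  expect_equal(ape::Ntip(fx$species_tree), 26)
  expect_length(fx$individuals, 53)
  expect_equal(ape::Ntip(fx$combined_tree), 26 - 1 + 53)
  expect_equal(ncol(fx$alignment), 3 * 251)
  expect_true(is_ultrametric_tree(fx$combined_tree))
  expect_length(fx$species_dist, fx$params$n_trees)

  # bit-identical regeneration from the parameter record
  fx2 <- make_study_fixture(master_seed = fx$params$master_seed)
  expect_identical(fx2$alignment, fx$alignment)
  expect_identical(write_newick(fx2$combined_tree), write_newick(fx$combined_tree))
  expect_identical(fx2$traits$value, fx$traits$value)
})

test_that("fixture files round-trip through the package readers", {
  fx <- make_study_fixture(list(n_species = 5L, n_individuals = 4L,
                                n_codons = 30L, n_trees = 3L), master_seed = 73)
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  tr <- read_newick(readLines(file.path(dir, "species_tree.nwk")), units = "Myr")
  expect_equal(ape::Ntip(tr), 5)
  dist <- read_tree_distribution(file.path(dir, "combined_dist.nwk"))
  expect_length(dist, 3)
  aln <- read_fasta(file.path(dir, "alignment.fasta"))
  ref <- fx$alignment; attr(ref, "n_resampled") <- NULL
  expect_identical(aln, ref)
  tt <- read_trait_table(file.path(dir, "species_traits.tsv"))
  expect_equal(nrow(tt), 5)
  prm <- jsonlite::read_json(file.path(dir, "params.json"))
  expect_equal(prm$master_seed, 73)

  # a minimal fixture still runs the core pipeline end to end
  mini <- make_study_fixture(list(n_species = 3L, n_individuals = 4L,
                                  n_codons = 20L, n_trees = 2L),
                             master_seed = 74)
  m <- subst_model("HKY", kappa = 4, pi = mini$params$pi)
  est <- rate_over_distribution(mini$micro_dist,
                                mini$alignment[mini$individuals, ], m)
  expect_s3_class(est, "rate_estimate")
  fit <- fit_bm(mini$species_tree, mini$traits)
  expect_s3_class(fit, "model_fit")
})
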