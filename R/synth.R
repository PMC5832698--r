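# Synthetic-data generator emulating the study design: a dated species tree,
# an intraspecific coalescent nested in one species, clock-like codon
# sequences with an elevated within-species rate (transient polymorphism),
# drift-evolved traits with intraspecific scatter, and a depth/genotype table.

#' Simulate a dated birth-death species tree
#'
#' Birth-death tree conditioned on the number of extant tips, rescaled to
#' the requested crown age.
#'
#' @param n_tips number of extant species (>= 2).
#' @param birth_rate speciation rate (> death_rate).
#' @param death_rate extinction rate (>= 0).
#' @param crown_age_Myr crown age of the returned tree.
#' @param seed integer seed.
#' @return ultrametric `phylo` in Myr.
#' @export
simulate_bd_tree <- function(n_tips, birth_rate, death_rate, crown_age_Myr,
                             seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  if (!(birth_rate > death_rate) || death_rate < 0)
    stop("need birth_rate > death_rate >= 0", call. = FALSE)
  tree <- local_seed(seed, ape::rphylo(n_tips, birth = birth_rate,
                                       death = death_rate, fossils = FALSE))
  calibrate_relative_tree(set_tree_units(tree, "relative"), crown_age_Myr)
}

#' Simulate a Kingman coalescent tree
#'
#' Constant-population-size coalescent: with k lineages the waiting time to
#' the next coalescence is exponential with rate `k (k - 1) / 2`. Branch
#' lengths are in coalescent units; one unit corresponds to `Ne`
#' generations, i.e. `Ne * tau * 1e-6` Myr (see
#' [coalescent_units_to_myr()]).
#'
#' @param n number of sampled lineages (>= 2).
#' @param seed integer seed.
#' @return `phylo` with units `"coalescent"`.
#' @export
simulate_coalescent_tree <- function(n, seed = NULL) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  tree <- local_seed(seed, ape::rcoal(n))
  set_tree_units(tree, "coalescent")
}

#' Convert a coalescent-units tree to Myr
#'
#' One coalescent unit equals `Ne` generations of `tau` years, i.e.
#' `Ne * tau * 1e-6` Myr.
#'
#' @param tree `phylo` in coalescent units.
#' @param Ne effective population size.
#' @param tau generation time in years.
#' @return `phylo` in Myr.
#' @export
coalescent_units_to_myr <- function(tree, Ne, tau) {
  .check_units(tree, "coalescent")
  tree$edge.length <- tree$edge.length * (Ne * tau * 1e-6)
  set_tree_units(tree, "Myr")
}

#' Jitter the node ages of an ultrametric tree
#'
#' Emulates the dating uncertainty of a posterior tree sample on a fixed
#' topology: the crown age is multiplied by a lognormal factor and every
#' internal node age is perturbed multiplicatively relative to its parent,
#' preserving ultrametricity and age ordering.
#'
#' @param tree ultrametric `phylo`.
#' @param sd lognormal standard deviation of the per-node perturbation.
#' @param crown_sd lognormal standard deviation of the crown-age factor.
#' @param seed integer seed.
#' @return perturbed ultrametric `phylo`, same topology and units.
#' @export
jitter_node_ages <- function(tree, sd = 0.1, crown_sd = 0.1, seed = NULL) {
  .validate_tree(tree, "jitter_node_ages")
  if (!is_ultrametric_tree(tree)) stop("tree must be ultrametric", call. = FALSE)
  local_seed(seed, {
    n_tip <- ape::Ntip(tree)
    root <- n_tip + 1L
    depth <- ape::node.depth.edgelength(tree)
    T0 <- max(depth[seq_len(n_tip)])
    age <- T0 - depth                      # node ages, tips ~ 0
    age[seq_len(n_tip)] <- 0
    new_age <- numeric(length(age))
    new_age[root] <- age[root] * exp(rnorm(1, 0, crown_sd))
    E <- ape::reorder.phylo(tree, "postorder")$edge
    for (e in rev(seq_len(nrow(E)))) {     # preorder: parents first
      p <- E[e, 1]; v <- E[e, 2]
      if (v <= n_tip) next
      rel <- age[v] / age[p]
      new_age[v] <- new_age[p] * min(0.999, rel * exp(rnorm(1, 0, sd)))
    }
    out <- tree
    elens <- new_age[tree$edge[, 1]] - new_age[tree$edge[, 2]]
    out$edge.length <- elens
    out
  })
}

#' Emulate a posterior tree distribution by node-age jitter
#'
#' @param tree ultrametric `phylo` (the "true" tree).
#' @param n number of trees.
#' @param sd,crown_sd passed to [jitter_node_ages()].
#' @param seed integer seed.
#' @return a `tree_distribution`.
#' @export
jittered_tree_distribution <- function(tree, n, sd = 0.1, crown_sd = 0.1,
                                       seed = 1L) {
  seeds <- local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  u <- tree_units(tree); if (is.na(u)) u <- "Myr"
  tree_distribution(lapply(seeds, function(s)
    jitter_node_ages(tree, sd = sd, crown_sd = crown_sd, seed = s)), units = u)
}

#' Simulate clock-like nucleotide sequences on a tree
#'
#' Evolves sequences from a root drawn from the model's base frequencies,
#' branch-wise with transition probabilities at distance `rate * branch
#' length` (a strict molecular clock when `rate` is scalar; a per-edge rate
#' vector, aligned with `tree$edge` rows, emulates lineage-specific rates
#' such as elevated within-species polymorphism). With `codon_safe = TRUE`
#' any state change that would create an internal stop codon (standard
#' code, frame 0) is resampled, so no sequence ever gains a stop.
#'
#' @param tree dated `phylo` (Myr).
#' @param model a [subst_model()].
#' @param rate substitutions/site/Myr; scalar or one value per edge of
#'   `tree$edge`.
#' @param n_sites alignment length (>= 1; multiple of 3 if `codon_safe`).
#' @param seed integer seed.
#' @param codon_safe logical; keep all sequences free of internal stops.
#' @return alignment matrix with an attribute `n_resampled` (number of
#'   stop-avoiding redraws).
#' @export
simulate_sequences <- function(tree, model, rate, n_sites, seed = NULL,
                               codon_safe = FALSE) {
  .validate_tree(tree, "simulate_sequences")
  stopifnot(inherits(model, "subst_model"))
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  if (!(length(rate) %in% c(1L, nrow(tree$edge))))
    stop("rate must be scalar or one value per edge", call. = FALSE)
  if (codon_safe && n_sites %% 3L != 0L)
    stop("codon_safe requires n_sites divisible by 3", call. = FALSE)
  scaled <- tree
  scaled$edge.length <- tree$edge.length * rate
  pt <- .prep_tree(scaled)
  states <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  n_resampled <- 0L
  local_seed(seed, {
    draw_root <- function() sample.int(4L, n_sites, replace = TRUE, prob = model$pi)
    fix_stops <- function(seqv, redraw) {
      # redraw(cols) returns new states for the given site indices
      if (!codon_safe) return(seqv)
      repeat {
        cods <- paste0(states[seqv[c(TRUE, FALSE, FALSE)]],
                       states[seqv[c(FALSE, TRUE, FALSE)]],
                       states[seqv[c(FALSE, FALSE, TRUE)]])
        bad <- which(cods %in% stops)
        if (length(bad) == 0L) return(seqv)
        n_resampled <<- n_resampled + length(bad)
        cols <- as.vector(vapply(bad, function(k) (3L * (k - 1L) + 1L):(3L * k),
                                 integer(3)))
        seqv[cols] <- redraw(cols)
        seqv
      }
    }
    seqs <- vector("list", pt$n_node)
    root_seq <- draw_root()
    root_seq <- fix_stops(root_seq, function(cols)
      sample.int(4L, length(cols), replace = TRUE, prob = model$pi))
    seqs[[pt$root]] <- root_seq
    E <- pt$edge
    for (e in rev(seq_len(nrow(E)))) {    # preorder
      par <- E[e, 1]; ch <- E[e, 2]
      P <- transition_probs(model, pt$el[e])
      parent_seq <- seqs[[par]]
      child <- integer(n_sites)
      for (i in 1:4) {
        idx <- which(parent_seq == i)
        if (length(idx))
          child[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[i, ])
      }
      child <- fix_stops(child, function(cols) {
        out <- integer(length(cols))
        for (j in seq_along(cols)) {
          out[j] <- sample.int(4L, 1L, prob = P[parent_seq[cols[j]], ])
        }
        out
      })
      seqs[[ch]] <- child
    }
    m <- do.call(rbind, lapply(seq_len(pt$n_tip), function(i) states[seqs[[i]]]))
    rownames(m) <- pt$tip_labels
    structure(as_alignment(m), n_resampled = n_resampled)
  })
}

#' Simulate intraspecific trait values around species means
#'
#' @param species_means named numeric vector or `trait_table` of species
#'   mean trait values.
#' @param s2 intraspecific variance (>= 0).
#' @param n_per_species individuals per species (>= 1).
#' @param seed integer seed.
#' @return a `trait_table` with `species`, `individual`, `value`.
#' @export
simulate_intraspecific_traits <- function(species_means, s2, n_per_species,
                                          seed = NULL) {
  if (s2 < 0) stop("s2 must be >= 0", call. = FALSE)
  if (n_per_species < 1) stop("n_per_species must be >= 1", call. = FALSE)
  if (is.data.frame(species_means))
    species_means <- setNames(species_means$value, species_means$species)
  local_seed(seed, {
    sp <- rep(names(species_means), each = n_per_species)
    vals <- rnorm(length(sp), mean = rep(species_means, each = n_per_species),
                  sd = sqrt(s2))
    trait_table(species = sp, value = vals,
                individual = paste0(sp, "_i", rep(seq_len(n_per_species),
                                                  times = length(species_means))))
  })
}

#' Simulate a biallelic amino-acid site with a depth effect
#'
#' Balanced biallelic states; depths are normal around
#' `base_depth_m +/- effect_m / 2` per state, truncated below at 0.5 m.
#'
#' @param n number of individuals (>= 4).
#' @param effect_m depth difference between the two state groups (m).
#' @param base_depth_m mean depth (m).
#' @param sd_m depth standard deviation within a state group (m).
#' @param seed integer seed.
#' @return data.frame `individual`, `state`, `depth`.
#' @export
simulate_depth_genotype <- function(n, effect_m, base_depth_m = 10, sd_m = 4,
                                    seed = NULL) {
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  local_seed(seed, {
    n1 <- n %/% 2L
    state <- c(rep("L", n1), rep("I", n - n1))
    mu <- ifelse(state == "L", base_depth_m - effect_m / 2,
                 base_depth_m + effect_m / 2)
    depth <- pmax(0.5, rnorm(n, mu, sd_m))
    data.frame(individual = sprintf("ind%02d", seq_len(n)),
               state = state, depth = depth, stringsAsFactors = FALSE)
  })
}

#' Default configuration of the study fixture
#'
#' Study conditions emulated by [make_study_fixture()]: a 26-species dated
#' tree (crown 10 Myr, birth 0.3 / death 0.1 per Myr), a 53-individual
#' coalescent clade calibrated to a 0.15 Myr crown grafted into the species
#' with the longest stem branch, a 251-codon alignment under HKY (kappa 4)
#' evolving at 1.16e-3 substitutions/site/Myr between species and 7.48e-3
#' within the focal species (transient polymorphism), drift parameters
#' s2 = 1, Ne = 1000, tau = 5 yr, and a biallelic depth site with an 8 m
#' effect. Posterior-like distributions of 20 trees are emulated by node-age
#' jitter (lognormal sd 0.1).
#'
#' @return named list of fixture parameters.
#' @export
fixture_defaults <- function() {
  list(
    n_species = 26L, crown_age = 10, birth = 0.3, death = 0.1,
    n_individuals = 53L, clade_crown_age = 0.15,
    n_codons = 251L, kappa = 4, pi = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
    macro_rate = 1.16e-3, micro_rate = 7.48e-3,
    s2 = 1, Ne = 1000L, tau = 5,
    depth_effect = 8, base_depth = 10, depth_sd = 4,
    n_trees = 20L, jitter_sd = 0.1, crown_jitter_sd = 0.1
  )
}

# Edge indices of `tree` lying inside the clade spanned by `tips`
# (edges whose parent is the clade MRCA or one of its descendants).
.clade_edges <- function(tree, tips) {
  mrca <- ape::getMRCA(tree, tips)
  E <- ape::reorder.phylo(tree, "postorder")$edge
  inside <- rep(FALSE, ape::Ntip(tree) + tree$Nnode)
  inside[mrca] <- TRUE
  for (e in rev(seq_len(nrow(E)))) {
    if (inside[E[e, 1]]) inside[E[e, 2]] <- TRUE
  }
  which(inside[tree$edge[, 1]])
}

#' Generate the full synthetic study fixture
#'
#' Composes all simulators into one dataset with known ground truth: dated
#' species tree and posterior-like distribution, intraspecific coalescent
#' clade and its distribution, the combined (grafted) trees, a codon-safe
#' alignment with elevated within-species rate, drift-evolved species traits
#' with intraspecific values for the focal species, and a depth/genotype
#' table. Everything is driven by `master_seed`; regenerating with the same
#' configuration and seed is bit-identical.
#'
#' @param config named list overriding entries of [fixture_defaults()].
#' @param master_seed integer master seed.
#' @return a `study_fixture` list; see Details.
#' @details The returned list contains `species_tree`, `micro_tree`,
#'   `combined_tree` (the generating trees), `species_dist`, `micro_dist`,
#'   `combined_dist` (jittered distributions), `alignment`, `traits`
#'   (species means), `individual_traits`, `depth_data`, `focal_species`,
#'   `individuals`, `params` (the full generating-parameter record) and
#'   `drift` (the [drift_params()]).
#' @export
make_study_fixture <- function(config = list(), master_seed = 1L) {
  cfg <- utils::modifyList(fixture_defaults(), config)
  seeds <- local_seed(master_seed, sample.int(.Machine$integer.max - 1L, 12))

  species_tree <- simulate_bd_tree(cfg$n_species, cfg$birth, cfg$death,
                                   cfg$crown_age, seed = seeds[1])
  species_tree$tip.label <- sprintf("sp%02d", seq_len(cfg$n_species))

  # focal species: the tip with the longest stem branch, so the
  # intraspecific crown always fits
  tip_edges <- match(seq_len(ape::Ntip(species_tree)), species_tree$edge[, 2])
  stems <- species_tree$edge.length[tip_edges]
  focal <- species_tree$tip.label[which.max(stems)]
  clade_crown <- min(cfg$clade_crown_age, 0.9 * max(stems))

  coal <- simulate_coalescent_tree(cfg$n_individuals, seed = seeds[2])
  coal$tip.label <- sprintf("%s_ind%02d", focal, seq_len(cfg$n_individuals))
  micro_tree <- calibrate_relative_tree(coal, clade_crown)
  combined_tree <- graft_subtree(species_tree, focal, micro_tree)

  species_dist <- jittered_tree_distribution(species_tree, cfg$n_trees,
                                             sd = cfg$jitter_sd,
                                             crown_sd = cfg$crown_jitter_sd,
                                             seed = seeds[3])
  micro_dist <- jittered_tree_distribution(micro_tree, cfg$n_trees,
                                           sd = cfg$jitter_sd,
                                           crown_sd = cfg$crown_jitter_sd,
                                           seed = seeds[4])
  combined_dist <- jittered_tree_distribution(combined_tree, cfg$n_trees,
                                              sd = cfg$jitter_sd,
                                              crown_sd = cfg$crown_jitter_sd,
                                              seed = seeds[5])

  model <- subst_model("HKY", kappa = cfg$kappa, pi = cfg$pi)
  rates <- rep(cfg$macro_rate, nrow(combined_tree$edge))
  rates[.clade_edges(combined_tree, micro_tree$tip.label)] <- cfg$micro_rate
  aln <- simulate_sequences(combined_tree, model, rates,
                            n_sites = 3L * cfg$n_codons, seed = seeds[6],
                            codon_safe = TRUE)

  drift <- drift_params(cfg$s2, cfg$Ne, cfg$tau)
  traits <- simulate_traits_on_tree(species_tree, drift, root_value = 0,
                                    mode = "diffusion", seed = seeds[7])
  focal_mean <- traits$value[traits$species == focal]
  ind_traits <- simulate_intraspecific_traits(setNames(focal_mean, focal),
                                              s2 = cfg$s2,
                                              n_per_species = cfg$n_individuals,
                                              seed = seeds[8])
  depth <- simulate_depth_genotype(cfg$n_individuals, cfg$depth_effect,
                                   cfg$base_depth, cfg$depth_sd,
                                   seed = seeds[9])
  depth$individual <- micro_tree$tip.label

  structure(list(
    species_tree = species_tree, micro_tree = micro_tree,
    combined_tree = combined_tree,
    species_dist = species_dist, micro_dist = micro_dist,
    combined_dist = combined_dist,
    alignment = aln, traits = traits, individual_traits = ind_traits,
    depth_data = depth, focal_species = focal,
    individuals = micro_tree$tip.label,
    drift = drift,
    params = c(cfg, list(master_seed = master_seed, focal_species = focal,
                         clade_crown_age_used = clade_crown))
  ), class = "study_fixture")
}

#' @export
print.study_fixture <- function(x, ...) {
  cat(sprintf("Synthetic study fixture: %d species (crown %.3g Myr), %d individuals in %s,\n",
              ape::Ntip(x$species_tree), tree_height(x$species_tree),
              length(x$individuals), x$focal_species))
  cat(sprintf("  alignment %d sites, %d trees per distribution, master seed %d\n",
              ncol(x$alignment), length(x$species_dist),
              x$params$master_seed))
  invisible(x)
}

#' Write all fixture components to standard-format files
#'
#' Newick trees and distributions, FASTA alignment, TSV trait and depth
#' tables and a JSON parameter record, all written deterministically.
#'
#' @param fixture a `study_fixture`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "study_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_newick(fixture$species_tree, fp("species_tree.nwk"))
  write_newick(fixture$micro_tree, fp("micro_tree.nwk"))
  write_newick(fixture$combined_tree, fp("combined_tree.nwk"))
  writeLines(vapply(fixture$species_dist, write_newick, ""), fp("species_dist.nwk"))
  writeLines(vapply(fixture$micro_dist, write_newick, ""), fp("micro_dist.nwk"))
  writeLines(vapply(fixture$combined_dist, write_newick, ""), fp("combined_dist.nwk"))
  write_fasta(fixture$alignment, fp("alignment.fasta"))
  # per-scale alignments: the individuals for the intraspecific analysis, and
  # one representative individual (relabelled as the species) for the
  # species-level analysis
  write_fasta(fixture$alignment[fixture$individuals, , drop = FALSE],
              fp("micro_alignment.fasta"))
  macro <- fixture$alignment[c(setdiff(rownames(fixture$alignment),
                                       fixture$individuals),
                               fixture$individuals[1]), , drop = FALSE]
  rownames(macro)[nrow(macro)] <- fixture$focal_species
  write_fasta(macro, fp("macro_alignment.fasta"))
  writeLines(fixture$individuals, fp("clade_tips.txt"))
  write_trait_table(fixture$traits, fp("species_traits.tsv"))
  write_trait_table(fixture$individual_traits, fp("individual_traits.tsv"))
  write.table(fixture$depth_data, fp("depth_data.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fixture$params, fp("params.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
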