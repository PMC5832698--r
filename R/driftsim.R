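#' Drift-simulation parameters
#'
#' The three intraspecific parameters that drive the forward-time drift
#' simulator: the (constant) intraspecific trait variance `s2` (trait
#' units squared), the effective population size `Ne` (individuals) and the
#' generation time `tau` (years).
#'
#' @param s2 intraspecific trait variance, >= 0.
#' @param Ne effective population size, integer >= 2.
#' @param tau generation time in years, > 0.
#' @return an object of class `drift_params`.
#' @examples
#' drift_params(s2 = 1, Ne = 1000, tau = 5)
#' @export
drift_params <- function(s2, Ne, tau) {
  if (!is.numeric(s2) || length(s2) != 1L || !is.finite(s2) || s2 < 0)
    stop("s2 must be a non-negative scalar", call. = FALSE)
  if (!is.numeric(Ne) || length(Ne) != 1L || !is.finite(Ne) ||
      Ne < 2 || abs(Ne - round(Ne)) > 1e-8)
    stop("Ne must be an integer >= 2", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a positive scalar (years)", call. = FALSE)
  structure(list(s2 = s2, Ne = as.integer(round(Ne)), tau = tau),
            class = "drift_params")
}

#' @export
print.drift_params <- function(x, ...) {
  cat(sprintf("Drift parameters: s2 = %.4g, Ne = %d, tau = %.4g yr (predicted BM rate %.4g /Myr)\n",
              x$s2, x$Ne, x$tau, predicted_bm_rate(x)))
  invisible(x)
}

#' Estimate drift parameters from individual trait values
#'
#' The intraspecific variance is the unbiased sample variance of the
#' individual measurements; generation time and effective population size
#' are supplied externally (field estimates or literature values).
#'
#' @param individual_values numeric vector of >= 2 trait measurements.
#' @param tau generation time in years.
#' @param Ne effective population size.
#' @return a [drift_params()] object.
#' @export
estimate_drift_params <- function(individual_values, tau, Ne) {
  x <- as.numeric(individual_values)
  if (length(x) < 2L) stop("need at least 2 individual values", call. = FALSE)
  drift_params(s2 = var(x), Ne = Ne, tau = tau)
}

#' Predicted Brownian-motion rate from drift parameters
#'
#' The diffusion limit of the per-generation drift of a species-mean trait:
#' each generation the mean moves by `N(0, s2/Ne)`, and with `1e6 / tau`
#' generations per Myr the accumulated variance per Myr is
#' `s2 * 1e6 / (Ne * tau)`.
#'
#' @param p a [drift_params()] object.
#' @return predicted BM rate sigma^2 in trait units squared per Myr.
#' @examples
#' predicted_bm_rate(drift_params(1, 1000, 5))  # 200
#' @export
predicted_bm_rate <- function(p) {
  stopifnot(inherits(p, "drift_params"))
  p$s2 * 1e6 / (p$Ne * p$tau)
}

#' Number of drift generations on a branch
#'
#' Branch durations are rarely exact multiples of the generation time; the
#' count is rounded to the nearest integer with a floor of one generation so
#' that no branch freezes evolution entirely.
#'
#' @param branch_myr branch duration in Myr.
#' @param tau generation time in years.
#' @return integer number of generations (>= 1 for positive durations).
#' @export
generations_on_branch <- function(branch_myr, tau) {
  pmax(1, round(branch_myr * 1e6 / tau))
}

#' Forward-time drift of a species-mean trait along one branch
#'
#' Iterates the mean across generations: each generation, `Ne` individuals
#' are drawn from `Normal(mean, s2)` and the next mean is their sample mean.
#' Because the sample mean of `Ne` independent normals is exactly
#' `Normal(mean, s2/Ne)`, each generation's update is drawn from that exact
#' law (one increment per generation, accumulated in compiled code); the
#' trajectory's distribution is identical to simulating all `Ne`
#' individuals.
#'
#' @param mean0 trait mean at the start of the branch.
#' @param p a [drift_params()] object.
#' @param n_gen number of generations (integer >= 0).
#' @param n_rep number of independent replicate endpoints to draw.
#' @return numeric vector of `n_rep` trait means after `n_gen` generations.
#' @examples
#' set.seed(1)
#' var(drift_one_branch(0, drift_params(1, 100, 5), n_gen = 50, n_rep = 1000))
#' # ~ 50 * 1 / 100 = 0.5
#' @export
drift_one_branch <- function(mean0, p, n_gen, n_rep = 1L) {
  stopifnot(inherits(p, "drift_params"))
  if (!is.numeric(n_gen) || length(n_gen) != 1L || n_gen < 0 ||
      abs(n_gen - round(n_gen)) > 1e-8)
    stop("n_gen must be a non-negative integer", call. = FALSE)
  n_gen <- round(n_gen)
  if (n_gen == 0 || p$s2 == 0) return(rep(mean0, n_rep))
  .Call(C_drift_endpoints, as.numeric(mean0), sqrt(p$s2 / p$Ne),
        as.numeric(n_gen), as.integer(n_rep))
}

#' Simulate a species-mean trait along a phylogeny by genetic drift
#'
#' Evolves a trait from the root to every tip of a dated tree. In `"exact"`
#' mode every branch is simulated generation by generation with
#' [drift_one_branch()] (`n_gen = max(1, round(branch_Myr * 1e6 / tau))`);
#' daughters inherit the parental mean at each node. In `"diffusion"` mode
#' each branch adds a single `Normal(0, sigma2_pred * branch_Myr)` increment,
#' where `sigma2_pred` is [predicted_bm_rate()] -- the distributionally
#' equivalent fast path for long branches.
#'
#' @param tree dated `phylo` (Myr). A non-ultrametric tree triggers a
#'   warning only; the simulation remains defined.
#' @param p a [drift_params()] object.
#' @param root_value trait value at the root.
#' @param mode `"exact"` or `"diffusion"`.
#' @param seed optional integer seed (local to this call).
#' @return a `trait_table` data.frame with columns `species`, `value`.
#' @export
simulate_traits_on_tree <- function(tree, p, root_value = 0,
                                    mode = c("exact", "diffusion"),
                                    seed = NULL) {
  mode <- match.arg(mode)
  .validate_tree(tree, "simulate_traits_on_tree")
  stopifnot(inherits(p, "drift_params"))
  if (!is_ultrametric_tree(tree))
    warning("tree is not ultrametric; drift simulation proceeds on the given branch durations")
  local_seed(seed, {
    pt <- .prep_tree(tree)
    E <- pt$edge
    vals <- numeric(pt$n_node)
    vals[pt$root] <- root_value
    sigma2 <- predicted_bm_rate(p)
    for (e in rev(seq_len(nrow(E)))) {       # preorder: parents before children
      par <- E[e, 1]; ch <- E[e, 2]
      len <- pt$el[e]
      vals[ch] <- if (mode == "exact") {
        drift_one_branch(vals[par], p, generations_on_branch(len, p$tau))
      } else {
        vals[par] + rnorm(1, 0, sqrt(sigma2 * len))
      }
    }
    trait_table(species = pt$tip_labels, value = vals[seq_len(pt$n_tip)])
  })
}

#' Replicated trait simulations with independent per-replicate seeds
#'
#' Runs [simulate_traits_on_tree()] `n_rep` times. Each replicate gets its
#' own RNG seed derived from `master_seed`, so the set is reproducible and
#' any subset of replicates can be regenerated independently of the others.
#'
#' @param tree dated `phylo` (Myr).
#' @param p a [drift_params()] object.
#' @param n_rep number of replicates.
#' @param root_value trait value at the root.
#' @param mode `"exact"` or `"diffusion"`.
#' @param master_seed integer master seed.
#' @return numeric matrix, tips x replicates, rownames = tip labels.
#' @export
simulate_trait_replicates <- function(tree, p, n_rep, root_value = 0,
                                      mode = c("exact", "diffusion"),
                                      master_seed = 1L) {
  mode <- match.arg(mode)
  seeds <- local_seed(master_seed, sample.int(.Machine$integer.max - 1L, n_rep))
  out <- vapply(seq_len(n_rep), function(r) {
    tt <- simulate_traits_on_tree(tree, p, root_value, mode, seed = seeds[r])
    setNames(tt$value, tt$species)
  }, numeric(ape::Ntip(tree)))
  rownames(out) <- tree$tip.label
  out
}

#' Trait tables
#'
#' A trait table maps species to trait values, optionally holding individual
#' measurements (one row per individual). Functions that need one value per
#' species average the individual values.
#'
#' @param species character vector of species names.
#' @param value numeric trait values.
#' @param individual optional individual identifiers.
#' @param trait optional trait name column.
#' @return a data.frame of class `trait_table`.
#' @export
trait_table <- function(species, value, individual = NULL, trait = NULL) {
  df <- data.frame(species = as.character(species), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (!is.null(individual)) df$individual <- as.character(individual)
  if (!is.null(trait)) df$trait <- as.character(trait)
  structure(df, class = c("trait_table", "data.frame"))
}

# One value per species, ordered to `tips` (errors on missing species).
.trait_vector <- function(traits, tips) {
  if (is.numeric(traits) && !is.null(names(traits))) {
    x <- traits
  } else if (is.data.frame(traits)) {
    if (!all(c("species", "value") %in% names(traits)))
      stop("trait table needs 'species' and 'value' columns", call. = FALSE)
    x <- tapply(traits$value, traits$species, mean)
    x <- setNames(as.numeric(x), names(x))
  } else {
    stop("traits must be a named numeric vector or a trait table", call. = FALSE)
  }
  missing <- setdiff(tips, names(x))
  if (length(missing))
    stop("missing trait values for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x[tips]
}

#' Read / write trait tables as TSV
#'
#' TSV with columns `species`, `value` and optionally `individual`, `trait`.
#'
#' @param path file path.
#' @return a `trait_table`.
#' @export
read_trait_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  trait_table(df$species, df$value, individual = df$individual, trait = df$trait)
}

#' @rdname read_trait_table
#' @param traits a `trait_table` (or compatible data.frame).
#' @export
write_trait_table <- function(traits, path) {
  write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
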