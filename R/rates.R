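#' Rate-estimate objects
#'
#' A `rate_estimate` stores a per-tree sample of molecular rates
#' (substitutions per site per Myr), its median and equal-tailed 95%
#' percentile interval, and a label identifying the evolutionary scale.
#'
#' @param sample numeric vector of non-negative per-tree rates.
#' @param label one of `"micro"`, `"macro"`, `"macro_predicted"`.
#' @return an object of class `rate_estimate`.
#' @export
rate_estimate <- function(sample, label = c("micro", "macro", "macro_predicted")) {
  label <- match.arg(label)
  sample <- as.numeric(sample)
  if (length(sample) == 0L) stop("empty rate sample", call. = FALSE)
  if (any(!is.finite(sample)) || any(sample < 0))
    stop("rates must be finite and non-negative", call. = FALSE)
  ci <- unname(quantile(sample, c(0.025, 0.975), type = 7))
  structure(list(sample = sample, median = median(sample),
                 ci_low = ci[1], ci_high = ci[2], label = label, n = length(sample)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Rate estimate [%s]: median %.4g (95%% CI %.4g - %.4g), n = %d trees\n",
              x$label, x$median, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' @export
as.data.frame.rate_estimate <- function(x, ...) {
  data.frame(label = x$label, rate = x$sample, stringsAsFactors = FALSE)
}

#' Summarise a rate estimate as a one-row data frame
#' @param object a `rate_estimate`.
#' @param ... unused.
#' @return data.frame with label, median, ci_low, ci_high, n.
#' @export
summary.rate_estimate <- function(object, ...) {
  data.frame(label = object$label, median = object$median,
             ci_low = object$ci_low, ci_high = object$ci_high, n = object$n,
             stringsAsFactors = FALSE)
}

#' Molecular rate as a branch-length ratio
#'
#' The mean molecular rate of a gene tree relative to a dated tree of the
#' same topology: the sum of the gene tree's branch lengths
#' (substitutions/site) divided by the sum of the time tree's branch lengths
#' (Myr).
#'
#' @param gene `phylo` with branch lengths in substitutions/site.
#' @param time `phylo` with the identical topology and tip set, branch
#'   lengths in Myr and positive total length.
#' @return rate in substitutions per site per Myr.
#' @export
rate_ratio <- function(gene, time) {
  .validate_tree(gene, "gene tree")
  .validate_tree(time, "time tree")
  .check_units(gene, "subs/site", "gene tree")
  .check_units(time, "Myr", "time tree")
  if (!setequal(gene$tip.label, time$tip.label) ||
      !identical(.topology_key(gene), .topology_key(time)))
    stop("gene and time trees must share topology and tip set", call. = FALSE)
  tt <- sum(time$edge.length)
  if (tt <= 0) stop("time tree has zero total branch length", call. = FALSE)
  sum(gene$edge.length) / tt
}

# Canonical topology fingerprint: sorted clade bipartitions by tip label.
.topology_key <- function(tree) {
  n <- ape::Ntip(tree)
  labs <- tree$tip.label
  tr <- ape::reorder.phylo(tree, "postorder")
  clades <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) clades[[i]] <- labs[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    clades[[p]] <- c(clades[[p]], clades[[ch]])
  }
  sort(vapply(clades, function(x) paste(sort(x), collapse = "|"), ""))
}

#' Molecular rate over a distribution of dated trees
#'
#' For each tree in a dated-tree distribution, re-estimates branch lengths of
#' the gene alignment by maximum likelihood on the fixed topology
#' ([optimize_branch_lengths()]) and takes the branch-length ratio
#' ([rate_ratio()]); returns the per-tree rate sample with median and 95%
#' percentile interval.
#'
#' @param dist a `tree_distribution` in Myr.
#' @param aln alignment covering all tips.
#' @param model a [subst_model()], or `NULL` for HKY with empirical base
#'   frequencies and jointly optimised kappa.
#' @param label label for the returned [rate_estimate()].
#' @param ... passed to [optimize_branch_lengths()].
#' @return a `rate_estimate`.
#' @export
rate_over_distribution <- function(dist, aln, model = NULL,
                                   label = c("micro", "macro", "macro_predicted"),
                                   ...) {
  label <- match.arg(label)
  if (length(dist) == 0L) stop("empty tree distribution", call. = FALSE)
  optimize_kappa <- FALSE
  if (is.null(model)) {
    model <- subst_model("HKY", pi = empirical_frequencies(aln))
    optimize_kappa <- TRUE
  }
  rates <- vapply(seq_along(dist), function(i) {
    time_tree <- set_tree_units(dist[[i]], attr(dist, "units") %||% "Myr")
    gene <- optimize_branch_lengths(time_tree, aln, model,
                                    optimize_kappa = optimize_kappa, ...)
    rate_ratio(gene, time_tree)
  }, numeric(1))
  rate_estimate(rates, label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare two rate estimates by confidence-interval overlap
#'
#' Two rates are declared significantly different when their 95% percentile
#' intervals do not overlap.
#'
#' @param a,b `rate_estimate` objects.
#' @return list with `significant` (logical), `overlap` (width of the CI
#'   intersection; 0 when disjoint) and `gap` (distance between the CIs when
#'   disjoint; 0 otherwise).
#' @export
rate_ci_compare <- function(a, b) {
  stopifnot(inherits(a, "rate_estimate"), inherits(b, "rate_estimate"))
  lo <- max(a$ci_low, b$ci_low)
  hi <- min(a$ci_high, b$ci_high)
  overlap <- max(0, hi - lo)
  list(significant = overlap == 0 && hi < lo,
       overlap = overlap,
       gap = max(0, lo - hi))
}

#' Predict the macroevolutionary rate by haplotype pruning
#'
#' Mimics the fixation of a single intraspecific haplotype at speciation:
#' for each combined tree (species tree with an intraspecific clade grafted
#' in) and each individual of the focal clade, all other clade members are
#' pruned, branch lengths are re-optimised by maximum likelihood, and the
#' predicted species-level rate is read off the retained terminal branch
#' (its optimised substitution length divided by its time length). The
#' procedure is iterated over every individual in `clade_tips`, pooling all
#' predicted rates into one `rate_estimate` labelled `"macro_predicted"`.
#'
#' @param combined list (or `tree_distribution`) of combined trees in Myr.
#' @param aln alignment covering all tips of the combined trees.
#' @param model a [subst_model()], or `NULL` for HKY with empirical
#'   frequencies and optimised kappa.
#' @param clade_tips labels of the intraspecific individuals (a proper,
#'   non-empty subset of every combined tree's tips).
#' @param individuals which clade members to retain one at a time
#'   (default: all of `clade_tips`).
#' @param ... passed to [optimize_branch_lengths()].
#' @return a `rate_estimate` with `length(combined) * length(individuals)`
#'   pooled predicted rates.
#' @export
predict_macro_rate_by_pruning <- function(combined, aln, model = NULL,
                                          clade_tips,
                                          individuals = clade_tips, ...) {
  if (length(combined) == 0L) stop("empty tree list", call. = FALSE)
  clade_tips <- unique(as.character(clade_tips))
  individuals <- unique(as.character(individuals))
  if (length(clade_tips) == 0L) stop("'clade_tips' is empty", call. = FALSE)
  if (!all(individuals %in% clade_tips))
    stop("'individuals' must be a subset of 'clade_tips'", call. = FALSE)
  optimize_kappa <- FALSE
  if (is.null(model)) {
    model <- subst_model("HKY", pi = empirical_frequencies(aln))
    optimize_kappa <- TRUE
  }
  rates <- numeric(0)
  for (i in seq_along(combined)) {
    tree <- combined[[i]]
    .validate_tree(tree, sprintf("combined tree %d", i))
    if (!all(clade_tips %in% tree$tip.label) ||
        length(clade_tips) >= ape::Ntip(tree))
      stop("'clade_tips' must be a proper subset of the combined tree's tips",
           call. = FALSE)
    others <- setdiff(tree$tip.label, clade_tips)
    for (ind in individuals) {
      time_tree <- prune_to_tips(tree, c(others, ind))
      time_tree <- set_tree_units(time_tree, "Myr")
      gene <- optimize_branch_lengths(time_tree, aln, model,
                                      optimize_kappa = optimize_kappa, ...)
      tip_t <- which(time_tree$tip.label == ind)
      tip_g <- which(gene$tip.label == ind)
      bl_time <- time_tree$edge.length[time_tree$edge[, 2] == tip_t]
      bl_gene <- gene$edge.length[gene$edge[, 2] == tip_g]
      rates <- c(rates, bl_gene / bl_time)
    }
  }
  rate_estimate(rates, "macro_predicted")
}

#' Species-level rate over combined trees, one individual as representative
#'
#' The species-level (macroevolutionary) rate when the focal species is
#' known from many individuals: for each combined tree and each chosen
#' representative individual, the tree is pruned to all species plus that
#' single individual, branch lengths are re-optimised by maximum
#' likelihood, and the branch-length ratio over the whole pruned tree is
#' taken. Pooling over individuals propagates the arbitrariness of which
#' haplotype represents the species.
#'
#' @inheritParams predict_macro_rate_by_pruning
#' @param individuals which clade members to use as representatives
#'   (default: all of `clade_tips`).
#' @return a `rate_estimate` labelled `"macro"`.
#' @export
macro_rate_over_combined <- function(combined, aln, model = NULL, clade_tips,
                                     individuals = clade_tips, ...) {
  if (length(combined) == 0L) stop("empty tree list", call. = FALSE)
  clade_tips <- unique(as.character(clade_tips))
  individuals <- unique(as.character(individuals))
  if (!all(individuals %in% clade_tips))
    stop("'individuals' must be a subset of 'clade_tips'", call. = FALSE)
  optimize_kappa <- FALSE
  if (is.null(model)) {
    model <- subst_model("HKY", pi = empirical_frequencies(aln))
    optimize_kappa <- TRUE
  }
  rates <- numeric(0)
  for (i in seq_along(combined)) {
    tree <- combined[[i]]
    others <- setdiff(tree$tip.label, clade_tips)
    for (ind in individuals) {
      time_tree <- set_tree_units(prune_to_tips(tree, c(others, ind)), "Myr")
      gene <- optimize_branch_lengths(time_tree, aln, model,
                                      optimize_kappa = optimize_kappa, ...)
      rates <- c(rates, rate_ratio(gene, time_tree))
    }
  }
  rate_estimate(rates, "macro")
}
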