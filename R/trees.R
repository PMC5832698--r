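#' @useDynLib evoscales, .registration = TRUE
#' @importFrom stats optimize quantile rnorm runif var median sd setNames
#'   fisher.test wilcox.test ks.test rexp
#' @importFrom utils write.table read.table
NULL

# Branch-length unit tags carried on every tree. Mixing units in arithmetic
# is an error: the source study juggles relative, time-calibrated and
# substitution-scaled trees, and silent unit mismatches are the main hazard.
.tree_units <- c("Myr", "subs/site", "relative", "coalescent")

#' Get or set the branch-length units of a tree
#'
#' Trees handled by this package carry an explicit units tag
#' (`"Myr"`, `"subs/site"`, `"relative"` or `"coalescent"`) as an attribute.
#'
#' @param tree an object of class `phylo`.
#' @param units one of `"Myr"`, `"subs/site"`, `"relative"`, `"coalescent"`.
#' @return `tree_units()` returns the units tag (or `NA` if unset);
#'   `set_tree_units()` returns the tree with the tag attached.
#' @export
tree_units <- function(tree) {
  u <- attr(tree, "units")
  if (is.null(u)) NA_character_ else u
}

#' @rdname tree_units
#' @export
set_tree_units <- function(tree, units) {
  units <- match.arg(units, .tree_units)
  attr(tree, "units") <- units
  tree
}

.check_units <- function(tree, expected, what = "tree") {
  u <- tree_units(tree)
  if (!is.na(u) && !(u %in% expected)) {
    stop(sprintf("%s has units '%s'; expected %s", what, u,
                 paste(expected, collapse = " or ")), call. = FALSE)
  }
  invisible(u)
}

#' Root-to-tip depths of a tree
#'
#' @param tree a rooted `phylo`.
#' @return named numeric vector of root-to-tip path lengths, one per tip.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (!is.null(tree$root.edge) && is.finite(tree$root.edge))
    d <- d + tree$root.edge   # depth measured from the original root
  names(d) <- tree$tip.label
  d
}

#' Height (maximum root-to-tip depth) of a tree
#' @param tree a rooted `phylo`.
#' @return scalar tree height in the tree's units.
#' @export
tree_height <- function(tree) max(tip_depths(tree))

#' Test ultrametricity within a relative tolerance
#'
#' A tree is treated as ultrametric when all root-to-tip path lengths agree
#' within `tol` times the tree height. The default tolerance absorbs the
#' floating-point noise typical of posterior tree samples.
#'
#' @param tree a rooted `phylo`.
#' @param tol relative tolerance (default `1e-6` of tree height).
#' @return logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  h <- max(d)
  if (h == 0) return(TRUE)
  (max(d) - min(d)) <= tol * h
}

.validate_tree <- function(tree, context = "tree") {
  if (!inherits(tree, "phylo")) stop(context, ": not a 'phylo' object", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop(context, ": duplicate tip labels (",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         ")", call. = FALSE)
  if (is.null(tree$edge.length))
    stop(context, ": branch lengths are missing", call. = FALSE)
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop(context, ": one or more branch lengths are missing or non-finite",
         call. = FALSE)
  if (any(tree$edge.length < 0))
    stop(context, ": negative branch length", call. = FALSE)
  invisible(tree)
}

#' Read a single Newick tree with validation
#'
#' Strict reader: the Newick statement must be well formed, every branch must
#' have a length, and tip labels must be unique. Node support values (Newick
#' internal node labels) are preserved but ignored by all computations.
#'
#' @param text a single Newick statement, e.g. `"(A:1,B:1):0;"`.
#' @param units branch-length units tag; see [tree_units()].
#' @return a rooted `phylo` with a units attribute.
#' @examples
#' tr <- read_newick("(A:1,(B:0.5,C:0.5):0.5);", units = "Myr")
#' tip_depths(tr)
#' @export
read_newick <- function(text, units = c("Myr", "subs/site", "relative", "coalescent")) {
  units <- match.arg(units)
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("Newick parse error: input is not a single well-formed tree", call. = FALSE)
  .validate_tree(tree, "read_newick")
  set_tree_units(tree, units)
}

#' Write a tree as a Newick string
#'
#' Deterministic writer (10 significant digits on branch lengths) so that
#' identical trees always serialise to identical strings.
#'
#' @param tree a `phylo`.
#' @param path optional file path; if `NULL` the string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read a tree distribution (posterior sample)
#'
#' Reads an ordered set of trees sharing one tip-label set, from a NEXUS
#' trees block (TRANSLATE tables are resolved) or a multi-line Newick file.
#'
#' @param path file path.
#' @param format `"nexus"` or `"multi-newick"`.
#' @param units branch-length units tag applied to every member.
#' @return a `tree_distribution`: a list of `phylo` objects, order preserved,
#'   with a units attribute.
#' @export
read_tree_distribution <- function(path,
                                   format = c("multi-newick", "nexus"),
                                   units = c("Myr", "subs/site", "relative", "coalescent")) {
  format <- match.arg(format)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  trees <- switch(format,
    "nexus" = ape::read.nexus(path),
    "multi-newick" = tryCatch(ape::read.tree(path),
                              error = function(e) stop("Newick parse error: ",
                                                       conditionMessage(e), call. = FALSE))
  )
  if (is.null(trees)) stop("no trees found in ", path, call. = FALSE)
  if (inherits(trees, "phylo")) trees <- list(trees)
  # extract with [[ so multiPhylo compressed tip labels are reattached
  trees <- lapply(seq_along(trees), function(i) trees[[i]])
  tree_distribution(lapply(trees, set_tree_units, units = units), units = units)
}

#' Construct a tree distribution from a list of trees
#'
#' @param trees non-empty list of `phylo` objects with identical tip-label sets.
#' @param units branch-length units tag.
#' @return a `tree_distribution` object.
#' @export
tree_distribution <- function(trees, units = c("Myr", "subs/site", "relative", "coalescent")) {
  units <- match.arg(units)
  if (length(trees) == 0L) stop("empty tree distribution", call. = FALSE)
  for (i in seq_along(trees)) .validate_tree(trees[[i]], sprintf("tree %d", i))
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop(sprintf("tree %d has a different tip set from tree 1", i), call. = FALSE)
  }
  trees <- lapply(trees, set_tree_units, units = units)
  structure(trees, class = "tree_distribution", units = units)
}

#' @export
print.tree_distribution <- function(x, ...) {
  cat(sprintf("Tree distribution: %d trees, %d tips each, units '%s'\n",
              length(x), ape::Ntip(x[[1]]), attr(x, "units")))
  invisible(x)
}

#' @export
`[.tree_distribution` <- function(x, i) {
  tree_distribution(unclass(x)[i], units = attr(x, "units"))
}

#' Prune a tree to a set of tips
#'
#' Removes all tips not in `keep`, collapsing the resulting unifurcations by
#' summing their branch lengths, so the root-to-tip depth of every retained
#' tip is unchanged.
#'
#' @param tree a `phylo`.
#' @param keep character vector of tip labels to retain (non-empty subset of
#'   the tree's tips).
#' @return the pruned `phylo`, same units.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' write_newick(prune_to_tips(tr, c("A", "C")))
#' @export
prune_to_tips <- function(tree, keep) {
  .validate_tree(tree, "prune_to_tips")
  keep <- unique(as.character(keep))
  if (length(keep) == 0L) stop("'keep' is empty", call. = FALSE)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("unknown tip label(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (setequal(keep, tree$tip.label)) return(tree)
  d_old <- tip_depths(tree)
  if (length(keep) == 1L) {
    # single retained tip: one terminal branch spanning its full depth
    out <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          edge.length = unname(d_old[keep]),
                          tip.label = keep, Nnode = 1L),
                     class = "phylo")
  } else {
    out <- ape::keep.tip(tree, keep)
    # keep.tip roots the result at the MRCA of the kept tips; preserve the
    # path to the original root as a root edge so tip depths are unchanged
    shift <- d_old[keep[1]] - ape::node.depth.edgelength(out)[
      match(keep[1], out$tip.label)]
    if (shift > 1e-12 * max(d_old)) out$root.edge <- unname(shift)
  }
  attr(out, "units") <- tree_units(tree)
  out
}

#' Calibrate a relative tree to an absolute crown age
#'
#' Multiplies every branch by `crown_age_Myr / height(tree)`, turning a
#' relatively dated ultrametric tree (e.g. root at depth 1) into a
#' time-calibrated tree with the stated crown age.
#'
#' @param rel an ultrametric `phylo` with positive height.
#' @param crown_age_Myr target crown age in Myr (> 0).
#' @return the rescaled `phylo`, units `"Myr"`.
#' @export
calibrate_relative_tree <- function(rel, crown_age_Myr) {
  .validate_tree(rel, "calibrate_relative_tree")
  if (!is.numeric(crown_age_Myr) || length(crown_age_Myr) != 1L || crown_age_Myr <= 0)
    stop("crown age must be a positive scalar", call. = FALSE)
  h <- tree_height(rel)
  if (h <= 0) stop("tree has zero root depth", call. = FALSE)
  if (!is_ultrametric_tree(rel))
    stop("tree is not ultrametric; cannot calibrate by crown age", call. = FALSE)
  f <- crown_age_Myr / h
  rel$edge.length <- rel$edge.length * f
  if (!is.null(rel$root.edge) && is.finite(rel$root.edge))
    rel$root.edge <- rel$root.edge * f
  set_tree_units(rel, "Myr")
}

#' Graft a subtree onto a tip of a species tree
#'
#' Replaces `tip_label` in `species_tree` by `subtree`, placing the subtree's
#' crown so its tips sit at depth 0 (the present) and shortening the
#' recipient stem branch accordingly. Both trees must be ultrametric and in
#' the same time units. If the subtree is older than the stem branch allows,
#' the operation fails rather than silently rescaling the subtree.
#'
#' @param species_tree ultrametric `phylo` (units `"Myr"`).
#' @param tip_label tip of `species_tree` to replace.
#' @param subtree ultrametric `phylo` (units `"Myr"`); its crown age must not
#'   exceed the stem branch length of `tip_label`.
#' @return the combined ultrametric `phylo` with
#'   `Ntip(species_tree) - 1 + Ntip(subtree)` tips.
#' @export
graft_subtree <- function(species_tree, tip_label, subtree) {
  .validate_tree(species_tree, "species_tree")
  .validate_tree(subtree, "subtree")
  ua <- tree_units(species_tree); ub <- tree_units(subtree)
  if (!is.na(ua) && !is.na(ub) && ua != ub)
    stop(sprintf("unit mismatch: species tree '%s' vs subtree '%s'", ua, ub),
         call. = FALSE)
  tip_idx <- match(tip_label, species_tree$tip.label)
  if (is.na(tip_idx)) stop("tip label not found: ", tip_label, call. = FALSE)
  subtree$root.edge <- NULL   # crown age excludes any stem carried on the subtree
  if (!is_ultrametric_tree(species_tree) || !is_ultrametric_tree(subtree))
    stop("both trees must be ultrametric", call. = FALSE)
  if (any(subtree$tip.label %in% species_tree$tip.label))
    stop("subtree tip labels collide with species-tree tips", call. = FALSE)
  h_sub <- tree_height(subtree)
  stem <- species_tree$edge.length[species_tree$edge[, 2] == tip_idx]
  if (h_sub > stem + 1e-9 * max(stem, h_sub))
    stop(sprintf("subtree crown age (%.6g) exceeds the stem branch of '%s' (%.6g)",
                 h_sub, tip_label, stem), call. = FALSE)
  if (ape::Ntip(subtree) == 1L) {
    # degenerate graft: relabel the tip
    species_tree$tip.label[tip_idx] <- subtree$tip.label
    return(species_tree)
  }
  subtree$root.edge <- 0
  pos <- min(h_sub, stem)  # attach the subtree crown h_sub above the tip
  combined <- ape::bind.tree(species_tree, subtree, where = tip_idx, position = pos)
  combined <- ape::drop.tip(combined, tip_label, collapse.singles = TRUE)
  attr(combined, "units") <- ua
  .validate_tree(combined, "graft_subtree result")
  combined
}

#' Randomly pair two tree distributions
#'
#' Forms `min(|A|, |B|)` tree pairs: the shorter distribution is taken in
#' order and, for each of its members, a partner is drawn uniformly with
#' replacement from the longer distribution. Mirrors the random combination
#' of an intraspecific posterior with a species-level posterior.
#'
#' @param distA,distB `tree_distribution` objects (non-empty).
#' @param seed integer seed; the pairing is reproducible.
#' @return a list of `list(a = , b = )` tree pairs, length `min(|A|, |B|)`.
#' @export
pair_distributions <- function(distA, distB, seed) {
  if (length(distA) == 0L || length(distB) == 0L)
    stop("empty tree distribution", call. = FALSE)
  n <- min(length(distA), length(distB))
  idx <- local_seed(seed, {
    if (length(distA) <= length(distB)) {
      cbind(seq_len(n), sample.int(length(distB), n, replace = TRUE))
    } else {
      cbind(sample.int(length(distA), n, replace = TRUE), seq_len(n))
    }
  })
  lapply(seq_len(n), function(k) list(a = distA[[idx[k, 1]]], b = distB[[idx[k, 2]]]))
}

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
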