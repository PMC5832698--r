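# Felsenstein pruning engine.
#
# Partial likelihoods are kept as 4 x n_patterns matrices with per-pattern
# log-scaling vectors to avoid underflow on large trees. The engine works on
# a postorder-reordered copy of the tree; node indexing follows ape: tips
# 1..n, root n+1.

.prep_tree <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, el = tr$edge.length, n_tip = ape::Ntip(tr),
       root = ape::Ntip(tr) + 1L, n_node = ape::Ntip(tr) + tr$Nnode,
       tip_labels = tr$tip.label, tree = tr)
}

.col_max4 <- function(X) pmax(X[1, ], X[2, ], X[3, ], X[4, ])

# Postorder (downward) partials for all nodes, given edge lengths `el`.
.down_partials <- function(pt, enc, model, el) {
  S <- enc$n_patterns
  down <- vector("list", pt$n_node)
  sc <- vector("list", pt$n_node)
  zero <- numeric(S)
  for (i in seq_len(pt$n_tip)) {
    down[[i]] <- enc$tips[[i]]
    sc[[i]] <- zero
  }
  E <- pt$edge
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1]; ch <- E[e, 2]
    contrib <- transition_probs(model, el[e]) %*% down[[ch]]
    if (is.null(down[[p]])) {
      down[[p]] <- contrib
      sc[[p]] <- sc[[ch]]
    } else {
      down[[p]] <- down[[p]] * contrib
      sc[[p]] <- sc[[p]] + sc[[ch]]
    }
    mx <- .col_max4(down[[p]])
    if (any(mx == 0)) mx[mx == 0] <- 1        # impossible pattern; logL -> -Inf at root
    down[[p]] <- down[[p]] / rep(mx, each = 4L)
    sc[[p]] <- sc[[p]] + log(mx)
  }
  list(down = down, sc = sc)
}

.root_loglik <- function(pt, enc, model, dp) {
  rl <- as.vector(crossprod(model$pi, dp$down[[pt$root]]))
  sum(enc$weights * (log(rl) + dp$sc[[pt$root]]))
}

# Upward ("outside") partial for one node: up[i, s] is the likelihood of all
# data outside subtree(v) as a function of state i at parent(v), with the
# root prior folded in. Computed by walking the root -> v path only, so a
# per-branch refresh costs O(path depth) rather than O(edges).
.up_for_node <- function(pt, enc, model, el, dp, v, edge_above, kids) {
  path <- integer(0)                       # nodes from just-below-root down to v
  w <- v
  while (w != pt$root) {
    path <- c(w, path)
    w <- pt$edge[edge_above[w], 1]
  }
  S <- enc$n_patterns
  up <- model$pi * matrix(1, 4, S)
  sc <- numeric(S)
  parent <- pt$root
  for (w in path) {
    if (parent != pt$root) {
      # fold the branch above `parent` into the outside partial
      up <- crossprod(transition_probs(model, el[edge_above[parent]]), up)
    }
    for (sib in kids[[parent]]) {
      u <- pt$edge[sib, 2]
      if (u == w) next
      up <- up * (transition_probs(model, el[sib]) %*% dp$down[[u]])
      sc <- sc + dp$sc[[u]]
    }
    mx <- .col_max4(up)
    if (any(mx == 0)) mx[mx == 0] <- 1
    up <- up / rep(mx, each = 4L)
    sc <- sc + log(mx)
    parent <- w
  }
  list(up = up, sc = sc)
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Computes the log-likelihood of a nucleotide alignment on a rooted tree
#' whose branch lengths are in expected substitutions per site, summing over
#' sites. Gaps and Ns are treated as missing data (partial likelihood 1 for
#' every state).
#'
#' @param tree rooted `phylo`, branch lengths in substitutions/site.
#' @param aln alignment (see [as_alignment()]) covering all tips.
#' @param model a [subst_model()].
#' @return scalar log-likelihood.
#' @examples
#' tr <- read_newick("(A:0.1,B:0.1);", units = "subs/site")
#' aln <- as_alignment(c(A = "ACGTACGT", B = "ACGTACGA"))
#' felsenstein_loglik(tr, aln, subst_model("JC"))
#' @export
felsenstein_loglik <- function(tree, aln, model) {
  .validate_tree(tree, "felsenstein_loglik")
  stopifnot(inherits(model, "subst_model"))
  pt <- .prep_tree(tree)
  enc <- .encode_alignment(aln, pt$tip_labels)
  dp <- .down_partials(pt, enc, model, pt$el)
  .root_loglik(pt, enc, model, dp)
}

# Per-branch log-likelihood profile using cached partials:
# f(t) = sum_s w_s log( colSums(up[v] * (P(t) %*% down[v])) ) + scale terms.
.branch_loglik <- function(t, model, up_v, down_v, weights, const) {
  x <- colSums(up_v * (transition_probs(model, t) %*% down_v))
  sum(weights * log(x)) + const
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Optimises every branch length of `topology` to maximise the
#' [felsenstein_loglik()] of `aln`, holding the topology fixed. The optimiser
#' is a cyclic per-branch bounded scalar maximisation (Brent on log branch
#' length, bounds `[1e-9, 10]` substitutions/site): partial likelihoods above
#' and below the focal branch are recomputed freshly for each branch, and
#' full passes over all branches are repeated until the log-likelihood
#' improves by less than `tol`. Optionally the HKY kappa parameter is
#' profiled jointly (one bounded 1-D optimisation per pass).
#'
#' @param topology rooted `phylo`; its branch lengths (any units) serve only
#'   as the starting point, clamped into the search bounds.
#' @param aln alignment covering all tips.
#' @param model a [subst_model()].
#' @param optimize_kappa if `TRUE` (HKY only), kappa is re-optimised after
#'   each pass.
#' @param tol convergence tolerance on the log-likelihood (default `1e-6`).
#' @param max_passes maximum number of optimisation passes; if reached
#'   without convergence a warning is issued and the best-found solution
#'   returned.
#' @return the tree with optimised branch lengths (units `"subs/site"`) and
#'   attributes `loglik`, `model` (the possibly updated model) and
#'   `convergence` (logical).
#' @export
optimize_branch_lengths <- function(topology, aln, model,
                                    optimize_kappa = FALSE,
                                    tol = 1e-6, max_passes = 25L) {
  .validate_tree(topology, "optimize_branch_lengths")
  stopifnot(inherits(model, "subst_model"))
  if (optimize_kappa && model$name != "HKY")
    stop("kappa can only be optimised for HKY", call. = FALSE)
  lb <- 1e-9; ub <- 10
  pt <- .prep_tree(topology)
  enc <- .encode_alignment(aln, pt$tip_labels)
  el <- pmin(pmax(pt$el, lb), ub)
  edge_above <- match(seq_len(pt$n_node), pt$edge[, 2])  # edge index above each node
  kids <- vector("list", pt$n_node)                      # child edges per node
  sp <- split(seq_len(nrow(pt$edge)), pt$edge[, 1])
  kids[as.integer(names(sp))] <- sp

  loglik_at <- function(el, model) {
    .root_loglik(pt, enc, model, .down_partials(pt, enc, model, el))
  }
  ll0 <- loglik_at(el, model)
  ll_prev <- ll0
  converged <- FALSE
  for (pass in seq_len(max_passes)) {
    for (e in seq_len(nrow(pt$edge))) {
      dp <- .down_partials(pt, enc, model, el)
      v <- pt$edge[e, 2]
      upv <- .up_for_node(pt, enc, model, el, dp, v, edge_above, kids)
      up_v <- upv$up; down_v <- dp$down[[v]]
      f <- function(u) .branch_loglik(exp(u), model, up_v, down_v, enc$weights, 0)
      cur <- f(log(el[e]))
      opt <- stats::optimize(f, interval = c(log(lb), log(ub)),
                             maximum = TRUE, tol = 1e-7)
      if (opt$objective > cur) el[e] <- exp(opt$maximum)
    }
    if (optimize_kappa) {
      fk <- function(lk) {
        loglik_at(el, subst_model("HKY", kappa = exp(lk), pi = model$pi))
      }
      ok <- stats::optimize(fk, interval = log(c(0.2, 100)), maximum = TRUE,
                            tol = 1e-4)
      model <- subst_model("HKY", kappa = exp(ok$maximum), pi = model$pi)
    }
    ll <- loglik_at(el, model)
    if (ll - ll_prev < tol && pass > 1L) { converged <- TRUE; ll_prev <- max(ll, ll_prev); break }
    ll_prev <- ll
  }
  if (!converged)
    warning("branch-length optimisation did not converge in ", max_passes,
            " passes; returning best-found solution")
  out <- pt$tree
  out$edge.length <- el
  out <- set_tree_units(out, "subs/site")
  attr(out, "loglik") <- ll_prev
  attr(out, "model") <- model
  attr(out, "convergence") <- converged
  out
}
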