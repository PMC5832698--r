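#' Nucleotide substitution models (JC, HKY)
#'
#' Constructs a reversible nucleotide substitution model with its rate matrix
#' normalised to one expected substitution per site per unit branch length,
#' eigendecomposed once so transition probabilities are cheap to evaluate.
#'
#' @param name `"JC"` or `"HKY"`.
#' @param kappa transition/transversion rate ratio (> 0, HKY only).
#' @param pi base frequencies in order A, C, G, T; must sum to 1. Defaults to
#'   uniform for JC; required (or taken empirically from data) for HKY.
#' @return an object of class `subst_model`.
#' @examples
#' m <- subst_model("HKY", kappa = 4, pi = c(0.3, 0.2, 0.2, 0.3))
#' rowSums(transition_probs(m, 0.1))
#' @export
subst_model <- function(name = c("JC", "HKY"), kappa = NULL, pi = NULL) {
  name <- match.arg(name)
  if (name == "JC") {
    if (is.null(pi)) pi <- rep(0.25, 4)
    if (max(abs(pi - 0.25)) > 1e-9)
      stop("JC requires uniform base frequencies", call. = FALSE)
    kappa <- 1
  } else {
    if (is.null(kappa)) kappa <- 4
    if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0", call. = FALSE)
    if (is.null(pi)) stop("HKY requires base frequencies 'pi'", call. = FALSE)
  }
  pi <- as.numeric(pi)
  if (length(pi) != 4L || any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    stop("pi must be 4 non-negative frequencies summing to 1", call. = FALSE)
  names(pi) <- c("A", "C", "G", "T")
  m <- list(name = name, kappa = kappa, pi = pi)
  m <- c(m, .decompose_rate_matrix(.hky_rate_matrix(kappa, pi), pi))
  structure(m, class = "subst_model")
}

# HKY rate matrix (JC is the kappa = 1, uniform-pi special case),
# normalised so -sum(pi * diag(Q)) = 1 substitution/site per unit length.
.hky_rate_matrix <- function(kappa, pi) {
  states <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(states, states))
  transitions <- rbind(c(1, 3), c(3, 1), c(2, 4), c(4, 2))  # A<->G, C<->T
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    rate <- pi[j]
    if (any(transitions[, 1] == i & transitions[, 2] == j)) rate <- rate * kappa
    Q[i, j] <- rate
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Symmetrise with sqrt(pi) similarity, eigendecompose; P(t) = L1 diag(e^{vt}) L2.
# Zero frequencies are perturbed infinitesimally to keep the similarity
# transform defined (they cannot occur for data containing all four bases).
.decompose_rate_matrix <- function(Q, pi) {
  pi <- pmax(pi, 1e-12)
  sq <- sqrt(pi)
  B <- (sq %o% (1 / sq)) * Q              # symmetric for reversible Q
  B <- (B + t(B)) / 2                     # guard numeric asymmetry
  e <- eigen(B, symmetric = TRUE)
  L1 <- (1 / sq) * e$vectors              # diag(1/sq) %*% U
  L2 <- t(e$vectors * sq)                 # t(U) %*% diag(sq) ... rows scaled
  list(Q = Q, eigenvalues = e$values, L1 = L1, L2 = L2)
}

#' Transition probability matrix P(t)
#'
#' @param model a [subst_model()].
#' @param t branch length in expected substitutions per site (>= 0).
#' @return 4x4 row-stochastic matrix, states in order A, C, G, T.
#' @export
transition_probs <- function(model, t) {
  if (t < 0) stop("negative branch length", call. = FALSE)
  P <- model$L1 %*% (exp(model$eigenvalues * t) * model$L2)
  P[P < 0] <- 0
  P
}

#' Empirical base frequencies of an alignment
#'
#' @param aln an alignment (see [as_alignment()]); gaps and Ns are ignored.
#' @return named numeric vector of A, C, G, T frequencies.
#' @export
empirical_frequencies <- function(aln) {
  m <- as_alignment(aln)
  counts <- table(factor(m, levels = c("A", "C", "G", "T")))
  f <- as.numeric(counts)
  if (sum(f) == 0) stop("alignment contains no unambiguous bases", call. = FALSE)
  f <- f / sum(f)
  names(f) <- c("A", "C", "G", "T")
  f
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s substitution model", x$name))
  if (x$name == "HKY") cat(sprintf(", kappa = %.4g", x$kappa))
  cat("\n  pi:", paste(sprintf("%s=%.4g", names(x$pi), x$pi), collapse = " "), "\n")
  invisible(x)
}
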