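# Standard genetic code, built once from seqinr's translation machinery.
.codon_env <- new.env(parent = emptyenv())

.codon_table <- function() {
  if (is.null(.codon_env$tab)) {
    bases <- c("A", "C", "G", "T")
    codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    codons <- sort(codons)
    aa <- vapply(codons, function(cd)
      seqinr::translate(tolower(strsplit(cd, "")[[1]])), "")
    .codon_env$tab <- setNames(aa, codons)
  }
  .codon_env$tab
}

.translate_codon <- function(codon) unname(.codon_table()[codon])

.is_stop <- function(codon) .translate_codon(codon) == "*"

#' Synonymous/non-synonymous step counts between two codons
#'
#' Averages the numbers of synonymous and non-synonymous single-nucleotide
#' steps over all minimal mutational paths between the two codons that avoid
#' stop codons at intermediate steps. Paths are minimal, so the two counts
#' always sum to the nucleotide Hamming distance. If every minimal path
#' passes through a stop codon (which does not occur for standard-code
#' non-stop codon pairs), all minimal paths are averaged instead.
#'
#' @param codon_a,codon_b three-letter nucleotide strings (non-stop codons).
#' @return named numeric vector `c(syn = , nonsyn = )`, possibly fractional.
#' @examples
#' codon_change_counts("AAA", "AGG")  # Lys->Arg via two 2-step paths
#' @export
codon_change_counts <- function(codon_a, codon_b) {
  a <- toupper(codon_a); b <- toupper(codon_b)
  tab <- .codon_table()
  for (cd in c(a, b)) {
    if (is.na(tab[cd])) stop("invalid codon: ", cd, call. = FALSE)
    if (tab[cd] == "*") stop("stop codon input: ", cd, call. = FALSE)
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  diff_pos <- which(av != bv)
  d <- length(diff_pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  orders <- .permutations(diff_pos)
  count_path <- function(ord) {
    cur <- av; syn <- 0; nonsyn <- 0
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- bv[pos]
      aa1 <- tab[paste(cur, collapse = "")]
      aa2 <- tab[paste(nxt, collapse = "")]
      if (aa2 == "*") return(NULL)           # path passes through a stop
      if (aa1 == aa2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  paths <- lapply(orders, count_path)
  valid <- paths[!vapply(paths, is.null, TRUE)]
  if (length(valid) == 0L) {
    # no stop-avoiding minimal path; average all minimal paths
    count_any <- function(ord) {
      cur <- av; syn <- 0; nonsyn <- 0
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- bv[pos]
        if (tab[paste(cur, collapse = "")] == tab[paste(nxt, collapse = "")])
          syn <- syn + 1 else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      c(syn = syn, nonsyn = nonsyn)
    }
    valid <- lapply(orders, count_any)
  }
  Reduce(`+`, valid) / length(valid)
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

#' McDonald-Kreitman tables
#'
#' Holds the 2x2 counts of the MK test: polymorphic (within the ingroup) and
#' fixed (ingroup vs outgroup) changes, split into non-synonymous and
#' synonymous. Counts may be fractional through mutational-path averaging.
#'
#' @param Pn,Ps polymorphic non-synonymous / synonymous counts.
#' @param Dn,Ds fixed (divergence) non-synonymous / synonymous counts.
#' @return an object of class `mk_table`; the neutrality index
#'   `NI = (Pn/Ps)/(Dn/Ds)`, `alpha = 1 - NI` and the Fisher p-value are
#'   `NA` until [mk_test()] fills them.
#' @export
mk_table <- function(Pn, Ps, Dn, Ds) {
  counts <- c(Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("MK counts must be finite and non-negative", call. = FALSE)
  structure(list(Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds,
                 NI = NA_real_, alpha = NA_real_, p = NA_real_),
            class = "mk_table")
}

#' @export
print.mk_table <- function(x, ...) {
  cat(sprintf("McDonald-Kreitman table: Pn = %.3g, Ps = %.3g, Dn = %.3g, Ds = %.3g\n",
              x$Pn, x$Ps, x$Dn, x$Ds))
  if (!is.na(x$p))
    cat(sprintf("  NI = %s, alpha = %s, Fisher p = %.4g\n",
                ifelse(is.na(x$NI), "NA", sprintf("%.4g", x$NI)),
                ifelse(is.na(x$alpha), "NA", sprintf("%.4g", x$alpha)), x$p))
  invisible(x)
}

#' MK polymorphism and divergence counts from codon alignments
#'
#' Per codon column: polymorphic changes are counted among the codon states
#' segregating within the ingroup (via [codon_change_counts()], each
#' segregating state counted once against the most frequent state, no
#' frequency weighting); fixed differences are counted between the ingroup
#' state and the outgroup state only at codons where the ingroup is
#' monomorphic. Codon columns containing a gap or N in any sequence, or a
#' stop codon, are wholly excluded.
#'
#' @param ingroup codon alignment of the ingroup (length divisible by 3,
#'   frame 0); see [as_alignment()].
#' @param outgroup a single outgroup sequence (string, or 1-row alignment)
#'   of the same length.
#' @return an [mk_table()] with counts filled and an `excluded_codons`
#'   attribute.
#' @export
mk_counts <- function(ingroup, outgroup) {
  m <- as_alignment(ingroup)
  if (is.character(outgroup) && length(outgroup) == 1L && is.null(names(outgroup)))
    outgroup <- setNames(outgroup, "outgroup")
  og <- as_alignment(outgroup)
  if (nrow(og) != 1L) stop("outgroup must be a single sequence", call. = FALSE)
  if (ncol(og) != ncol(m)) stop("outgroup length does not match ingroup", call. = FALSE)
  if (ncol(m) %% 3L != 0L)
    stop("alignment length must be divisible by 3 (reading frame 0)", call. = FALSE)
  n_codon <- ncol(m) %/% 3L
  Pn <- Ps <- Dn <- Ds <- 0
  excluded <- 0L
  tab <- .codon_table()
  for (k in seq_len(n_codon)) {
    cols <- (3L * (k - 1L) + 1L):(3L * k)
    cods_in <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    cod_out <- paste(og[1, cols], collapse = "")
    all_cods <- c(cods_in, cod_out)
    if (any(grepl("[-N]", all_cods)) || any(tab[all_cods] == "*")) {
      excluded <- excluded + 1L
      next
    }
    states <- unique(cods_in)
    if (length(states) > 1L) {
      major <- names(sort(table(cods_in), decreasing = TRUE))[1]
      for (s in setdiff(states, major)) {
        cc <- codon_change_counts(major, s)
        Ps <- Ps + cc["syn"]; Pn <- Pn + cc["nonsyn"]
      }
    } else if (states != cod_out) {
      cc <- codon_change_counts(states, cod_out)
      Ds <- Ds + cc["syn"]; Dn <- Dn + cc["nonsyn"]
    }
  }
  out <- mk_table(Pn = unname(Pn), Ps = unname(Ps),
                  Dn = unname(Dn), Ds = unname(Ds))
  attr(out, "excluded_codons") <- excluded
  out
}

#' McDonald-Kreitman test
#'
#' Two-sided Fisher exact test on the 2x2 table `[[Pn, Ps], [Dn, Ds]]`
#' (fractional counts are rounded to the nearest integer for the exact
#' test; the raw counts are kept for the neutrality index). Fills
#' `NI = (Pn/Ps)/(Dn/Ds)` and `alpha = 1 - NI`; both are reported as `NA`
#' whenever a denominator is zero.
#'
#' @param table an [mk_table()] with counts filled.
#' @return the table with `p`, `NI` and `alpha` filled.
#' @examples
#' mk_test(mk_table(Pn = 2, Ps = 8, Dn = 10, Ds = 5))
#' @export
mk_test <- function(table) {
  stopifnot(inherits(table, "mk_table"))
  counts <- c(table$Pn, table$Ps, table$Dn, table$Ds)
  if (all(counts == 0)) stop("all-zero MK table", call. = FALSE)
  m <- matrix(round(counts), 2, 2, byrow = TRUE)
  table$p <- fisher.test(m)$p.value
  table$NI <- if (table$Ps > 0 && table$Dn > 0 && table$Ds > 0)
    (table$Pn / table$Ps) / (table$Dn / table$Ds) else NA_real_
  table$alpha <- if (is.na(table$NI)) NA_real_ else 1 - table$NI
  table
}

#' Association between an amino-acid site and water depth
#'
#' Tests whether the water depths of individuals carrying the two amino-acid
#' states at a site differ, with an unpaired two-sample rank test
#' (Mann-Whitney U): exact p-value when both groups have at most 12
#' observations and there are no ties, normal approximation with tie
#' correction otherwise. States carried by fewer than 2 individuals are
#' dropped; exactly two states must remain.
#'
#' @param data data.frame with columns `individual`, `state` (amino-acid
#'   state at the site) and `depth` (metres, > 0).
#' @return list with `statistic` (Mann-Whitney U of the first state group),
#'   `p`, the two group sizes, the test flavour used, and a `note` recording
#'   that the unpaired rank-sum test is applied (the sampling design has no
#'   pairing).
#' @export
depth_association <- function(data) {
  stopifnot(is.data.frame(data), all(c("state", "depth") %in% names(data)))
  if (any(!is.finite(data$depth)) || any(data$depth <= 0))
    stop("depths must be positive", call. = FALSE)
  counts <- table(data$state)
  keep <- names(counts)[counts >= 2]
  data <- data[data$state %in% keep, , drop = FALSE]
  states <- sort(unique(data$state))
  if (length(states) < 2L)
    stop("site is monomorphic after dropping rare states; association undefined",
         call. = FALSE)
  if (length(states) > 2L)
    stop("more than two amino-acid states; test requires a biallelic site",
         call. = FALSE)
  g1 <- data$depth[data$state == states[1]]
  g2 <- data$depth[data$state == states[2]]
  if (length(unique(c(g1, g2))) == 1L)
    stop("all depths tied; association undefined", call. = FALSE)
  has_ties <- anyDuplicated(c(g1, g2)) > 0
  use_exact <- length(g1) <= 12 && length(g2) <= 12 && !has_ties
  wt <- suppressWarnings(
    wilcox.test(g1, g2, exact = use_exact, correct = !use_exact)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = c(length(g1), length(g2)),
       states = states,
       method = if (use_exact) "exact" else "normal approximation, tie-corrected",
       note = "unpaired rank-sum (Mann-Whitney) test; depth groups are independent samples")
}
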