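#' Coerce sequences to an alignment matrix
#'
#' An alignment is stored as a character matrix (rows = sequences, columns =
#' sites) over the alphabet A, C, G, T, `-`, N. Input may be a character
#' matrix, a named character vector of equal-length strings, or a list of
#' character vectors (as returned by FASTA readers). IUPAC ambiguity codes
#' other than N are mapped to N.
#'
#' @param x sequences in any of the accepted forms.
#' @return character matrix with unique rownames.
#' @export
as_alignment <- function(x) {
  if (is.matrix(x) && is.character(x)) {
    m <- x
  } else if (is.character(x)) {
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stop("sequences must have unique names", call. = FALSE)
    lens <- nchar(x)
    if (length(unique(lens)) != 1L)
      stop("sequences have unequal lengths", call. = FALSE)
    m <- do.call(rbind, strsplit(x, ""))
    rownames(m) <- names(x)
  } else if (is.list(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) != 1L)
      stop("sequences have unequal lengths", call. = FALSE)
    m <- do.call(rbind, x)
    rownames(m) <- names(x)
  } else {
    stop("cannot interpret 'x' as an alignment", call. = FALSE)
  }
  if (ncol(m) == 0L) stop("alignment has zero length", call. = FALSE)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("sequences must have unique names", call. = FALSE)
  m <- toupper(m)
  m[m == "U"] <- "T"
  m[!(m %in% c("A", "C", "G", "T", "-", "N"))] <- "N"
  m
}

#' Read a FASTA nucleotide alignment
#'
#' @param path FASTA file; all sequences must have equal length.
#' @return alignment matrix, see [as_alignment()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- ape::read.FASTA(path)
  if (length(seqs) == 0L) stop("no sequences in ", path, call. = FALSE)
  as_alignment(as.character(seqs))
}

#' Write an alignment to FASTA
#'
#' @param aln alignment (see [as_alignment()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  m <- as_alignment(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(c(paste0(">", rownames(m)[i]), paste(m[i, ], collapse = "")), con)
  }
  invisible(path)
}

# Encode an alignment for the pruning engine: site-pattern compression plus
# per-tip 4 x n_patterns conditional-likelihood matrices (gap/N = all ones).
.encode_alignment <- function(aln, tip_labels) {
  m <- as_alignment(aln)
  missing <- setdiff(tip_labels, rownames(m))
  if (length(missing))
    stop("tip(s) without sequence: ", paste(missing, collapse = ", "), call. = FALSE)
  m <- m[tip_labels, , drop = FALSE]
  key <- apply(m, 2, paste, collapse = "\r")
  first <- !duplicated(key)
  weights <- as.numeric(table(factor(key, levels = key[first])))
  mp <- m[, first, drop = FALSE]
  states <- c("A", "C", "G", "T")
  tips <- vector("list", length(tip_labels))
  for (i in seq_along(tip_labels)) {
    L <- matrix(0, 4, ncol(mp))
    known <- mp[i, ] %in% states
    idx <- match(mp[i, known], states)
    L[cbind(idx, which(known))] <- 1
    L[, !known] <- 1
    tips[[i]] <- L
  }
  list(tips = tips, weights = weights, n_sites = ncol(m), n_patterns = ncol(mp))
}
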