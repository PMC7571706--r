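#' Reverse complement of DNA sequences
#'
#' Watson-Crick complement, reversed. Vectorised over its argument and an
#' involution: `revcomp(revcomp(x))` equals `x`.
#'
#' @param x Character vector of DNA sequences over the alphabet A, C, G, T.
#' @return Character vector of the same length.
#' @examples
#' revcomp("ACCGTTAG")  # "CTAACGGT"
#' @export
revcomp <- function(x) {
  .check_seq(x)
  if (!length(x)) return(character(0))
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

#' Canonical identity of a double-stranded binding site
#'
#' A binding site and its reverse complement denote the same double-stranded
#' DNA molecule. The canonical representative is the lexicographic minimum of
#' the two strands, so `canonical_genotype(s) == canonical_genotype(revcomp(s))`
#' and the function is idempotent.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of canonical genotypes.
#' @examples
#' canonical_genotype("TTTTTTTT")  # "AAAAAAAA"
#' @export
canonical_genotype <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

#' Enumerate all canonical genotypes of length k
#'
#' Enumerates every DNA k-mer, collapses strand-equivalent pairs to their
#' canonical representative, and returns the distinct genotypes, sorted.
#' For even k the count is (4^k - 4^(k/2))/2 + 4^(k/2); for k = 8 this is
#' 32,896 double-stranded sequences.
#'
#' @param k Sequence length (positive integer).
#' @return Sorted character vector of canonical genotypes.
#' @export
enumerate_genotypes <- function(k) {
  stopifnot(length(k) == 1L, k >= 1, k == as.integer(k))
  key <- as.character(k)
  cached <- .genotype_cache[[key]]
  if (!is.null(cached)) return(cached)
  n <- 4L^k
  idx <- matrix(0L, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    idx[, j] <- rep(rep(0:3, each = 4L^(k - j)), length.out = n)
  }
  chars <- matrix(.BASES[idx + 1L], nrow = n)
  seqs <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
  comp <- matrix(c("T", "G", "C", "A")[idx + 1L], nrow = n)
  rcs <- do.call(paste0, as.data.frame(comp[, k:1, drop = FALSE],
                                       stringsAsFactors = FALSE))
  out <- sort(unique(ifelse(seqs <= rcs, seqs, rcs)))
  .genotype_cache[[key]] <- out
  out
}

.genotype_cache <- new.env(parent = emptyenv())

#' Classify a point mutation as transition or transversion
#'
#' Transitions exchange a purine for a purine (A and G) or a pyrimidine for a
#' pyrimidine (C and T); the remaining eight base changes are transversions.
#' The classification is symmetric in its arguments and invariant under
#' complementing both bases, so it is well defined on double-stranded sites.
#'
#' @param from,to Single bases (vectorised); must differ elementwise.
#' @return Character vector with elements `"transition"` or `"transversion"`.
#' @examples
#' classify_mutation("A", "G")  # transition
#' classify_mutation("C", "A")  # transversion
#' @export
classify_mutation <- function(from, to) {
  .check_seq(from, "from"); .check_seq(to, "to")
  stopifnot(all(nchar(from) == 1L), all(nchar(to) == 1L))
  if (any(from == to)) {
    stop("'from' and 'to' must be distinct bases", call. = FALSE)
  }
  unname(ifelse(.TI_PARTNER[from] == to, "transition", "transversion"))
}

#' Point-mutation neighbourhood of a canonical genotype
#'
#' All distinct canonical genotypes reachable by a single substitution in
#' either strand, each with its mutation class. Mutants of a palindromic
#' sequence coalesce pairwise after canonicalisation, so palindromes have
#' 3k/2 neighbours instead of 3k; the class of a merged pair is well defined
#' because classification is complement-invariant.
#'
#' @param g A single canonical genotype.
#' @return `data.frame` with columns `genotype` and `class`.
#' @export
genotype_neighbors <- function(g) {
  stopifnot(length(g) == 1L)
  .check_seq(g)
  b <- strsplit(g, "", fixed = TRUE)[[1]]
  k <- length(b)
  muts <- character(3L * k)
  cls <- character(3L * k)
  pos <- 0L
  for (i in seq_len(k)) {
    for (nb in .BASES[.BASES != b[i]]) {
      pos <- pos + 1L
      m <- b
      m[i] <- nb
      muts[pos] <- paste(m, collapse = "")
      cls[pos] <- if (.TI_PARTNER[[b[i]]] == nb) "transition" else "transversion"
    }
  }
  cg <- canonical_genotype(muts)
  keep <- !duplicated(cg) & cg != g
  data.frame(genotype = cg[keep], class = cls[keep], stringsAsFactors = FALSE)
}

# Hamming distance between two equal-length sequences given as strings
.hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# substitution distance between canonical genotypes, minimised over strand
.canonical_distance <- function(a, b) {
  min(.hamming(a, b), .hamming(revcomp(a), b))
}
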