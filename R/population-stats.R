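# Coerce a population representation to a named count vector.
# Accepts: a wf_sim (landscape + off-landscape counts), a named numeric
# vector of counts, or a plain vector of elements (tabulated).
.as_counts <- function(x) {
  if (inherits(x, "wf_sim")) {
    cnt <- c(x$counts[x$counts > 0], x$off_counts)
    return(cnt)
  }
  if (is.numeric(x) && !is.null(names(x))) {
    if (any(x < 0)) stop("negative multiplicities", call. = FALSE)
    return(x[x > 0])
  }
  tab <- table(x)
  setNames(as.numeric(tab), names(tab))
}

#' Overlap coefficient between two populations (multisets)
#'
#' `O(A, B) = |A intersect B| / min(|A|, |B|)`, where the intersection takes
#' the elementwise minimum of multiplicities and `|A|` is the sum of
#' multiplicities. 1 when the populations are identical (same individuals in
#' the same proportions), 0 when they share no individuals. Symmetric and
#' invariant to relabelling.
#'
#' @param a,b Populations: `wf_sim` objects, named count vectors, or plain
#'   vectors of elements.
#' @return Overlap in \[0, 1\].
#' @examples
#' overlap(c(1, 1, 2, 2, 2, 3), c(1, 2, 2, 4))  # 0.75
#' @export
overlap <- function(a, b) {
  ca <- .as_counts(a)
  cb <- .as_counts(b)
  if (!length(ca) || !length(cb)) stop("empty multiset", call. = FALSE)
  keys <- union(names(ca), names(cb))
  ma <- setNames(numeric(length(keys)), keys); ma[names(ca)] <- ca
  mb <- setNames(numeric(length(keys)), keys); mb[names(cb)] <- cb
  sum(pmin(ma, mb)) / min(sum(ca), sum(cb))
}

#' Normalized Shannon diversity of a population
#'
#' `H = -sum_i p_i log2 p_i / log2 n`, with `n` the number of sequences in
#' the landscape: 0 for a monomorphic population, 1 for a population spread
#' uniformly over all landscape genotypes.
#'
#' @param pop Population (`wf_sim`, named counts, or element vector).
#' @param n Landscape size (>= 2); inferred from a `wf_sim`.
#' @return Diversity in \[0, 1\].
#' @export
shannon_diversity <- function(pop, n = NULL) {
  if (inherits(pop, "wf_sim") && is.null(n)) n <- pop$landscape_n
  if (is.null(n) || n < 2) stop("'n' (landscape size) must be >= 2",
                                call. = FALSE)
  cnt <- .as_counts(pop)
  if (!length(cnt)) stop("empty population", call. = FALSE)
  p <- cnt / sum(cnt)
  -sum(p * log2(p)) / log2(n)
}

#' Nucleotide diversity of a population of binding sites
#'
#' `pi = sum_{x,y} p_x p_y d(x, y) / k`, the expected per-site substitution
#' distance between two individuals drawn with replacement, where `d` is the
#' substitution distance between canonical genotypes minimised over strand
#' orientation. Population (not sample-corrected) estimator by default; the
#' `n/(n-1)` correction is available via `corrected`.
#'
#' @param pop Population with genotype names (`wf_sim` or named counts).
#' @param corrected Apply the `N/(N-1)` sample-size correction
#'   (default `FALSE`).
#' @return Nucleotide diversity in \[0, 1\].
#' @export
nucleotide_diversity <- function(pop, corrected = FALSE) {
  cnt <- .as_counts(pop)
  if (!length(cnt)) stop("empty population", call. = FALSE)
  .check_seq(names(cnt), "genotype")
  h <- names(cnt)
  k <- nchar(h[1])
  p <- cnt / sum(cnt)
  if (length(h) == 1L) return(0)
  hm <- lapply(h, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  rm_ <- lapply(revcomp(h), function(s) strsplit(s, "", fixed = TRUE)[[1]])
  d <- matrix(0, length(h), length(h))
  for (a in seq_along(h)) for (z in seq_along(h)) {
    if (a < z) {
      d[a, z] <- min(sum(hm[[a]] != hm[[z]]), sum(rm_[[a]] != hm[[z]])) / k
      d[z, a] <- d[a, z]
    }
  }
  pi_ <- as.numeric(t(p) %*% d %*% p)
  if (corrected) {
    N <- sum(cnt)
    if (N > 1) pi_ <- pi_ * N / (N - 1)
  }
  pi_
}

#' Mutational robustness of a binding site
#'
#' The fraction of all possible point mutations to the site that produce
#' another site in the landscape — by default the dominant genotype network;
#' `scope = "bound"` uses the full bound set recorded on the landscape. The
#' denominator is the size of the canonical neighbourhood (3k for
#' non-palindromic sites, 3k/2 for palindromes).
#'
#' @param g A genotype in the landscape.
#' @param L A `tf_landscape`.
#' @param scope `"dominant"` (default) or `"bound"`.
#' @return Robustness in \[0, 1\].
#' @export
robustness <- function(g, L, scope = c("dominant", "bound")) {
  stopifnot(inherits(L, "tf_landscape"))
  scope <- match.arg(scope)
  if (!g %in% L$genotype) stop("genotype not in landscape", call. = FALSE)
  nb <- genotype_neighbors(g)
  ref <- if (scope == "dominant") L$genotype else L$bound_set
  if (!nrow(nb)) return(0)
  mean(nb$genotype %in% ref)
}

#' Count-weighted mean robustness of a population
#'
#' Averages [robustness()] over the in-landscape individuals of a
#' population, weighted by their counts (off-landscape mutants carry no
#' defined robustness and are excluded).
#'
#' @param pop Population (`wf_sim` or named counts over landscape genotypes).
#' @param L A `tf_landscape`.
#' @param scope Passed to [robustness()].
#' @return Mean robustness in \[0, 1\].
#' @export
population_robustness <- function(pop, L, scope = c("dominant", "bound")) {
  scope <- match.arg(scope)
  cnt <- .as_counts(pop)
  cnt <- cnt[names(cnt) %in% L$genotype]
  if (!length(cnt)) stop("no in-landscape individuals", call. = FALSE)
  r <- vapply(names(cnt), robustness, numeric(1), L = L, scope = scope)
  sum(r * cnt) / sum(cnt)
}

#' Allele-frequency spectrum relative to a reference site
#'
#' Tabulates the single-base polymorphisms segregating in a population
#' relative to a reference genotype (conventionally the site that evolved to
#' the highest frequency in the absence of mutation bias). Each population
#' genotype is oriented to the strand closer to the reference's stored
#' orientation; genotypes one substitution away contribute an entry
#' (position, reference base, alternative base, mutation class, frequency),
#' genotypes further away are pooled into a multi-hit mass. Entry
#' frequencies, the multi-hit mass and the reference frequency sum to 1.
#'
#' @param pop Population (`wf_sim` or named counts).
#' @param reference Reference genotype string.
#' @return List with `entries` (data.frame), `multi_hit` and
#'   `reference_frequency`.
#' @export
allele_spectrum <- function(pop, reference) {
  .check_seq(reference, "reference")
  cnt <- .as_counts(pop)
  if (!length(cnt)) stop("empty population", call. = FALSE)
  p <- cnt / sum(cnt)
  refb <- strsplit(reference, "", fixed = TRUE)[[1]]
  entries <- data.frame(position = integer(0), ref = character(0),
                        alt = character(0), class = character(0),
                        frequency = numeric(0), stringsAsFactors = FALSE)
  multi <- 0
  ref_freq <- 0
  for (g in names(cnt)) {
    cand <- c(g, revcomp(g))
    dd <- vapply(cand, .hamming, numeric(1), b = reference)
    s <- cand[which.min(dd)]  # forward orientation wins ties
    d <- min(dd)
    if (d == 0) {
      ref_freq <- ref_freq + p[[g]]
    } else if (d == 1) {
      sb <- strsplit(s, "", fixed = TRUE)[[1]]
      pos <- which(sb != refb)
      key <- paste(pos, refb[pos], sb[pos])
      hit <- which(entries$position == pos & entries$alt == sb[pos])
      if (length(hit)) {
        entries$frequency[hit] <- entries$frequency[hit] + p[[g]]
      } else {
        entries <- rbind(entries, data.frame(
          position = pos, ref = refb[pos], alt = sb[pos],
          class = classify_mutation(refb[pos], sb[pos]),
          frequency = p[[g]], stringsAsFactors = FALSE))
      }
    } else {
      multi <- multi + p[[g]]
    }
  }
  entries <- entries[order(entries$position, entries$alt), , drop = FALSE]
  rownames(entries) <- NULL
  list(entries = entries, multi_hit = unname(multi),
       reference_frequency = unname(ref_freq))
}

#' Evolvability of an evolved population across a landscape collection
#'
#' Collects the one-mutant neighbours of every genotype present in the
#' population that are not part of the focal landscape, and reports the
#' fraction (and count) of other landscapes in the collection that contain
#' at least one such neighbour — the ability of mutation to bring forth new
#' binding phenotypes.
#'
#' @param pop Population (`wf_sim` or named counts).
#' @param focal The focal `tf_landscape` the population evolved on.
#' @param collection List of other `tf_landscape`s (excluding the focal
#'   one).
#' @return List with `fraction` and `count`.
#' @export
evolvability <- function(pop, focal, collection) {
  stopifnot(inherits(focal, "tf_landscape"))
  if (!length(collection)) stop("empty landscape collection", call. = FALSE)
  stopifnot(all(vapply(collection, inherits, TRUE, "tf_landscape")))
  cnt <- .as_counts(pop)
  present <- names(cnt)
  nb <- unique(unlist(lapply(present,
                             function(g) genotype_neighbors(g)$genotype)))
  off_focal <- setdiff(nb, focal$genotype)
  hits <- vapply(collection, function(Lc) any(off_focal %in% Lc$genotype),
                 logical(1))
  list(fraction = mean(hits), count = sum(hits))
}
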