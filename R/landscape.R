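#' Score tables of 8-mer binding affinities
#'
#' A score table maps canonical double-stranded genotypes to protein-binding
#' microarray scores: an E-score in \[-0.5, 0.5\] (a rank-based proxy for
#' relative binding affinity) and, optionally, a Z-score. Both strand
#' orientations of an input row collapse to a single canonical entry.
#'
#' @param genotype Character vector of DNA sequences (canonicalised here).
#' @param escore Numeric vector of E-scores.
#' @param zscore Optional numeric vector of Z-scores.
#' @param tf_name Optional transcription factor name.
#' @param replicate_id Optional replicate identifier.
#' @return A `score_table`: a data.frame with columns `genotype`, `escore`
#'   and (if given) `zscore`, one row per canonical genotype.
#' @export
score_table <- function(genotype, escore, zscore = NULL, tf_name = NULL,
                        replicate_id = NULL) {
  .check_seq(genotype, "genotype")
  stopifnot(is.numeric(escore), length(escore) == length(genotype))
  if (length(unique(nchar(genotype))) > 1L) {
    stop("all genotypes in a score table must have the same length",
         call. = FALSE)
  }
  g <- canonical_genotype(genotype)
  df <- data.frame(genotype = g, escore = as.numeric(escore),
                   stringsAsFactors = FALSE)
  if (!is.null(zscore)) {
    stopifnot(length(zscore) == length(genotype))
    df$zscore <- as.numeric(zscore)
  }
  dup <- duplicated(df$genotype)
  if (any(dup)) {
    sc <- split(df$escore, df$genotype)
    spread <- vapply(sc, function(v) diff(range(v)), numeric(1))
    if (any(spread > 1e-8)) {
      stop("conflicting scores for canonical genotype '",
           names(spread)[which.max(spread)], "'", call. = FALSE)
    }
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$genotype), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, tf_name = tf_name, replicate_id = replicate_id,
            class = c("score_table", "data.frame"))
}

#' Read a k-mer score table
#'
#' Reads tab-separated protein-binding-microarray exports. Each row holds a
#' k-mer, optionally its reverse complement, and one or more numeric score
#' columns (E-score first; a trailing column, when present, is taken as the
#' Z-score). Lines starting with `#` are comments; a header line is detected
#' automatically. Rows listing the two orientations of one site separately
#' must agree in score.
#'
#' @param path Path to a TSV file.
#' @param tf_name,replicate_id Optional metadata stored on the result.
#' @return A [score_table()].
#' @export
read_score_table <- function(path, tf_name = NULL, replicate_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data rows in '", path, "'", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_dna <- function(x) grepl("^[ACGTacgt]+$", x)
  if (!is_dna(fields[[1]][1])) {  # header row
    fields <- fields[-1]
    lineno <- lineno[-1]
    if (!length(fields)) stop("no data rows in '", path, "'", call. = FALSE)
  }
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L || ncol < 2L) {
    stop("malformed row at line ", lineno[which(lengths(fields) != ncol[1])[1]],
         " of '", path, "'", call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = ncol, byrow = TRUE)
  kmer <- toupper(m[, 1])
  has_rc <- ncol >= 3L && all(is_dna(m[, 2])) && all(nchar(m[, 2]) == nchar(kmer))
  score_cols <- if (has_rc) 3L:ncol else 2L:ncol
  if (has_rc) {
    rc <- toupper(m[, 2])
    bad <- canonical_genotype(kmer) != canonical_genotype(rc)
    if (any(bad)) {
      stop("k-mer and reverse complement disagree at line ",
           lineno[which(bad)[1]], " of '", path, "'", call. = FALSE)
    }
  }
  num <- suppressWarnings(
    matrix(as.numeric(m[, score_cols, drop = FALSE]), nrow = nrow(m)))
  if (anyNA(num[, 1])) {
    stop("non-numeric score at line ", lineno[which(is.na(num[, 1]))[1]],
         " of '", path, "'", call. = FALSE)
  }
  zscore <- if (length(score_cols) >= 2L) num[, ncol(num)] else NULL
  score_table(kmer, num[, 1], zscore = zscore, tf_name = tf_name,
              replicate_id = replicate_id)
}

#' Write a score table in the same TSV dialect the reader accepts
#'
#' @param tab A [score_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(tab, path) {
  stopifnot(inherits(tab, "score_table"))
  df <- data.frame(kmer = tab$genotype, kmer_rc = revcomp(tab$genotype),
                   escore = tab$escore, stringsAsFactors = FALSE)
  if (!is.null(tab$zscore)) df$zscore <- tab$zscore
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a genotype-phenotype landscape from a score table
#'
#' Thresholds the table at `bind_threshold` (sequences specifically bound by
#' the factor have E-score above 0.35), connects bound genotypes that differ
#' by a single point mutation of either strand, and keeps the largest
#' connected component (the dominant genotype network). Sizes of discarded
#' components are recorded on the result. The landscape surface is the score
#' of each retained genotype; `delta` is the measurement-noise threshold used
#' to decide whether two sites genuinely differ in affinity (see
#' [estimate_delta()]).
#'
#' @param table A [score_table()].
#' @param bind_threshold Binding threshold; genotypes with score strictly
#'   above it are retained. Default 0.35.
#' @param min_component Minimum admissible size of the dominant component.
#'   Default 100.
#' @param delta Noise threshold to store on the landscape (default 0).
#' @param score_kind Which score defines the surface: `"escore"` (default) or
#'   `"zscore"`.
#' @return A `tf_landscape` object: genotypes, named score vector, undirected
#'   edge list with mutation classes, `delta`, the global peak, and the sizes
#'   of any discarded components.
#' @export
build_landscape <- function(table, bind_threshold = 0.35, min_component = 100,
                            delta = 0, score_kind = c("escore", "zscore")) {
  stopifnot(inherits(table, "score_table"), nrow(table) > 0, delta >= 0)
  score_kind <- match.arg(score_kind)
  if (score_kind == "zscore" && is.null(table$zscore)) {
    stop("score table has no zscore column", call. = FALSE)
  }
  s_all <- if (score_kind == "escore") table$escore else table$zscore
  bound <- !is.na(s_all) & s_all > bind_threshold
  if (!any(bound)) stop("no bound genotypes above threshold ", bind_threshold,
                        call. = FALSE)
  nodes <- table$genotype[bound]
  score <- setNames(s_all[bound], nodes)
  edges <- .hamming1_edges(nodes)
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    comp <- igraph::components(g)
    sizes <- comp$csize
    big <- which(sizes == max(sizes))
    if (length(big) > 1L) {  # deterministic tie-break: smallest member name
      first_member <- vapply(big, function(ci) {
        min(names(comp$membership)[comp$membership == ci])
      }, character(1))
      big <- big[order(first_member)][1L]
    }
    keep <- names(comp$membership)[comp$membership == big]
    discarded <- sizes[-big]
  } else {
    keep <- min(nodes)
    discarded <- rep(1L, length(nodes) - 1L)
  }
  if (length(keep) < min_component) {
    stop("landscape too small: dominant component has ", length(keep),
         " genotypes (< ", min_component, ")", call. = FALSE)
  }
  keep <- sort(keep)
  score <- score[keep]
  edges <- edges[edges$from %in% keep & edges$to %in% keep, , drop = FALSE]
  rownames(edges) <- NULL
  peak <- .peak_of(score)
  structure(list(
    tf = attr(table, "tf_name"),
    genotype = keep,
    score = score,
    edges = edges,
    delta = delta,
    peak = peak,
    score_kind = score_kind,
    k = nchar(keep[1L]),
    bound_set = sort(nodes),
    discarded_components = sort(as.integer(discarded), decreasing = TRUE)
  ), class = "tf_landscape")
}

# undirected Hamming-1 edge list (from < to) over a canonical genotype set
.hamming1_edges <- function(nodes) {
  from <- character(0); to <- character(0); cls <- character(0)
  in_set <- new.env(parent = emptyenv())
  for (g in nodes) assign(g, TRUE, envir = in_set)
  for (g in nodes) {
    nb <- genotype_neighbors(g)
    hit <- vapply(nb$genotype, function(x)
      exists(x, envir = in_set, inherits = FALSE), logical(1))
    hit <- hit & nb$genotype > g
    if (any(hit)) {
      from <- c(from, rep(g, sum(hit)))
      to <- c(to, nb$genotype[hit])
      cls <- c(cls, nb$class[hit])
    }
  }
  data.frame(from = from, to = to, class = cls, stringsAsFactors = FALSE)
}

.peak_of <- function(score) {
  mx <- max(score)
  at_max <- sort(names(score)[score == mx])
  if (length(at_max) > 1L) {
    warning("global peak tied among ", length(at_max),
            " genotypes; lexicographically smallest chosen", call. = FALSE)
  }
  at_max[1L]
}

#' Estimate the measurement-noise threshold from replicate arrays
#'
#' `delta` is the residual standard error of an ordinary least-squares
#' regression of the second replicate's scores on the first replicate's
#' scores, over the genotypes bound (score above `bind_threshold`) in both
#' replicates. The regression orientation (replicate 2 on replicate 1) is a
#' fixed convention; OLS is not symmetric in its arguments.
#'
#' @param rep1,rep2 Two [score_table()]s for the same factor.
#' @param bind_threshold Binding threshold (default 0.35).
#' @param score_kind `"escore"` (default) or `"zscore"`.
#' @return The noise threshold, `sqrt(SSR / (n - 2)) >= 0`.
#' @export
estimate_delta <- function(rep1, rep2, bind_threshold = 0.35,
                           score_kind = c("escore", "zscore")) {
  stopifnot(inherits(rep1, "score_table"), inherits(rep2, "score_table"))
  score_kind <- match.arg(score_kind)
  col <- score_kind
  s1 <- setNames(rep1[[col]], rep1$genotype)
  s2 <- setNames(rep2[[col]], rep2$genotype)
  shared <- intersect(names(s1)[s1 > bind_threshold],
                      names(s2)[s2 > bind_threshold])
  if (length(shared) < 3L) {
    stop("fewer than 3 genotypes bound in both replicates", call. = FALSE)
  }
  fit <- lm(y ~ x, data = data.frame(x = s1[shared], y = s2[shared]))
  sqrt(sum(fit$residuals^2) / (length(shared) - 2L))
}

#' Global peak of a landscape
#'
#' The genotype with the maximum score; ties are broken lexicographically on
#' the canonical identifier (with a warning), for determinism.
#'
#' @param L A `tf_landscape`.
#' @return A single genotype string.
#' @export
global_peak <- function(L) {
  stopifnot(inherits(L, "tf_landscape"))
  L$peak
}

#' Topography summary of a landscape
#'
#' Aggregates size, mean GC content, mean degree, mean per-genotype
#' mutational robustness and whole-landscape composition bias.
#'
#' @param L A `tf_landscape`.
#' @return A one-row `data.frame`.
#' @export
landscape_summary <- function(L) {
  stopifnot(inherits(L, "tf_landscape"))
  n <- length(L$genotype)
  gc <- vapply(strsplit(L$genotype, "", fixed = TRUE),
               function(b) mean(b %in% c("G", "C")), numeric(1))
  deg <- if (nrow(L$edges)) 2 * nrow(L$edges) / n else 0
  rob <- mean(vapply(L$genotype, robustness, numeric(1), L = L))
  cb <- if (nrow(L$edges)) landscape_composition_bias(L)$value else NA_real_
  data.frame(
    tf = if (is.null(L$tf)) NA_character_ else L$tf,
    n = n,
    n_edges = nrow(L$edges),
    mean_gc = mean(gc),
    mean_degree = deg,
    mean_robustness = rob,
    composition_bias = cb,
    delta = L$delta,
    peak = L$peak,
    peak_score = unname(L$score[L$peak]),
    n_discarded_components = length(L$discarded_components),
    stringsAsFactors = FALSE
  )
}

#' @export
print.tf_landscape <- function(x, ...) {
  cat("Genotype-phenotype landscape",
      if (!is.null(x$tf)) paste0("for ", x$tf), "\n")
  cat("  genotypes: ", length(x$genotype), " (k = ", x$k, ")",
      "   edges: ", nrow(x$edges), "\n", sep = "")
  cat("  score (", x$score_kind, ") range: [",
      format(min(x$score), digits = 4), ", ",
      format(max(x$score), digits = 4), "]   delta: ",
      format(x$delta, digits = 4), "\n", sep = "")
  cat("  global peak: ", x$peak, "\n", sep = "")
  if (length(x$discarded_components)) {
    cat("  discarded components:", length(x$discarded_components),
        "(sizes", paste(head(x$discarded_components, 5L), collapse = ", "),
        if (length(x$discarded_components) > 5L) "..." else "", ")\n")
  }
  invisible(x)
}

#' @export
summary.tf_landscape <- function(object, ...) landscape_summary(object)

#' Plot a landscape's dominant genotype network
#'
#' Nodes are shaded by score (darker = higher affinity); transition edges are
#' drawn blue and transversions green.
#'
#' @param x A `tf_landscape`.
#' @param ... Passed on to [igraph::plot.igraph()].
#' @export
plot.tf_landscape <- function(x, ...) {
  g <- igraph::graph_from_data_frame(
    x$edges, directed = FALSE,
    vertices = data.frame(name = x$genotype, stringsAsFactors = FALSE))
  sc <- (x$score[x$genotype] - min(x$score)) /
    max(max(x$score) - min(x$score), .Machine$double.eps)
  plot(g,
       vertex.color = grey(1 - 0.8 * sc),
       vertex.label = NA, vertex.size = 6,
       edge.color = ifelse(x$edges$class == "transition",
                           "steelblue", "darkgreen"),
       ...)
  invisible(x)
}

#' Write a landscape as node and edge tables
#'
#' Emits `<stem>_nodes.tsv` (genotype, score) and `<stem>_edges.tsv`
#' (from, to, class), plus `<stem>_summary.json` when the jsonlite package
#' is available.
#'
#' @param L A `tf_landscape`.
#' @param stem Output path stem.
#' @return The stem, invisibly.
#' @export
write_landscape <- function(L, stem) {
  stopifnot(inherits(L, "tf_landscape"))
  utils::write.table(
    data.frame(genotype = L$genotype, score = unname(L$score[L$genotype])),
    paste0(stem, "_nodes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(L$edges, paste0(stem, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(as.list(landscape_summary(L)),
                         paste0(stem, "_summary.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(stem)
}
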