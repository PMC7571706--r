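#' Transition/transversion bias statistic
#'
#' The bias of a mutation spectrum (or of the mutation types present in a
#' landscape or path) relative to the null expectation of one transition per
#' two transversions: `Ti / (Ti + Tv/2)`. A value of 0.5 is the null; values
#' below 0.5 indicate enrichment of transversions, values above 0.5
#' enrichment of transitions. Scale-invariant, so `Ti` and `Tv` may be counts
#' or rates.
#'
#' @param ti,tv Non-negative transition and transversion counts or rates;
#'   not both zero.
#' @return A `bias_value`: list with elements `value`, `Ti`, `Tv`.
#' @examples
#' mutation_bias(1, 2)$value  # 0.5, the null spectrum
#' @export
mutation_bias <- function(ti, tv) {
  stopifnot(length(ti) == 1L, length(tv) == 1L)
  if (is.na(ti) || is.na(tv) || ti < 0 || tv < 0) {
    stop("'ti' and 'tv' must be non-negative", call. = FALSE)
  }
  if (ti == 0 && tv == 0) {
    stop("at least one of 'ti' and 'tv' must be positive", call. = FALSE)
  }
  structure(list(value = ti / (ti + tv / 2), Ti = ti, Tv = tv),
            class = "bias_value")
}

.bias_missing <- function() {
  structure(list(value = NA_real_, Ti = NA_real_, Tv = NA_real_),
            class = "bias_value")
}

#' @export
print.bias_value <- function(x, ...) {
  cat("bias = ", format(x$value, digits = 4),
      "  (Ti = ", format(x$Ti, digits = 4),
      ", Tv = ", format(x$Tv, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @export
as.double.bias_value <- function(x, ...) x$value

#' Composition bias of an entire landscape
#'
#' The bias statistic over the transition/transversion counts of all
#' undirected edges of the dominant genotype network — a property of the
#' sequences the landscape contains, independent of the mutation process.
#'
#' @param L A `tf_landscape` with at least one edge.
#' @return A `bias_value`.
#' @export
landscape_composition_bias <- function(L) {
  stopifnot(inherits(L, "tf_landscape"))
  if (!nrow(L$edges)) stop("landscape has no edges", call. = FALSE)
  ti <- sum(L$edges$class == "transition")
  mutation_bias(ti, nrow(L$edges) - ti)
}

#' Accessible-mutation graph of a landscape
#'
#' Directs each network edge toward higher affinity when the step clears the
#' noise threshold. Under the strict criterion an edge i -> j is accessible
#' iff `b_j - b_i > delta` (the resulting graph is acyclic); under the
#' relaxed criterion iff `b_j - b_i >= -delta` (steps may be neutral or
#' slightly deleterious, and cycles can occur). The start set comprises the
#' bottom fraction `q` of genotypes by score (ties resolved by score then
#' genotype, deterministically); the target is the global peak.
#'
#' @param L A `tf_landscape` (its `delta` is used).
#' @param mode `"strict"` (default) or `"relaxed"`.
#' @param q Bottom fraction defining the start set (default 0.10).
#' @return An `accessible_graph`: directed edge list with classes and score
#'   gains, start set, target, mode.
#' @export
accessible_graph <- function(L, mode = c("strict", "relaxed"), q = 0.10) {
  stopifnot(inherits(L, "tf_landscape"))
  mode <- match.arg(mode)
  n <- length(L$genotype)
  ns <- ceiling(q * n)
  if (ns < 1L) stop("empty start set (q too small)", call. = FALSE)
  ord <- order(L$score[L$genotype], L$genotype)
  starts <- L$genotype[ord][seq_len(ns)]
  s <- L$score
  e <- L$edges
  d_fwd <- s[e$to] - s[e$from]
  if (mode == "strict") {
    fwd <- d_fwd > L$delta
    bwd <- -d_fwd > L$delta
  } else {
    fwd <- d_fwd >= -L$delta
    bwd <- -d_fwd >= -L$delta
  }
  edges <- rbind(
    data.frame(from = e$from[fwd], to = e$to[fwd], class = e$class[fwd],
               gain = unname(d_fwd[fwd]), stringsAsFactors = FALSE),
    data.frame(from = e$to[bwd], to = e$from[bwd], class = e$class[bwd],
               gain = unname(-d_fwd[bwd]), stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  structure(list(edges = edges, starts = starts, target = L$peak,
                 mode = mode, q = q, delta = L$delta,
                 genotype = L$genotype, score = s,
                 tf = L$tf),
            class = "accessible_graph")
}

#' @export
print.accessible_graph <- function(x, ...) {
  cat("Accessible-mutation graph (", x$mode, "): ",
      length(x$genotype), " genotypes, ", nrow(x$edges),
      " directed edges\n", sep = "")
  cat("  starts: ", length(x$starts), " (bottom ",
      format(100 * x$q), "% by score)   target: ", x$target, "\n", sep = "")
  invisible(x)
}

.ag_graph <- function(AG) {
  igraph::graph_from_data_frame(
    AG$edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = AG$genotype, stringsAsFactors = FALSE))
}

# logical vector over AG edges: does the edge lie on >= 1 start->target path
.on_path_edges <- function(AG) {
  g <- .ag_graph(AG)
  d_from <- igraph::distances(g, v = AG$starts, mode = "out")
  reach_f <- colnames(d_from)[apply(is.finite(d_from), 2, any)]
  d_to <- igraph::distances(g, v = AG$target, mode = "in")
  reach_b <- colnames(d_to)[is.finite(d_to[1L, ])]
  AG$edges$from %in% reach_f & AG$edges$to %in% reach_b
}

#' Composition bias of accessible mutational paths to the global peak
#'
#' Under `edge_set` semantics (the default) transitions and transversions are
#' counted once per directed edge that lies on at least one start-to-peak
#' path. Under `path_weighted` semantics (strict graphs only) they are the
#' expected per-path counts under a uniform start choice and the unbiased
#' (alpha = 0.5) origin-fixation chain, conditioned on absorption at the
#' peak; the two semantics agree exactly on single-path graphs.
#'
#' @param AG An [accessible_graph()].
#' @param semantics `"edge_set"` or `"path_weighted"`.
#' @return A `bias_value`; when the peak is unreachable from every start the
#'   value is `NA` (missing, not zero).
#' @export
path_composition_bias <- function(AG, semantics = c("edge_set",
                                                    "path_weighted")) {
  stopifnot(inherits(AG, "accessible_graph"))
  semantics <- match.arg(semantics)
  if (!nrow(AG$edges)) return(.bias_missing())
  if (semantics == "edge_set") {
    on <- .on_path_edges(AG)
    if (!any(on)) return(.bias_missing())
    cls <- AG$edges$class[on]
    return(mutation_bias(sum(cls == "transition"), sum(cls == "transversion")))
  }
  if (AG$mode != "strict") {
    stop("path_weighted semantics require a strict accessible graph",
         call. = FALSE)
  }
  cnt <- .expected_edge_traversals(AG, alpha = 0.5)
  if (is.null(cnt)) return(.bias_missing())
  ti <- sum(cnt[AG$edges$class == "transition"])
  tv <- sum(cnt[AG$edges$class == "transversion"])
  if (ti + tv <= 0) return(.bias_missing())
  mutation_bias(ti, tv)
}

# Expected number of traversals of each AG edge per start->peak path, under
# the alpha-weighted origin-fixation chain restricted to AG's edges and
# conditioned on absorption at the peak. Returns NULL if unreachable.
.expected_edge_traversals <- function(AG, alpha = 0.5) {
  states <- AG$genotype
  n <- length(states)
  idx <- setNames(seq_len(n), states)
  ei <- idx[AG$edges$from]
  ej <- idx[AG$edges$to]
  w <- AG$score
  f <- w[AG$edges$to] / w[AG$edges$from] - 1
  if (any(f <= 0)) f <- pmax(f, .Machine$double.eps)  # strict => positive
  phi <- ifelse(AG$edges$class == "transition", alpha, 1 - alpha)
  wgt <- phi * f
  tot <- numeric(n)
  agg <- tapply(wgt, ei, sum)
  tot[as.integer(names(agg))] <- agg
  p <- wgt / tot[ei]
  cond <- .condition_on_peak(unname(ei), unname(ej), unname(p), n,
                             unname(idx[AG$starts]), unname(idx[AG$target]))
  if (is.null(cond)) return(NULL)
  # expected traversals of edge (i,j): nu_i * Ptilde[i,j]
  q <- cond$q
  nu <- cond$nu
  ok <- q[ei] > 0 & q[ej] > 0 & ei != unname(idx[AG$target])
  out <- numeric(length(ei))
  out[ok] <- nu[ei[ok]] * p[ok] * q[ej[ok]] / q[ei[ok]]
  out
}

#' Affinity gain per accessible step, by mutation class and distance to peak
#'
#' For each accessible edge that lies on a start-to-peak path, records the
#' percent increase in binding affinity `100 * (b_j - b_i) / b_i`, grouped by
#' mutation class and by the mutational distance of the source genotype to
#' the global peak (shortest accessible-path length).
#'
#' @param AG A strict [accessible_graph()].
#' @return `data.frame` with columns `distance`, `class`, `gain_pct` (one row
#'   per qualifying edge); empty if no edge lies on a path.
#' @export
step_gain_by_class <- function(AG) {
  stopifnot(inherits(AG, "accessible_graph"))
  if (AG$mode != "strict") {
    stop("step gains are defined for strict accessible graphs", call. = FALSE)
  }
  empty <- data.frame(distance = integer(0), class = character(0),
                      gain_pct = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(AG$edges)) return(empty)
  on <- .on_path_edges(AG)
  if (!any(on)) return(empty)
  g <- .ag_graph(AG)
  d <- igraph::distances(g, to = AG$target, mode = "out")[, 1L]
  e <- AG$edges[on, , drop = FALSE]
  data.frame(distance = as.integer(d[e$from]),
             class = e$class,
             gain_pct = 100 * e$gain / AG$score[e$from],
             row.names = NULL, stringsAsFactors = FALSE)
}
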