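.as_landscape_list <- function(landscapes) {
  if (inherits(landscapes, "tf_landscape")) landscapes <- list(landscapes)
  if (!length(landscapes)) stop("empty landscape list", call. = FALSE)
  stopifnot(all(vapply(landscapes, inherits, TRUE, "tf_landscape")))
  landscapes
}

.with_delta <- function(L, delta) {
  L$delta <- delta
  L
}

#' Ensemble composition-bias report
#'
#' One row per landscape (or per landscape and noise threshold when
#' `deltas` is given): size, GC content, degree, robustness, whole-landscape
#' composition bias and the composition bias of accessible paths to the
#' global peak.
#'
#' @param landscapes A `tf_landscape` or list of them.
#' @param mode,semantics,q Passed to [accessible_graph()] and
#'   [path_composition_bias()].
#' @param deltas Optional vector of noise thresholds to sweep (overriding
#'   each landscape's own delta).
#' @return `data.frame` with one row per (landscape, delta).
#' @export
run_bias_report <- function(landscapes, mode = "strict",
                            semantics = "edge_set", q = 0.10,
                            deltas = NULL) {
  landscapes <- .as_landscape_list(landscapes)
  rows <- lapply(landscapes, function(L) {
    dvec <- if (is.null(deltas)) L$delta else deltas
    do.call(rbind, lapply(dvec, function(d) {
      Ld <- .with_delta(L, d)
      base <- landscape_summary(Ld)
      pb <- path_composition_bias(accessible_graph(Ld, mode = mode, q = q),
                                  semantics = semantics)
      cbind(base,
            data.frame(mode = mode, semantics = semantics,
                       path_bias = pb$value, path_Ti = pb$Ti,
                       path_Tv = pb$Tv, stringsAsFactors = FALSE))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ensemble navigability sweep
#'
#' Evaluates `P_peak` on the mutation-bias grid for each landscape.
#'
#' @param landscapes A `tf_landscape` or list of them.
#' @param grid Alpha grid (default 19 values in \[0.05, 0.95\]).
#' @param t Steps (default 1000).
#' @param ... Passed to [fixation_chain()].
#' @return `data.frame` (tf, alpha, p_peak) with a per-landscape `summary`
#'   attribute giving the alpha maximising `P_peak`.
#' @export
run_navigability <- function(landscapes,
                             grid = seq(0.05, 0.95, length.out = 19),
                             t = 1000, ...) {
  landscapes <- .as_landscape_list(landscapes)
  sweeps <- lapply(landscapes, alpha_sweep, grid = grid, t = t,
                   entropy = FALSE, ...)
  out <- do.call(rbind, lapply(seq_along(sweeps), function(i) {
    data.frame(tf = landscapes[[i]]$tf %||% paste0("landscape", i),
               alpha = sweeps[[i]]$alpha, p_peak = sweeps[[i]]$p_peak,
               stringsAsFactors = FALSE)
  }))
  smry <- do.call(rbind, lapply(seq_along(sweeps), function(i) {
    s <- attr(sweeps[[i]], "summary")
    data.frame(tf = landscapes[[i]]$tf %||% paste0("landscape", i),
               alpha_max_ppeak = s$alpha_max_ppeak,
               stringsAsFactors = FALSE)
  }))
  structure(out, summary = smry)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ensemble predictability (path entropy) sweep
#'
#' Evaluates path entropy on the mutation-bias grid for each landscape and
#' summarises the entropy-minimising and -maximising alphas and the
#' relative entropy changes against the unbiased supply.
#'
#' @inheritParams run_navigability
#' @return `data.frame` (tf, alpha, entropy) with a per-landscape `summary`
#'   attribute (alpha_min_entropy, alpha_max_entropy, entropy ratios).
#' @export
run_predictability <- function(landscapes,
                               grid = seq(0.05, 0.95, length.out = 19),
                               t = 1000, ...) {
  landscapes <- .as_landscape_list(landscapes)
  sweeps <- lapply(landscapes, alpha_sweep, grid = grid, t = t,
                   entropy = TRUE, ...)
  out <- do.call(rbind, lapply(seq_along(sweeps), function(i) {
    data.frame(tf = landscapes[[i]]$tf %||% paste0("landscape", i),
               alpha = sweeps[[i]]$alpha, entropy = sweeps[[i]]$entropy,
               stringsAsFactors = FALSE)
  }))
  smry <- do.call(rbind, lapply(seq_along(sweeps), function(i) {
    s <- attr(sweeps[[i]], "summary")
    data.frame(tf = landscapes[[i]]$tf %||% paste0("landscape", i),
               alpha_min_entropy = s$alpha_min_entropy,
               alpha_max_entropy = s$alpha_max_entropy,
               entropy_no_bias = s$entropy_no_bias,
               entropy_ratio_min = s$entropy_ratio_min,
               entropy_ratio_max = s$entropy_ratio_max,
               stringsAsFactors = FALSE)
  }))
  structure(out, summary = smry)
}

#' Wright-Fisher experiment grid
#'
#' Runs the replicate-by-initial-condition-by-alpha grid of Wright-Fisher
#' simulations on one landscape. Replicate r of every (initial condition,
#' alpha) cell is seeded with `seed + 1000 * initial-condition index + r`,
#' so runs differing only in alpha share their random stream — the design
#' that lets replicate variation be compared against mutation-bias
#' variation.
#'
#' @param L A `tf_landscape`.
#' @param N Population size (default 1000).
#' @param Nmu Mutation supply values; `mu = Nmu / N` (default c(5, 20, 50)).
#' @param alphas Mutation-bias values (default the 19-value grid).
#' @param replicates Replicates per cell (default 15).
#' @param n_initial Number of initial conditions drawn from the bottom-10%
#'   start set (default 10).
#' @param generations Generations per run (default 1000).
#' @param seed Base seed (default 1).
#' @param keep_populations Attach the final count vectors as a list
#'   attribute `populations` (default `FALSE`).
#' @return `data.frame` with one row per run: Nmu, alpha, initial condition,
#'   replicate, seed, final diversity, nucleotide diversity, mean
#'   robustness, final peak fraction, steady-state generation.
#' @export
run_wf_suite <- function(L, N = 1000, Nmu = c(5, 20, 50),
                         alphas = seq(0.05, 0.95, length.out = 19),
                         replicates = 15, n_initial = 10,
                         generations = 1000, seed = 1,
                         keep_populations = FALSE) {
  stopifnot(inherits(L, "tf_landscape"))
  n <- length(L$genotype)
  ord <- order(L$score[L$genotype], L$genotype)
  starts <- L$genotype[ord][seq_len(ceiling(0.1 * n))]
  inits <- .with_seed(seed, {
    starts[sample.int(length(starts), min(n_initial, length(starts)),
                      replace = n_initial > length(starts))]
  })
  grid <- expand.grid(rep = seq_len(replicates),
                      init = seq_along(inits),
                      alpha = alphas, Nmu = Nmu,
                      KEEP.OUT.ATTRS = FALSE)
  pops <- if (keep_populations) vector("list", nrow(grid)) else NULL
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gr <- grid[i, ]
    run_seed <- seed + 1000L * gr$init + gr$rep
    sim <- wf_simulate(L, N = N, mu = gr$Nmu / N, alpha = gr$alpha,
                       generations = generations,
                       initial = inits[gr$init], seed = run_seed)
    rows[[i]] <- data.frame(
      tf = L$tf %||% "landscape", Nmu = gr$Nmu, mu = gr$Nmu / N,
      alpha = gr$alpha, init = inits[gr$init], replicate = gr$rep,
      seed = run_seed,
      diversity = sim$diversity[length(sim$diversity)],
      pi = nucleotide_diversity(sim),
      robustness = population_robustness(sim, L),
      peak_fraction = sim$peak_frac[length(sim$peak_frac)],
      reached_peak = sim$peak_frac[length(sim$peak_frac)] >= 0.5,
      steady_generation = steady_state_reached(sim),
      stringsAsFactors = FALSE)
    if (keep_populations) pops[[i]] <- .as_counts(sim)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_populations) attr(out, "populations") <- pops
  out
}
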