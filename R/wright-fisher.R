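# Per-genotype mutation targets: for each landscape genotype, its 3k
# single-base alternatives (on the stored strand), the class of each slot
# and the landscape index of the canonical mutant (0 when it leaves the
# bound set). Every genotype has k transition slots and 2k transversion
# slots, so P(transition | mutation) = alpha / (2 - alpha).
.mutation_table <- function(L) {
  n <- length(L$genotype)
  k <- L$k
  idx <- setNames(seq_len(n), L$genotype)
  targets <- matrix("", n, 3L * k)
  is_ti <- matrix(FALSE, n, 3L * k)
  land <- matrix(0L, n, 3L * k)
  for (g in seq_len(n)) {
    b <- strsplit(L$genotype[g], "", fixed = TRUE)[[1]]
    slot <- 0L
    for (p in seq_len(k)) {
      for (nb in .BASES[.BASES != b[p]]) {
        slot <- slot + 1L
        m <- b
        m[p] <- nb
        cg <- canonical_genotype(paste(m, collapse = ""))
        targets[g, slot] <- cg
        is_ti[g, slot] <- .TI_PARTNER[[b[p]]] == nb
        hit <- idx[cg]
        land[g, slot] <- if (is.na(hit)) 0L else unname(hit)
      }
    }
  }
  list(targets = targets, is_ti = is_ti, land = land, k = k)
}

#' Wright-Fisher simulation with biased mutation
#'
#' High mutation supply (N*mu > 1): a population of `N` sequences evolves on
#' the landscape by, each generation, (i) multinomial resampling of `N`
#' individuals with probability linearly proportional to binding affinity,
#' then (ii) mutation of each individual with probability `mu`. A mutating
#' sequence picks one of its 3k single-base alternatives with per-slot
#' weight `alpha` (the transition at that position) or `1 - alpha` (each of
#' the two transversions), so the proportion of transitions among proposed
#' mutations is `alpha / (2 - alpha)` — 1/3 at the unbiased supply, matching
#' one transition per two transversions. Mutants that leave the bound set
#' either stay in the population with fitness 0 (`"lethal"`, the default:
#' produced but never selected) or the mutation is discarded (`"rejected"`).
#'
#' @param L A `tf_landscape`.
#' @param N Population size (default 10^4).
#' @param mu Per-sequence per-generation mutation probability.
#' @param alpha Mutation bias in (0, 1).
#' @param generations Number of generations (default 1000).
#' @param initial Initial genotype; default a random member of the
#'   bottom-10% start set. Must be in the landscape.
#' @param seed Integer seed; a fixed seed makes the trajectory
#'   bit-reproducible. The caller's RNG stream is left untouched.
#' @param off_landscape `"lethal"` or `"rejected"` (see above).
#' @return A `wf_sim`: final counts over landscape genotypes, counts of
#'   off-landscape mutants, the normalized-diversity and peak-fraction
#'   traces (generations 0..`generations`), and tallies of proposed
#'   transition/transversion mutations.
#' @export
wf_simulate <- function(L, N = 1e4, mu, alpha, generations = 1000,
                        initial = NULL, seed = NULL,
                        off_landscape = c("lethal", "rejected")) {
  stopifnot(inherits(L, "tf_landscape"), N >= 1, mu >= 0, mu <= 1,
            alpha > 0, alpha < 1, generations >= 0)
  off_landscape <- match.arg(off_landscape)
  .with_seed(seed, {
    n <- length(L$genotype)
    b <- unname(L$score[L$genotype])
    if (any(b <= 0)) stop("binding scores must be positive for ",
                          "affinity-proportional selection", call. = FALSE)
    mt <- .mutation_table(L)
    k <- mt$k
    # cumulative slot weights per genotype; row totals all equal k*(2-alpha)
    cwm <- t(apply(ifelse(mt$is_ti, alpha, 1 - alpha), 1, cumsum))
    total_w <- k * (2 - alpha)
    if (is.null(initial)) {
      ord <- order(b, L$genotype)
      starts <- L$genotype[ord][seq_len(ceiling(0.1 * n))]
      initial <- sample(starts, 1L)
    }
    g0 <- match(initial, L$genotype)
    if (is.na(g0)) stop("initial genotype not in landscape", call. = FALSE)

    counts <- integer(n)
    counts[g0] <- as.integer(N)
    off <- new.env(parent = emptyenv())  # off-landscape genotype -> count
    peak_idx <- match(L$peak, L$genotype)
    ti_events <- 0L; tv_events <- 0L
    diversity <- numeric(generations + 1L)
    peak_frac <- numeric(generations + 1L)
    record <- function(gen) {
      offc <- unlist(as.list(off), use.names = FALSE)
      p <- c(counts[counts > 0L], offc) / N
      diversity[gen + 1L] <<- if (n >= 2) -sum(p * log2(p)) / log2(n) else 0
      peak_frac[gen + 1L] <<- counts[peak_idx] / N
    }
    record(0L)

    for (gen in seq_len(generations)) {
      # selection: off-landscape individuals have fitness 0 and vanish here
      wsel <- counts * b
      if (sum(wsel) <= 0) stop("population extinct (no bound individuals)",
                               call. = FALSE)
      counts <- as.integer(rmultinom(1L, N, wsel))
      if (length(ls(off))) rm(list = ls(off), envir = off)
      # mutation: Bernoulli(mu) per sequence, at most one substitution
      nm <- rbinom(1L, N, mu)
      if (nm > 0L) {
        cum <- cumsum(counts)
        who <- findInterval(sample.int(N, nm) - 1L, cum) + 1L
        u <- runif(nm) * total_w
        for (e in seq_len(nm)) {
          g <- who[e]
          slot <- findInterval(u[e], cwm[g, ], left.open = TRUE) + 1L
          if (mt$is_ti[g, slot]) ti_events <- ti_events + 1L
          else tv_events <- tv_events + 1L
          tgt <- mt$land[g, slot]
          if (tgt > 0L) {
            counts[g] <- counts[g] - 1L
            counts[tgt] <- counts[tgt] + 1L
          } else if (off_landscape == "lethal") {
            counts[g] <- counts[g] - 1L
            nm_str <- mt$targets[g, slot]
            prev <- get0(nm_str, envir = off, ifnotfound = 0L)
            assign(nm_str, prev + 1L, envir = off)
          }  # "rejected": the sequence keeps its genotype
        }
      }
      record(gen)
    }

    offc <- unlist(as.list(off))
    structure(list(
      counts = setNames(counts, L$genotype),
      off_counts = if (is.null(offc)) integer(0) else offc,
      N = as.integer(N), generations = generations,
      diversity = diversity, peak_frac = peak_frac,
      ti_events = ti_events, tv_events = tv_events,
      alpha = alpha, mu = mu, seed = seed, initial = initial,
      off_landscape = off_landscape,
      peak = L$peak, landscape_n = n, tf = L$tf
    ), class = "wf_sim")
  })
}

#' @export
print.wf_sim <- function(x, ...) {
  cat("Wright-Fisher run: N = ", x$N, ", mu = ", format(x$mu),
      ", alpha = ", format(x$alpha), ", ", x$generations,
      " generations\n", sep = "")
  cat("  final peak fraction: ",
      format(x$peak_frac[length(x$peak_frac)], digits = 4),
      "   final diversity: ",
      format(x$diversity[length(x$diversity)], digits = 4), "\n", sep = "")
  cat("  proposed mutations: ", x$ti_events, " transitions, ",
      x$tv_events, " transversions\n", sep = "")
  invisible(x)
}

#' Simulate Wright-Fisher replicates on a landscape
#'
#' `simulate()` method for landscapes: runs `nsim` replicate Wright-Fisher
#' simulations, seeding replicate `r` with `seed + r - 1` so replicates are
#' individually reproducible.
#'
#' @param object A `tf_landscape`.
#' @param nsim Number of replicates.
#' @param seed Base seed (replicate r uses `seed + r - 1`); `NULL` leaves
#'   the RNG stream as is.
#' @param ... Passed to [wf_simulate()] (`N`, `mu`, `alpha`, ...).
#' @return A list of `wf_sim` objects.
#' @export
simulate.tf_landscape <- function(object, nsim = 1, seed = NULL, ...) {
  lapply(seq_len(nsim), function(r) {
    wf_simulate(object, seed = if (is.null(seed)) NULL else seed + r - 1L, ...)
  })
}

#' Navigability under high mutation supply
#'
#' The fraction of completed runs whose final population has at least half
#' of its individuals at the global peak.
#'
#' @param sims A list of `wf_sim` objects (or a single one).
#' @return Fraction in \[0, 1\].
#' @export
p_peak_wf <- function(sims) {
  if (inherits(sims, "wf_sim")) sims <- list(sims)
  stopifnot(length(sims) >= 1, all(vapply(sims, inherits, TRUE, "wf_sim")))
  mean(vapply(sims, function(s) {
    s$counts[[s$peak]] >= s$N / 2
  }, logical(1)))
}

#' First generation at which a diversity trace has reached steady state
#'
#' Scans a recorded diversity trajectory for the first generation after
#' which every value stays within a relative tolerance of the final value.
#'
#' @param trace Numeric vector of diversity values for generations
#'   0, 1, ..., or a `wf_sim` (its diversity trace is used).
#' @param tol Relative tolerance (default 1e-4, i.e. 0.01% of the final
#'   level).
#' @return Generation index (0-based).
#' @export
steady_state_reached <- function(trace, tol = 1e-4) {
  if (inherits(trace, "wf_sim")) trace <- trace$diversity
  stopifnot(is.numeric(trace), length(trace) >= 1)
  final <- trace[length(trace)]
  ok <- abs(trace - final) <= tol * abs(final)
  bad <- which(!ok)
  if (!length(bad)) return(0L)
  max(bad)  # trace index max(bad)+1 is first inside; 0-based => max(bad)
}
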