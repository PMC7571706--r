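# Independent oracles used across test files. These deliberately use
# different algorithms from the package internals (dense matrices, explicit
# enumeration, closed forms) so the two routes can disagree.

# Brute-force canonical enumeration: canonicalise all 4^k strings directly.
brute_force_genotypes <- function(k) {
  seqs <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                      stringsAsFactors = FALSE))
  sort(unique(canonical_genotype(seqs)))
}

# Enumerate every start->peak path of a fixation chain by depth-first
# search over the raw (unconditioned) jump matrix, and return the entropy
# of the path distribution conditioned on absorption at the peak, plus the
# path probabilities themselves.
enumerate_path_entropy <- function(M, log_base = 2) {
  P <- as.matrix(M$P)
  n <- length(M$states)
  peak <- M$peak_idx
  starts <- match(M$starts, M$states)
  probs <- numeric(0)
  walk <- function(i, pr) {
    if (i == peak) {
      probs[length(probs) + 1L] <<- pr
      return(invisible())
    }
    nxt <- which(P[i, ] > 0)
    nxt <- nxt[nxt != i]
    for (j in nxt) walk(j, pr * P[i, j])
  }
  for (s in starts) walk(s, 1 / length(starts))
  if (!length(probs)) return(NULL)
  p <- probs / sum(probs)
  list(entropy = -sum(p * log(p)) / log(log_base), n_paths = length(p),
       mass = sum(probs))
}

# Monte-Carlo origin-fixation walkers: simulate `n_walkers` independent
# jump-chain trajectories for `t` steps and return the fraction absorbed at
# the peak plus its binomial standard error.
mc_p_peak <- function(M, t = 100, n_walkers = 1e5, seed = 1) {
  P <- as.matrix(M$P)
  n <- length(M$states)
  starts <- match(M$starts, M$states)
  withr::with_seed(seed, {
    state <- sample(starts, n_walkers, replace = TRUE)
    cum <- t(apply(P, 1, cumsum))
    for (step in seq_len(t)) {
      moving <- which(!M$absorbing[state])
      if (!length(moving)) break
      u <- runif(length(moving))
      state[moving] <- vapply(seq_along(moving), function(ii) {
        findInterval(u[ii], cum[state[moving[ii]], ], left.open = TRUE) + 1L
      }, integer(1))
    }
    phat <- mean(state == M$peak_idx)
    list(p = phat, se = sqrt(phat * (1 - phat) / n_walkers))
  })
}

# Random small landscape over k = 3 genotype space: picks a connected
# induced subgraph of <= n_max canonical 3-mers and assigns random scores.
# Used to generate many acyclic chains for the entropy equivalence check.
random_small_landscape <- function(seed, n_max = 15, delta = 0.005) {
  withr::with_seed(seed, {
    geno <- enumerate_genotypes(3)
    start <- sample(geno, 1)
    sel <- start
    frontier <- start
    while (length(sel) < n_max && length(frontier)) {
      nb <- unique(unlist(lapply(frontier,
                                 function(g) genotype_neighbors(g)$genotype)))
      nb <- setdiff(nb, sel)
      if (!length(nb)) break
      take <- sample(nb, min(length(nb), n_max - length(sel)))
      sel <- c(sel, take)
      frontier <- take
    }
    tab <- score_table(sel, runif(length(sel), 0.36, 0.5))
    build_landscape(tab, min_component = 1, delta = delta)
  })
}
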