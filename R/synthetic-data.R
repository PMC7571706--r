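# Integer-coded base matrices (stored orientation and reverse complement)
# for the canonical genotype set of length k; cached per k.
.genotype_mats <- function(k) {
  key <- paste0("mats", k)
  cached <- .genotype_cache[[key]]
  if (!is.null(cached)) return(cached)
  geno <- enumerate_genotypes(k)
  split_int <- function(x) {
    m <- matrix(unlist(strsplit(x, "", fixed = TRUE)), ncol = k, byrow = TRUE)
    matrix(match(m, .BASES), ncol = k)
  }
  out <- list(geno = geno, fwd = split_int(geno), rc = split_int(revcomp(geno)))
  .genotype_cache[[key]] <- out
  out
}

#' Configuration for the synthetic landscape generator
#'
#' Describes a synthetic protein-binding-microarray experiment: a full
#' k-mer score table plus a noisy replicate. `gc_skew` steers the base
#' composition of the bound set and thereby its composition bias: at -1 the
#' peak region is A/T-only and the cheap substitutions are A<->T
#' transversions (composition bias well below 0.5); at +1 the peak is G/C
#' rich and the cheap substitutions are transitions (G<->A, C<->T), giving
#' composition bias above 0.5; 0 is neutral. `target_bound_size` sets the
#' size of the dominant genotype network; `noise_sd` the replicate
#' measurement noise; `n_local_optima` the landscape ruggedness (number of
#' seeded secondary peaks). The configuration plus seed fully determine the
#' output.
#'
#' @param k Sequence length (default 8).
#' @param gc_skew Composition steering in \[-1, 1\] (default 0).
#' @param target_bound_size Minimum size of the dominant component
#'   (default 150).
#' @param noise_sd Gaussian noise sd added to replicate 2 (default 0.01).
#' @param n_local_optima Number of seeded local optima (default 6, a
#'   realistically rugged landscape; 0 gives a smooth single-peak funnel).
#' @param jitter_sd Small score jitter shared by both replicates
#'   (default 0.005).
#' @param seed Integer seed (default 1).
#' @param tf_name Optional name; a descriptive default is generated.
#' @return A `synth_config` list.
#' @export
synth_config <- function(k = 8, gc_skew = 0, target_bound_size = 150,
                         noise_sd = 0.01, n_local_optima = 6,
                         jitter_sd = 0.005, seed = 1, tf_name = NULL) {
  stopifnot(k >= 2, k == as.integer(k),
            gc_skew >= -1, gc_skew <= 1,
            target_bound_size >= 3, noise_sd >= 0, jitter_sd >= 0,
            n_local_optima >= 0)
  if (is.null(tf_name)) {
    tf_name <- sprintf("synth_gc%+.1f_s%d", gc_skew, seed)
  }
  structure(list(k = as.integer(k), gc_skew = gc_skew,
                 target_bound_size = as.integer(target_bound_size),
                 noise_sd = noise_sd,
                 n_local_optima = as.integer(n_local_optima),
                 jitter_sd = jitter_sd, seed = as.integer(seed),
                 tf_name = tf_name),
            class = "synth_config")
}

# per-position substitution cost relative to a peak base, as a 4x4 matrix
# (row: peak base code, col: candidate base code). gc_skew tilts the cheap
# deviation between the within-pair transversion (A<->T, C<->G) and the
# transition partner: negative skew makes within-pair transversions cheap
# (with an A/T-rich peak this yields a transversion-dominated, low-GC bound
# set), positive skew makes transitions cheap (transition-dominated paths,
# GC-balanced composition). The contrast is moderate so the expensive class
# still appears in the bound set and mutation bias has purchase.
.cost_matrix <- function(gc_skew) {
  m_ti <- 2 - 0.7 * gc_skew    # transition partner
  m_tv1 <- 2 + 0.7 * gc_skew   # A<->T or C<->G transversion
  # the remaining transversions change both the pairing partner and the
  # purine/pyrimidine attribute; they are the most disruptive substitutions
  # and effectively abolish binding
  m_tv2 <- 9
  C <- matrix(m_tv2, 4, 4, dimnames = list(.BASES, .BASES))
  diag(C) <- 0
  for (b in .BASES) C[b, .TI_PARTNER[[b]]] <- m_ti
  C["A", "T"] <- C["T", "A"] <- m_tv1
  C["C", "G"] <- C["G", "C"] <- m_tv1
  C
}

# additive penalty of every canonical genotype against a peak sequence,
# minimised over strand orientation
.peak_penalty <- function(mats, peak_codes, C) {
  n <- nrow(mats$fwd)
  pf <- numeric(n); pr <- numeric(n)
  for (pos in seq_along(peak_codes)) {
    crow <- C[peak_codes[pos], ]
    pf <- pf + crow[mats$fwd[, pos]]
    pr <- pr + crow[mats$rc[, pos]]
  }
  pmin(pf, pr)
}

#' Generate a synthetic landscape as a pair of replicate score tables
#'
#' Builds a full k-mer E-score table from a smooth additive score field: a
#' peak sequence (base composition set by `gc_skew`) defines per-position
#' substitution costs, the score decays linearly in total cost, optional
#' secondary peaks add ruggedness, and a small shared jitter roughens the
#' surface. Scores are calibrated so the dominant component of the
#' thresholded table reaches `target_bound_size` (the calibration is
#' re-tried with a wider bound region a bounded number of times). Replicate
#' 2 equals replicate 1 plus Gaussian noise of sd `noise_sd`, exercising
#' the noise-threshold estimation. Bound scores lie in (0.35, 0.5\];
#' identical configuration and seed give byte-identical tables.
#'
#' @param cfg A [synth_config()].
#' @return List with elements `rep1` and `rep2`, both [score_table()]s.
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  mats <- .genotype_mats(cfg$k)
  n <- length(mats$geno)
  C <- .cost_matrix(cfg$gc_skew)
  .with_seed(cfg$seed, {
    # peak base composition: strongly A/T-rich at negative skew (A/T-only
    # at -1), but only moderately G/C-enriched at positive skew --
    # transition-dominated factors bind GC-balanced, not GC-pure, motifs
    p_gc <- (1 + min(cfg$gc_skew, 0) + 0.4 * max(cfg$gc_skew, 0)) / 2
    # within each pair the purine is strongly preferred, giving a
    # strand-asymmetric (purine-rich) motif; near-palindromic peaks would
    # let strand canonicalisation open spurious within-pair shortcut routes
    peak_codes <- vapply(seq_len(cfg$k), function(i) {
      if (runif(1) < p_gc) {
        if (runif(1) < 0.9) 3L else 2L   # G over C
      } else {
        if (runif(1) < 0.9) 1L else 4L   # A over T
      }
    }, integer(1))
    pen0 <- .peak_penalty(mats, peak_codes, C)
    peak_idx <- which.min(pen0)[1L]
    jitter <- rnorm(n, 0, cfg$jitter_sd)
    noise <- rnorm(n, 0, cfg$noise_sd)
    sorted_pen <- sort(pen0[pen0 > 0])
    score <- NULL
    for (margin in c(1.3, 1.8, 2.5, 3.5, 5, 7, 10, 14)) {
      m_star <- min(length(sorted_pen), ceiling(cfg$target_bound_size * margin))
      pcut <- sorted_pen[m_star]
      scale <- 0.15 / pcut
      sc <- 0.5 - scale * pen0
      if (cfg$n_local_optima > 0) {
        # Secondary optima model alternative binding modes that recognise
        # variant motifs: each centre is the primary motif with a few
        # substitutions of the class the primary mode disfavours, and its
        # basin makes exactly that class cheap. Mutational paths into a
        # secondary optimum are therefore enriched for the class that is
        # rare on paths to the global peak -- the empirical situation, where
        # whole-landscape class mixtures sit near the null while
        # accessible-path mixtures are strongly skewed.
        ti_part <- c(3L, 4L, 1L, 2L)   # A<->G, C<->T
        wc_part <- c(4L, 3L, 2L, 1L)   # A<->T, C<->G
        C_alt <- .cost_matrix(-cfg$gc_skew)
        for (oi in seq_len(cfg$n_local_optima)) {
          # centres sit far from the global peak (several disfavoured-class
          # substitutions), so a low-score moat separates their basin from
          # the peak's core and the optimum genuinely absorbs
          centre <- peak_codes
          n_disp <- min(cfg$k - 2L, sample(4:6, 1))
          pos <- sample.int(cfg$k, n_disp)
          part <- if (cfg$gc_skew < 0) ti_part
                  else if (cfg$gc_skew > 0) wc_part
                  else if (runif(1) < 0.5) ti_part else wc_part
          centre[pos] <- part[centre[pos]]
          h <- runif(1, 0.43, 0.48)
          steep <- scale * runif(1, 0.8, 1.3)
          pen_c <- .peak_penalty(mats, centre, C_alt)
          sc <- pmax(sc, h - steep * pen_c)
        }
      }
      sc <- pmin(pmax(sc + jitter, -0.5), 0.499)
      sc[peak_idx] <- 0.5
      tab <- score_table(mats$geno, sc, tf_name = cfg$tf_name,
                        replicate_id = 1L)
      size <- tryCatch(
        length(build_landscape(tab, min_component = 1)$genotype),
        error = function(e) 0L)
      if (size >= cfg$target_bound_size) {
        score <- sc
        break
      }
    }
    if (is.null(score)) {
      stop("could not reach target bound-set size within the retry budget",
           call. = FALSE)
    }
    rep1 <- score_table(mats$geno, score, tf_name = cfg$tf_name,
                        replicate_id = 1L)
    rep2 <- score_table(mats$geno, pmin(pmax(score + noise, -0.5), 0.5),
                        tf_name = cfg$tf_name, replicate_id = 2L)
    list(rep1 = rep1, rep2 = rep2)
  })
}

#' Generate and build a synthetic landscape in one step
#'
#' Runs [generate_landscape()], estimates the noise threshold from the two
#' replicates (0 when `noise_sd` is 0), and builds the dominant genotype
#' network from replicate 1.
#'
#' @param cfg A [synth_config()].
#' @param min_component Passed to [build_landscape()]; defaults to the
#'   smaller of 100 and the configured bound-set size.
#' @return A `tf_landscape`.
#' @export
synth_landscape <- function(cfg, min_component = NULL) {
  reps <- generate_landscape(cfg)
  if (is.null(min_component)) {
    min_component <- min(100L, cfg$target_bound_size)
  }
  delta <- if (cfg$noise_sd > 0) {
    estimate_delta(reps$rep1, reps$rep2)
  } else 0
  build_landscape(reps$rep1, min_component = min_component, delta = delta)
}

#' Generate a collection of landscapes over the same genotype space
#'
#' Member i uses the template configuration with seed `seed + i - 1` and a
#' member-specific name, producing partially overlapping bound sets —
#' suitable for evolvability analyses across factors.
#'
#' @param m Number of landscapes (>= 2).
#' @param cfg Template [synth_config()].
#' @return List of `tf_landscape`s.
#' @export
generate_collection <- function(m, cfg) {
  stopifnot(m >= 2, inherits(cfg, "synth_config"))
  lapply(seq_len(m), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1L
    cfg_i$tf_name <- sprintf("%s_m%02d", cfg$tf_name, i)
    synth_landscape(cfg_i)
  })
}

# registry of hand-built toy landscapes with exactly known paths and classes
.TOY_REGISTRY <- list(
  # 5-step staircase to the peak: four transversions then one transition,
  # so the composition bias of its single accessible path is 1/3
  single_path = list(
    genotype = c("AAAAAAAA", "CAAAAAAA", "CCAAAAAA", "CCCAAAAA",
                 "CCCCAAAA", "CCCCGAAA"),
    score = c(0.36, 0.38, 0.40, 0.42, 0.44, 0.46),
    delta = 0.01),
  # three accessible routes to the peak: two all-transition 2-step paths
  # and one 3-step path entered by a transversion; the near-tie between
  # 0.435 and 0.44 and the exact tie at 0.40 block the cross edges
  three_paths = list(
    genotype = c("AAAAAAAA", "CAAAAAAA", "CGAAAAAA", "GAAAAAAA",
                 "AGAAAAAA", "GGAAAAAA"),
    score = c(0.36, 0.40, 0.44, 0.40, 0.435, 0.48),
    delta = 0.01),
  # a single start with an improving transition (f = 0.1) and an improving
  # transversion (f = 0.3) leading to a local and the global peak
  fork = list(
    genotype = c("AAAAAAAA", "AGAAAAAA", "CAAAAAAA"),
    score = c(0.38, 0.418, 0.494),
    delta = 0.01),
  # start adjacent to a local peak (transition) and to the route toward the
  # global peak (transversion); absorption at the local peak is positive
  # for every alpha, so P_peak < 1 throughout
  two_peaks = list(
    genotype = c("AAAAAAAA", "AGAAAAAA", "CAAAAAAA", "CAGAAAAA"),
    score = c(0.38, 0.45, 0.42, 0.49),
    delta = 0.01),
  # two internally disjoint 4-step routes to the peak, one all-transition
  # and one all-transversion, giving edge-set path bias 4/(4+2) = 2/3
  twin_paths = list(
    genotype = c("ACAAAAAA", "ACGAAAAA", "GCGAAAAA", "GTGAAAAA",
                 "AGAAAAAA", "CGAAAAAA", "CTAAAAAA", "GTAAAAAA"),
    score = c(0.36, 0.38, 0.40, 0.42, 0.38, 0.40, 0.42, 0.50),
    delta = 0.01)
)

#' Hand-built toy landscapes with exactly known structure
#'
#' Small landscapes whose accessible paths, mutation classes and scores are
#' known by construction, used for exact checks of path statistics and
#' chain dynamics. Available fixtures: `"single_path"`, `"three_paths"`,
#' `"fork"`, `"two_peaks"`, `"twin_paths"`.
#'
#' @param name Fixture name.
#' @return A `tf_landscape`.
#' @export
toy_fixture <- function(name) {
  spec <- .TOY_REGISTRY[[name]]
  if (is.null(spec)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.TOY_REGISTRY), collapse = ", "), call. = FALSE)
  }
  tab <- score_table(spec$genotype, spec$score, tf_name = name)
  build_landscape(tab, min_component = 1, delta = spec$delta)
}
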