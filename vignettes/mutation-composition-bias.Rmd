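---
title: "Mutation bias on binding-affinity landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation bias on binding-affinity landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfscape)
```

## The scientific problem

A transcription factor binds short DNA sites with graded affinity. Because
binding sites are short (here, 8 bp), the affinity of *every* possible site
can be measured on protein-binding microarrays, giving a complete
genotype-phenotype landscape: nodes are double-stranded 8-mers bound by the
factor (E-score > 0.35), edges connect sites differing by one point
mutation, and the surface is relative affinity. Adaptive evolution of
stronger binding is hill climbing on this landscape.

Mutation is not uniform: transitions (A&#8596;G, C&#8596;T) typically occur
at different rates than transversions (the other eight changes). tfscape
quantifies both biases on the same unit scale,

$$\alpha \;=\; \frac{Ti}{Ti + Tv/2},$$

where $Ti$ and $Tv$ are transition and transversion rates (mutation bias)
or counts (composition bias). The null spectrum of one transition per two
transversions gives $\alpha = 0.5$; smaller values mean transversion
enrichment. A landscape has a *composition bias*: the sequences it happens
to contain fix which classes of mutation are even possible along
affinity-increasing ("accessible") paths, independent of the mutation
process. The package's purpose is to quantify how the two biases interact
to shape navigability (the chance of reaching the global peak),
predictability (path entropy), and the diversity, robustness and
evolvability of evolved populations, under low and high mutation supply.

## Genotype identity and neighbourhoods

A binding site and its reverse complement are one molecule. All functions
work on canonical genotypes — the lexicographic minimum of the two strands
— so the k = 8 space has $(4^8 - 4^4)/2 + 4^4 = 32{,}896$ genotypes.
Mutation classification is complement-invariant, so edge classes are well
defined on double-stranded identities. Palindromic sites have 12 rather
than 24 distinct neighbours because complementary mutants coalesce;
robustness denominators use the actual neighbourhood size.

## Landscape construction and the noise threshold

`build_landscape()` applies the binding threshold (E-score > 0.35, strict),
connects Hamming-1 canonical pairs, and keeps the largest connected
component (the dominant genotype network), recording discarded component
sizes. Affinity differences smaller than the measurement noise are not
trusted: `estimate_delta()` regresses replicate 2 scores on replicate 1
scores over the sites bound in both replicates and uses the residual
standard error as the per-factor noise threshold $\delta$. The regression
orientation (replicate 2 on replicate 1) and the both-replicates bound-set
rule are conventions fixed here; OLS is not symmetric and the source data
conventions are not self-describing. Ties at the global peak are broken
lexicographically (with a warning) so every run is deterministic.

A mutation is *accessible* when it increases affinity by more than
$\delta$ (strict criterion; the resulting directed graph is acyclic), or —
under the relaxed criterion — when it does not decrease affinity by more
than $\delta$. Start sets are the bottom 10% of sites by affinity
(`q = 0.10`), with ties resolved by score then identifier.

Path composition bias supports two counting semantics because either could
underlie an ensemble distribution over paths: `edge_set` (default) counts
each directed edge lying on at least one start-to-peak path once;
`path_weighted` weights edges by their expected traversals under the
unbiased origin-fixation chain conditioned on reaching the peak. They
agree exactly on single-path landscapes; `edge_set` is cheaper and free of
model assumptions, which is why it is the default.

## Origin-fixation dynamics (low mutation supply)

With $N\mu \ll 1$ the population is monomorphic between fixations and
evolution is a Markov jump chain: from site $i$, the probability of fixing
neighbour $j$ is

$$P_{ij} = \frac{\varphi_{ij} f_{ij}}{\sum_k \varphi_{ik} f_{ik}}, \qquad
  f_{ij} = \max\!\left(w_j/w_i - 1,\, 0\right),$$

with $\varphi_{ij} = \alpha$ on transition edges and $1-\alpha$ on
transversion edges. Fitness $w$ is the E-score itself (`linear`, the
default) or a Gaussian preference
$\exp\!\big(-((b - E_{opt})/\sigma)^2\big)$ with defaults
$E_{opt} = 0.35$, $\sigma = 0.1$, which models selection for *low*
affinity. By default moves must also clear the noise threshold
(`use_delta = TRUE`); for monotone fitness this is exactly the strict
accessibility rule. For non-monotone (Gaussian) fitness the two conditions
are combined as "fitness improves and the score change exceeds
$\delta$" — the literal score-increase rule would contradict the fitness
direction. States with no allowed move are absorbing: a lineage waits at a
local peak. Navigability is the start-averaged probability of sitting at
the global peak after $t = 1000$ jumps, computed by repeated vector-matrix
products with early exit on convergence, never by dense matrix powers.

### Path entropy

Predictability is measured by the Shannon entropy of the distribution over
mutational paths from the start set to the global peak. Enumerating paths
is exponential; instead the chain is conditioned on absorption at the peak
by a Doob transform, $\tilde P_{ij} = P_{ij} q_j / q_i$ with $q$ the
absorption probability, and the entropy is computed exactly from the
visit-count identity $H = H(\text{start mixture}) + \sum_i \nu_i h_i$,
where $\nu$ are expected visits under $\tilde P$ and $h_i$ is the step
entropy of row $i$. Conditioning is necessary: without it the path
distribution is improper whenever local peaks absorb probability mass. The
start mixture is uniform over the bottom-10% set, reweighted by each
start's chance of reaching the peak (that is what conditioning a uniform
mixture yields). Entropy is reported in bits (base 2, the same base as the
diversity index); the base is a parameter. The implementation is verified
against brute-force path enumeration to 1e-9 on hundreds of random small
landscapes.

### Quasispecies steady state

For an infinite population the steady state is the dominant left
eigenvector of $P$, computed by damped power iteration
($v \leftarrow (v + vP/\|vP\|_1)/2$, tolerance $10^{-12}$), which also
converges on periodic chains. For a chain with a single absorbing state
this is degenerate — the indicator of that state — which is the honest
consequence of applying the eigenvector definition to an absorbing jump
matrix; distances between steady states under different $\alpha$ are
Euclidean.

## Wright-Fisher dynamics (high mutation supply)

With $N\mu \geq 1$ many mutations segregate simultaneously.
`wf_simulate()` iterates generations of (i) multinomial resampling of $N$
individuals with weights linearly proportional to affinity and (ii)
per-individual mutation with probability $\mu$ (at most one substitution
per sequence per generation; at $\mu \le 5\times10^{-3}$ multi-hits are
negligible, and the single-hit rule keeps the per-event class calculus
exact). A mutating sequence picks one of its $3k$ single-base alternatives
with weight $\alpha$ for the transition at a position and $1-\alpha$ for
each transversion, so
$P(\text{transition} \mid \text{mutation}) = \alpha/(2-\alpha)$ — 1/3 at
$\alpha = 0.5$, the null spectrum. Mutants that leave the bound set have
fitness 0 by default ("lethal": produced, never selected), the minimal
assumption under which robustness matters; a "rejected" mode (mutation
discarded) is available. Runs are bit-reproducible from their seed, and
grid designs seed replicate $r$ identically across $\alpha$ values so
replicate variation and bias-induced variation can be compared fairly.
Populations are summarised by the overlap coefficient
$|A \cap B| / \min(|A|,|B|)$ (min-multiplicity intersection), normalized
Shannon diversity $-\sum_i p_i \log_2 p_i / \log_2 n$, nucleotide
diversity $\pi$ (mean pairwise substitution distance per site, minimised
over strand orientation; the population estimator, with the $N/(N-1)$
correction behind a flag, since the source convention is not stated),
count-weighted mutational robustness, allele spectra relative to a
reference site (on the reference's stored orientation, with multi-hit mass
reported separately), and evolvability (the fraction and count of other
factors' landscapes containing a one-mutant neighbour of the evolved
population).

## The synthetic landscape generator

Real protein-binding-microarray data cannot ship with the package, so
`generate_landscape()` builds score tables with the statistical features
the analyses rely on, from an additive score field over the full 32,896
canonical 8-mers:

* a primary motif (the peak sequence) whose base composition follows
  `gc_skew`: A/T-only at $-1$, G/C-balanced (roughly 70% G/C) at $+1$.
  Within each base pair the purine is strongly preferred, giving a
  strand-asymmetric (purine-rich) motif; near-palindromic peaks would let
  strand canonicalisation open spurious within-pair shortcut routes;
* per-position substitution costs relative to the peak that depend on the
  mutation class of the deviation. `gc_skew` tilts which class is
  favoured: at $-1$ within-pair transversions (A&#8596;T, C&#8596;G) are
  cheap — an A/T-rich, transversion-dominated bound set; at $+1$
  transitions are cheap — a G/C-balanced, transition-dominated bound set.
  The contrast is moderate (costs $2 \mp 0.7\,gc$), so the disfavoured
  class still appears in the bound set and mutation bias has purchase.
  Double-attribute transversions (A&#8596;C, G&#8596;T type) abolish
  binding, reflecting their maximal disruptiveness;
* secondary optima ("alternative binding modes", default 6) that make
  landscapes rugged: each centre is the primary motif displaced by several
  disfavoured-class substitutions, far enough from the peak that a
  low-score moat isolates its basin, and its basin costs are skewed the
  opposite way, so mutational routes into a secondary optimum are enriched
  for the class that is rare on routes to the global peak. This mirrors
  the empirical situation in which whole-landscape class mixtures sit much
  closer to the null than accessible-path mixtures, and it is what makes
  navigability genuinely sensitive to mutation bias: misaligned bias
  steers walks into the secondary basins. In validation this alignment is
  strong for transversion-favoured landscapes; the transition-favoured
  mirror is markedly weaker, plausibly because the genotype space offers
  two transversion alternatives per transition at every position, an
  asymmetry the two-class mutation weighting cannot remove;
* scale calibration so the dominant component reaches
  `target_bound_size` (re-tried with a wider bound region a bounded
  number of times), bound scores in (0.35, 0.5];
* a small shared jitter (`jitter_sd`, default 0.005) roughening both
  replicates identically, and replicate noise (`noise_sd`, default 0.01)
  added to replicate 2 only, so `estimate_delta()` recovers a
  $\delta$ close to the configured noise and exactly 0 when
  `noise_sd = 0`.

What the generator does *not* emulate: biophysical energy models, probe
normalisation artefacts, correlated (non-additive) epistasis beyond the
seeded optima, and the empirical distribution of landscape sizes. Tests
passing on these synthetic landscapes therefore demonstrate correctness of
the algorithms and the qualitative bias interactions, not quantitative
agreement with any particular factor's data.

## Problem sizes and numerical choices

The packaged analyses use desk-scale problem sizes chosen to exercise each
regime: ensembles of 16-30 synthetic landscapes of 100-150 bound sites for
navigability sweeps; Wright-Fisher populations of N = 500-2000 for 250-500
generations (the mutation supply $N\mu$, not $N$ itself, governs the
regime, and steady state arrives within a few hundred generations on
landscapes of this size); $10^5$ Monte-Carlo walkers for chain
cross-checks; 19-point $\alpha$ grids on [0.05, 0.95]. Absorption
probabilities and visit counts come from sparse triangular-ish solves;
power iteration runs to $10^{-12}$; path-entropy equivalence is asserted
to $10^{-9}$. Degenerate inputs are handled explicitly: empty bound sets,
sub-minimum dominant components, unreachable peaks (missing values, never
zeros), tied peaks (lexicographic rule plus warning), and extinct
populations (error).

## Known limitations

* The additive cost field yields landscapes smoother than real PBM
  surfaces; ruggedness is controlled, not emergent.
* The origin-fixation fixation probability is linear in the relative
  affinity gain; population-size-dependent (Kimura-type) fixation is out
  of scope.
* Path entropy requires the strict (acyclic) accessibility criterion;
  relaxed-criterion chains can cycle and have no proper path distribution.
* The quasispecies eigenvector is degenerate for single-absorber chains;
  it is reported literally rather than regularised.
* Indels, IUPAC ambiguity codes and RNA alphabets are not modelled.
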