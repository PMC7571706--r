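#' Origin-fixation jump chain on a landscape
#'
#' Low mutation supply (N*mu << 1): evolution proceeds by sequential fixation
#' of single mutations and is modelled as a Markov jump chain over the
#' landscape's genotypes. The jump probability from genotype i to a
#' one-mutant neighbour j is proportional to `phi_ij * f_ij`, where
#' `phi_ij` is `alpha` for a transition edge and `1 - alpha` for a
#' transversion edge (the mutation-supply bias), and
#' `f_ij = w_j / w_i - 1` is the relative fitness advantage of an improving
#' neighbour (0 for non-improving moves). Rows are normalised to 1; states
#' with no allowed improving move are absorbing (`P[i,i] = 1`) — the walker
#' waits at local peaks.
#'
#' Fitness `w` is either the binding score itself (`"linear"`) or a Gaussian
#' preference `exp(-((b - e_opt)/sigma)^2)`, which favours scores near
#' `e_opt` and models selection for low affinity when `e_opt` is at the
#' bottom of the score range. With `use_delta = TRUE` (default) a move is
#' allowed only when the fitness improves and the score change clears the
#' noise threshold (`|b_j - b_i| > delta`); for monotone (linear) fitness
#' this is exactly the accessibility criterion `b_j - b_i > delta`. With
#' `use_delta = FALSE` any fitness improvement is allowed.
#'
#' @param L A `tf_landscape`.
#' @param alpha Mutation bias in (0, 1); 0.5 is the unbiased supply.
#' @param fitness `"linear"` (default) or `"gaussian"`.
#' @param e_opt,sigma Gaussian fitness parameters (defaults 0.35 and 0.1).
#' @param use_delta Apply the landscape's noise threshold to moves
#'   (default `TRUE`).
#' @return A `fixation_chain`: sparse row-stochastic matrix `P`, state
#'   labels, peak index, absorbing-state flags, default start set (bottom
#'   10% by score).
#' @export
fixation_chain <- function(L, alpha, fitness = c("linear", "gaussian"),
                           e_opt = 0.35, sigma = 0.1, use_delta = TRUE) {
  stopifnot(inherits(L, "tf_landscape"),
            length(alpha) == 1L, alpha > 0, alpha < 1)
  fitness <- match.arg(fitness)
  states <- L$genotype
  n <- length(states)
  idx <- setNames(seq_len(n), states)
  b <- unname(L$score[states])
  w <- if (fitness == "linear") b else exp(-((b - e_opt) / sigma)^2)
  if (any(w <= 0)) stop("nonpositive fitness value", call. = FALSE)

  e <- L$edges
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  if (nrow(e)) {
    a <- idx[e$from]; z <- idx[e$to]
    cand_i <- c(a, z); cand_j <- c(z, a)
    cls <- c(e$class, e$class)
    improve <- w[cand_j] > w[cand_i]
    if (use_delta) improve <- improve & abs(b[cand_j] - b[cand_i]) > L$delta
    ii <- cand_i[improve]; jj <- cand_j[improve]
    f <- w[jj] / w[ii] - 1
    phi <- ifelse(cls[improve] == "transition", alpha, 1 - alpha)
    xx <- phi * f
  }
  tot <- numeric(n)
  if (length(ii)) {
    agg <- tapply(xx, ii, sum)
    tot[as.integer(names(agg))] <- agg
  }
  absorbing <- tot == 0
  if (length(ii)) xx <- xx / tot[ii]
  P <- Matrix::sparseMatrix(i = c(ii, which(absorbing)),
                            j = c(jj, which(absorbing)),
                            x = c(xx, rep(1, sum(absorbing))),
                            dims = c(n, n), dimnames = list(states, states))
  ord <- order(b, states)
  starts <- states[ord][seq_len(ceiling(0.1 * n))]
  structure(list(P = P, states = states, score = setNames(b, states),
                 fitnessv = setNames(w, states),
                 peak = L$peak, peak_idx = unname(idx[L$peak]),
                 absorbing = setNames(absorbing, states),
                 starts = starts, alpha = alpha, fitness = fitness,
                 use_delta = use_delta, delta = L$delta, tf = L$tf),
            class = "fixation_chain")
}

#' @export
print.fixation_chain <- function(x, ...) {
  cat("Origin-fixation chain over ", length(x$states), " genotypes",
      " (alpha = ", format(x$alpha, digits = 3), ", ", x$fitness,
      " fitness)\n", sep = "")
  cat("  absorbing states: ", sum(x$absorbing),
      "   global peak: ", x$peak, "\n", sep = "")
  invisible(x)
}

.resolve_starts <- function(M, starts) {
  if (is.null(starts)) starts <- M$starts
  if (is.character(starts)) {
    miss <- setdiff(starts, M$states)
    if (length(miss)) stop("unknown start genotype '", miss[1], "'",
                           call. = FALSE)
    starts <- match(starts, M$states)
  }
  unique(as.integer(starts))
}

#' Navigability: probability of reaching the global peak
#'
#' The mean over start genotypes of the t-step absorption probability
#' `(P^t)[start, peak]`, computed by repeated vector-matrix products with an
#' early exit once the start-averaged state distribution stops changing
#' (never by dense matrix powers).
#'
#' @param M A [fixation_chain()].
#' @param starts Start genotypes (character) or state indices; default the
#'   chain's bottom-10% start set.
#' @param t Number of steps (default 1000).
#' @return A probability in \[0, 1\].
#' @export
p_peak <- function(M, starts = NULL, t = 1000) {
  stopifnot(inherits(M, "fixation_chain"), t >= 1)
  starts <- .resolve_starts(M, starts)
  n <- length(M$states)
  v <- numeric(n)
  v[starts] <- 1 / length(starts)
  for (step in seq_len(t)) {
    v_new <- as.vector(v %*% M$P)
    if (max(abs(v_new - v)) < 1e-16) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v[M$peak_idx]
}

# Doob-condition a (sub)stochastic chain, given as sparse triplets, on
# absorption at `peak`. Self-loops and moves out of the peak are removed
# before computing q (the probability of eventually absorbing at the peak),
# so q is 0 at other absorbing states. Returns NULL if the peak is
# unreachable from every start; otherwise the absorption probabilities q,
# the conditioned transition triplets, the conditioned start distribution w
# and expected visit counts nu.
.condition_on_peak <- function(i, j, x, n, starts, peak) {
  drop <- i == j | i == peak
  i <- i[!drop]; j <- j[!drop]; x <- x[!drop]
  A <- Matrix::Diagonal(n) - Matrix::sparseMatrix(i = i, j = j, x = x,
                                                  dims = c(n, n))
  b <- numeric(n); b[peak] <- 1
  q <- as.vector(Matrix::solve(A, b))
  q[q < 1e-14] <- 0
  if (all(q[starts] == 0)) return(NULL)
  w <- numeric(n)
  w[starts] <- q[starts] / length(starts)
  w <- w / sum(w)
  keep <- q[i] > 0 & q[j] > 0
  ti <- i[keep]; tj <- j[keep]
  tx <- x[keep] * q[tj] / q[ti]
  Pt <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n))
  A2 <- Matrix::Diagonal(n) - Matrix::t(Pt)
  nu <- as.vector(Matrix::solve(A2, w))
  nu[nu < 0] <- 0
  list(q = q, w = w, nu = nu, i = ti, j = tj, x = tx)
}

#' Shannon entropy of the path distribution to the global peak
#'
#' The entropy of the probability distribution over mutational paths from
#' the start set to the global peak, conditioned on absorption at the peak,
#' with a uniform start mixture. Computed exactly (no path enumeration) via
#' the Doob-transformed chain `Ptilde[i,j] = P[i,j] q_j / q_i`, where `q` is
#' the probability of absorbing at the peak, using the visit-count identity
#' `H = H(start mixture) + sum_i nu_i h_i` with `nu` the expected visits
#' under the conditioned chain and `h_i` the per-state step entropy. Low
#' entropy means few, high-probability paths (predictable evolution); high
#' entropy means many low-probability paths.
#'
#' @param M A [fixation_chain()] whose improving moves form an acyclic graph
#'   (always true for strict, delta-thresholded chains).
#' @param starts Start genotypes or indices; default the chain's start set.
#' @param log_base Logarithm base (default 2: entropy in bits).
#' @return Entropy (non-negative scalar).
#' @export
path_entropy <- function(M, starts = NULL, log_base = 2) {
  stopifnot(inherits(M, "fixation_chain"))
  starts <- .resolve_starts(M, starts)
  n <- length(M$states)
  trip <- methods::as(M$P, "TsparseMatrix")
  i <- trip@i + 1L; j <- trip@j + 1L; x <- trip@x
  off <- i != j
  if (any(off)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = i[off], to = j[off]), directed = TRUE,
      vertices = data.frame(name = seq_len(n)))
    if (!igraph::is_dag(g)) {
      stop("path entropy requires an acyclic (strict) chain", call. = FALSE)
    }
  }
  cond <- .condition_on_peak(i, j, x, n, starts, M$peak_idx)
  if (is.null(cond)) {
    stop("global peak unreachable from every start", call. = FALSE)
  }
  lb <- log(log_base)
  wpos <- cond$w[cond$w > 0]
  h_start <- -sum(wpos * log(wpos)) / lb
  step_terms <- -cond$x * log(cond$x) / lb
  h_state <- numeric(n)
  agg <- tapply(step_terms, cond$i, sum)
  h_state[as.integer(names(agg))] <- agg
  h_start + sum(cond$nu * h_state)
}

#' Sweep the mutation bias parameter
#'
#' Evaluates navigability and (optionally) path entropy on a grid of
#' mutation bias values — by default the 19 linearly spaced values in
#' \[0.05, 0.95\] — and summarises the alpha maximising `p_peak`, the alphas
#' minimising/maximising entropy, and the relative entropy changes
#' `H(no bias)/H_min` and `H_max/H(no bias)` (no bias meaning the grid value
#' closest to 0.5).
#'
#' @param L A `tf_landscape`.
#' @param grid Alpha grid (default `seq(0.05, 0.95, length.out = 19)`).
#' @param t Steps for [p_peak()] (default 1000).
#' @param entropy Also compute path entropy per alpha (default `TRUE`).
#' @param starts Start set passed to [p_peak()] and [path_entropy()].
#' @param ... Passed to [fixation_chain()] (`fitness`, `use_delta`, ...).
#' @return An `alpha_sweep`: data.frame with columns `alpha`, `p_peak`,
#'   `entropy`, carrying a `summary` attribute.
#' @export
alpha_sweep <- function(L, grid = seq(0.05, 0.95, length.out = 19),
                        t = 1000, entropy = TRUE, starts = NULL, ...) {
  stopifnot(inherits(L, "tf_landscape"), length(grid) >= 1)
  pp <- numeric(length(grid))
  en <- rep(NA_real_, length(grid))
  for (g in seq_along(grid)) {
    M <- fixation_chain(L, alpha = grid[g], ...)
    pp[g] <- p_peak(M, starts = starts, t = t)
    if (entropy) {
      en[g] <- tryCatch(path_entropy(M, starts = starts),
                        error = function(e) NA_real_)
    }
  }
  out <- data.frame(alpha = grid, p_peak = pp, entropy = en)
  i0 <- which.min(abs(grid - 0.5))
  smry <- list(
    tf = L$tf,
    alpha_max_ppeak = grid[which.max(pp)],
    alpha_min_entropy = if (any(!is.na(en))) grid[which.min(en)] else NA_real_,
    alpha_max_entropy = if (any(!is.na(en))) grid[which.max(en)] else NA_real_,
    entropy_no_bias = en[i0],
    entropy_ratio_min = if (!is.na(en[i0])) en[i0] / min(en, na.rm = TRUE)
                        else NA_real_,
    entropy_ratio_max = if (!is.na(en[i0])) max(en, na.rm = TRUE) / en[i0]
                        else NA_real_
  )
  structure(out, summary = smry, class = c("alpha_sweep", "data.frame"))
}

#' @export
print.alpha_sweep <- function(x, ...) {
  s <- attr(x, "summary")
  cat("Mutation-bias sweep (", nrow(x), " alpha values)\n", sep = "")
  cat("  alpha maximising P_peak: ", format(s$alpha_max_ppeak), "\n", sep = "")
  if (!is.na(s$alpha_min_entropy)) {
    cat("  alpha minimising path entropy: ", format(s$alpha_min_entropy),
        "   (H_no_bias / H_min = ",
        format(s$entropy_ratio_min, digits = 4), ")\n", sep = "")
    cat("  alpha maximising path entropy: ", format(s$alpha_max_entropy),
        "   (H_max / H_no_bias = ",
        format(s$entropy_ratio_max, digits = 4), ")\n", sep = "")
  }
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.alpha_sweep <- function(x, ...) {
  has_entropy <- any(!is.na(x$entropy))
  if (has_entropy) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  plot(x$alpha, x$p_peak, type = "b", xlab = expression(alpha),
       ylab = expression(P[peak]), ...)
  graphics::abline(v = 0.5, lty = 2)
  if (has_entropy) {
    plot(x$alpha, x$entropy, type = "b", xlab = expression(alpha),
         ylab = "path entropy (bits)", ...)
    graphics::abline(v = 0.5, lty = 2)
  }
  invisible(x)
}

#' Quasispecies stationary distribution
#'
#' The steady state of an infinite population on the landscape: the left
#' eigenvector of the jump matrix associated with its largest eigenvalue,
#' normalised to sum 1, computed by damped power iteration. For a chain with
#' a single absorbing state this is the indicator of that state.
#'
#' @param M A [fixation_chain()] or a non-negative square matrix.
#' @param tol Convergence tolerance on the iterate (default 1e-12).
#' @param max_iter Iteration budget (default 1e6).
#' @return Probability vector over states (named when state names exist).
#' @export
stationary_distribution <- function(M, tol = 1e-12, max_iter = 1e6) {
  A <- if (inherits(M, "fixation_chain")) M$P else M
  stopifnot(nrow(A) == ncol(A))
  if (any(A < 0)) stop("matrix must be non-negative", call. = FALSE)
  n <- nrow(A)
  v <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    v1 <- as.vector(v %*% A)
    s <- sum(v1)
    if (s <= 0) stop("iterate vanished; matrix has no positive dominant ",
                     "eigenvector reachable from the uniform start",
                     call. = FALSE)
    v_new <- 0.5 * (v + v1 / s)
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    if (it == max_iter) stop("power iteration did not converge", call. = FALSE)
    v <- v_new
  }
  v <- v / sum(v)
  if (!is.null(rownames(A))) names(v) <- rownames(A)
  v
}

#' Euclidean distance between steady-state distributions
#'
#' @param v1,v2 Numeric vectors of equal length.
#' @return The l2 distance; 0 iff identical.
#' @export
steady_state_distance <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("dimension mismatch", call. = FALSE)
  sqrt(sum((as.numeric(v1) - as.numeric(v2))^2))
}
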