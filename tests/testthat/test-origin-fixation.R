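test_that("jump probabilities follow the weighted-selection rule", {
  # hand evaluation: improving transition with f = 0.1 and improving
  # transversion with f = 0.3 at alpha = 0.5 give 0.25 / 0.75
  L <- toy_fixture("fork")
  M <- fixation_chain(L, alpha = 0.5)
  P <- as.matrix(M$P)
  s <- "AAAAAAAA"; j <- "AGAAAAAA"; k_ <- "CAAAAAAA"
  expect_equal(P[s, j], 0.25, tolerance = 1e-12)
  expect_equal(P[s, k_], 0.75, tolerance = 1e-12)
  # transversion weight vanishes as alpha -> 1
  P99 <- as.matrix(fixation_chain(L, alpha = 0.999)$P)
  expect_gt(P99[s, j], 0.99)
  # the global peak row is absorbing
  expect_equal(P[k_, k_], 1)
  expect_true(M$absorbing[[k_]])
})

test_that("rows of the jump matrix sum to one and respect no-bias symmetry", {
  for (seed in c(41, 42, 43)) {
    L <- random_small_landscape(seed, n_max = 14)
    for (a in c(0.1, 0.5, 0.9)) {
      M <- fixation_chain(L, alpha = a)
      expect_true(all(abs(Matrix::rowSums(M$P) - 1) < 1e-12))
    }
    # at alpha = 0.5 swapping all edge class labels leaves P unchanged
    M5 <- fixation_chain(L, alpha = 0.5)
    Lsw <- L
    Lsw$edges$class <- ifelse(L$edges$class == "transition",
                              "transversion", "transition")
    M5s <- fixation_chain(Lsw, alpha = 0.5)
    expect_lt(max(abs(M5$P - M5s$P)), 1e-12)
  }
})

test_that("navigability from matrix propagation matches hand values", {
  two <- build_landscape(
    score_table(c("AAAAAAAA", "AAAAAAAC"), c(0.36, 0.45)),
    min_component = 1, delta = 0.01)
  M2 <- fixation_chain(two, alpha = 0.3)
  expect_equal(p_peak(M2, t = 1), 1)
  expect_equal(p_peak(M2, t = 1000), 1)
  # a start that is itself a non-peak local optimum contributes 0
  Lt <- toy_fixture("two_peaks")
  Mt <- fixation_chain(Lt, alpha = 0.5)
  expect_equal(p_peak(Mt, starts = "AGAAAAAA", t = 50), 0)
  # fork: 0.75 at alpha = 0.5 for any t >= 1
  Mf <- fixation_chain(toy_fixture("fork"), alpha = 0.5)
  expect_equal(p_peak(Mf, t = 1), 0.75, tolerance = 1e-12)
  expect_equal(p_peak(Mf, t = 1000), 0.75, tolerance = 1e-12)
})

test_that("p_peak is non-decreasing in t and below 1 on two-peak landscapes", {
  L <- toy_fixture("two_peaks")
  for (a in c(0.05, 0.5, 0.95)) {
    M <- fixation_chain(L, alpha = a)
    pp <- vapply(c(1, 2, 5, 20, 100), function(t) p_peak(M, t = t), numeric(1))
    expect_true(all(diff(pp) >= -1e-14))
    expect_lt(pp[length(pp)], 1)
    expect_gt(pp[length(pp)], 0)
  }
})

test_that("p_peak matches Monte-Carlo walkers within 3 standard errors", {
  for (fx in c("fork", "two_peaks", "three_paths")) {
    L <- toy_fixture(fx)
    M <- fixation_chain(L, alpha = 0.35)
    exact <- p_peak(M, t = 100)
    mc <- mc_p_peak(M, t = 100, n_walkers = 1e5, seed = 7)
    expect_lt(abs(exact - mc$p), 3 * max(mc$se, 1e-4))
  }
})

test_that("path entropy equals brute-force enumeration on toy fixtures", {
  # single start, single path -> 0 bits
  M1 <- fixation_chain(toy_fixture("single_path"), alpha = 0.5)
  expect_equal(path_entropy(M1), 0, tolerance = 1e-12)
  # twin_paths at alpha = 0.5: the transition and transversion first steps
  # have equal fitness gains, later steps are forced, so the two routes are
  # equiprobable -> exactly 1 bit
  M2 <- fixation_chain(toy_fixture("twin_paths"), alpha = 0.5)
  expect_equal(path_entropy(M2), 1, tolerance = 1e-12)
  for (fx in c("three_paths", "twin_paths")) {
    for (a in c(0.1, 0.5, 0.9)) {
      M <- fixation_chain(toy_fixture(fx), alpha = a)
      oracle <- enumerate_path_entropy(M)
      expect_equal(path_entropy(M), oracle$entropy, tolerance = 1e-9)
    }
  }
})

test_that("path entropy equals enumeration on random acyclic landscapes", {
  n_cases <- 40
  ok <- 0
  for (s in seq_len(n_cases)) {
    L <- random_small_landscape(1000 + s, n_max = 15)
    M <- fixation_chain(L, alpha = withr::with_seed(2000 + s, runif(1, 0.05, 0.95)))
    oracle <- enumerate_path_entropy(M)
    if (is.null(oracle)) next  # peak unreachable from the start set
    expect_equal(path_entropy(M), oracle$entropy, tolerance = 1e-9)
    ok <- ok + 1
  }
  expect_gt(ok, n_cases / 2)
})

test_that("conditioned path probabilities sum to one on enumeration fixtures", {
  for (fx in c("three_paths", "twin_paths", "fork")) {
    M <- fixation_chain(toy_fixture(fx), alpha = 0.4)
    oracle <- enumerate_path_entropy(M)
    expect_lte(oracle$mass, 1 + 1e-12)
  }
})

test_that("alpha sweeps use the 19-value grid and locate extreme optima", {
  L <- toy_fixture("three_paths")
  sw <- alpha_sweep(L, t = 100)
  expect_equal(nrow(sw), 19L)
  expect_equal(sw$alpha[1], 0.05)
  expect_equal(sw$alpha[19], 0.95)
  s <- attr(sw, "summary")
  # one transversion-first route vs two all-transition routes: entropy is
  # minimised at extreme transversion bias
  expect_equal(s$alpha_min_entropy, 0.05)
  expect_gt(s$entropy_ratio_min, 1)
  expect_gte(s$entropy_ratio_max, 1)
  # single-route landscape: p_peak is 1 at every alpha
  sw1 <- alpha_sweep(toy_fixture("single_path"), t = 100)
  expect_true(all(abs(sw1$p_peak - 1) < 1e-12))
})

test_that("stationary distributions match a dense eigensolver", {
  # absorbing chain: indicator at the single absorbing peak
  M <- fixation_chain(toy_fixture("single_path"), alpha = 0.5)
  v <- stationary_distribution(M)
  expect_equal(unname(v[M$peak]), 1, tolerance = 1e-9)
  # doubly stochastic 2x2
  expect_equal(stationary_distribution(matrix(0.5, 2, 2)), c(0.5, 0.5),
               tolerance = 1e-9)
  # random irreducible stochastic matrices vs dense left eigenvector
  withr::with_seed(51, {
    for (i in 1:8) {
      n <- sample(5:20, 1)
      A <- matrix(runif(n * n, 0.01, 1), n, n)
      A <- A / rowSums(A)
      v <- stationary_distribution(A)
      e <- eigen(t(A))
      lead <- which.max(Re(e$values))
      ref <- Re(e$vectors[, lead]); ref <- ref / sum(ref)
      expect_lt(max(abs(v - ref)), 1e-9)
    }
  })
})

test_that("steady-state distance is the euclidean metric", {
  expect_equal(steady_state_distance(c(1, 0), c(1, 0)), 0)
  expect_equal(steady_state_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_equal(steady_state_distance(c(0.5, 0.5, 0), c(0, 0.5, 0.5)),
               sqrt(0.5))
  expect_error(steady_state_distance(c(1, 0), c(1, 0, 0)), "dimension")
})
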