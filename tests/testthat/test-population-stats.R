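test_that("the overlap coefficient reproduces its defining example", {
  expect_equal(overlap(c(1, 1, 2, 2, 2, 3), c(1, 2, 2, 4)), 0.75)
  expect_equal(overlap(c("a", "a", "b"), c("a", "a", "b")), 1)
  expect_equal(overlap(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap(c(1, 1, 2), c(2, 1, 1)), 1)  # order-free
  # symmetric, and invariant to relabeling
  a <- c(x = 3, y = 2); b <- c(x = 1, z = 4)
  expect_equal(overlap(a, b), overlap(b, a))
  a2 <- c(u = 3, v = 2); b2 <- c(u = 1, w = 4)
  expect_equal(overlap(a, b), overlap(a2, b2))
  expect_error(overlap(numeric(0), c(1)), "empty")
})

test_that("normalized Shannon diversity spans [0, 1] with known extremes", {
  expect_equal(shannon_diversity(c(AAAA = 100), n = 50), 0)
  uniform <- setNames(rep(2, 50), paste0("g", 1:50))
  expect_equal(shannon_diversity(uniform, n = 50), 1)
  expect_equal(shannon_diversity(c(a = 5, b = 5), n = 4), 0.5)
  expect_error(shannon_diversity(c(a = 1), n = 1), ">= 2")
  # moving a copy from the most to the least frequent genotype raises H
  withr::with_seed(81, {
    for (i in 1:10) {
      cnt <- setNames(sort(rpois(6, 20) + 2), paste0("g", 1:6))
      h0 <- shannon_diversity(cnt, n = 10)
      cnt2 <- cnt
      cnt2[6] <- cnt2[6] - 1; cnt2[1] <- cnt2[1] + 1
      expect_gt(shannon_diversity(cnt2, n = 10), h0)
    }
  })
})

test_that("nucleotide diversity equals the hand double sum", {
  expect_equal(nucleotide_diversity(c(ACGTACGT = 10)), 0)
  two <- c(AAAAAAAA = 5, AAAAAAAC = 5)
  expect_equal(nucleotide_diversity(two), 2 * 0.25 * (1 / 8))
  expect_equal(nucleotide_diversity(two, corrected = TRUE),
               2 * 0.25 * (1 / 8) * 10 / 9)
  # hand double-sum on a 3-haplotype fixture
  cnt <- c(AAAAAAAA = 2, AAAAAAAC = 1, AAAAAACC = 1)
  p <- cnt / sum(cnt)
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1 / 8
  d[1, 3] <- d[3, 1] <- 2 / 8
  d[2, 3] <- d[3, 2] <- 1 / 8
  expect_equal(nucleotide_diversity(cnt), as.numeric(t(p) %*% d %*% p))
  # strand symmetry: replacing genotypes by reverse complements changes
  # nothing (distances are minimised over orientation)
  rc <- setNames(as.numeric(cnt), revcomp(names(cnt)))
  expect_equal(nucleotide_diversity(rc), nucleotide_diversity(cnt))
})

test_that("robustness is the bound fraction of the neighbourhood", {
  chain <- build_landscape(
    score_table(c("AAAAAAAA", "AAAAAAAC", "AAAAAACC"), c(0.36, 0.40, 0.47)),
    min_component = 1)
  expect_equal(robustness("AAAAAAAA", chain), 1 / 24)
  expect_equal(robustness("AAAAAAAC", chain), 2 / 24)
  expect_error(robustness("GGGGGGGG", chain), "not in landscape")
  single <- build_landscape(score_table("AAAAAAAA", 0.4), min_component = 1)
  expect_equal(robustness("AAAAAAAA", single), 0)
  # population mean is count-weighted; edge-count consistency: the sum of
  # bound-neighbour counts over all genotypes is twice the edge count
  L <- random_small_landscape(82, n_max = 12)
  frac <- vapply(L$genotype, function(g) {
    nb <- genotype_neighbors(g)
    c(sum(nb$genotype %in% L$genotype), nrow(nb))
  }, numeric(2))
  expect_equal(sum(frac[1, ]), 2 * nrow(L$edges))
  pop <- setNames(rep(1, length(L$genotype)), L$genotype)
  expect_equal(population_robustness(pop, L), mean(frac[1, ] / frac[2, ]))
})

test_that("allele spectra partition the population mass", {
  ref <- "AAAAAAAA"
  mono <- c(AAAAAAAA = 100)
  sp <- allele_spectrum(mono, ref)
  expect_equal(nrow(sp$entries), 0L)
  expect_equal(sp$reference_frequency, 1)
  pop <- c(AAAAAAAA = 90, GAAAAAAA = 10)
  sp2 <- allele_spectrum(pop, ref)
  expect_equal(nrow(sp2$entries), 1L)
  expect_equal(sp2$entries$frequency, 0.1)
  expect_equal(sp2$entries$class, "transition")
  expect_equal(sp2$entries$position, 1L)
  # multi-hit mass + entries + reference = 1
  pop3 <- c(AAAAAAAA = 70, GAAAAAAA = 10, CAAAAAAA = 10, GGAAAAAA = 10)
  sp3 <- allele_spectrum(pop3, ref)
  expect_equal(sum(sp3$entries$frequency) + sp3$multi_hit +
                 sp3$reference_frequency, 1)
  expect_equal(sp3$multi_hit, 0.1)
  # strand handling: the reverse complement of a one-mutant is still a
  # one-mutant on the reference orientation
  sp4 <- allele_spectrum(setNames(c(50, 50), c("AAAAAAAA",
                                               revcomp("AAGAAAAA"))), ref)
  expect_equal(nrow(sp4$entries), 1L)
  expect_equal(sp4$entries$position, 3L)
})

test_that("evolvability counts collection landscapes reached by one-mutants", {
  mk <- function(genos, scores) {
    build_landscape(score_table(genos, scores), min_component = 1)
  }
  focal <- mk(c("AAAAAAAA", "AAAAAAAC"), c(0.40, 0.45))
  pop <- c(AAAAAAAA = 10)
  hit1 <- mk(c("GAAAAAAA", "GAAAAAAC"), c(0.40, 0.41))   # contains a neighbour
  hit2 <- mk("AAAAAAAT", 0.40)                            # contains a neighbour
  miss <- mk(c("GGGGAAAA", "GGGGAAAC"), c(0.40, 0.41))    # contains none
  ev <- evolvability(pop, focal, list(hit1, miss))
  expect_equal(ev$count, 1)
  expect_equal(ev$fraction, 0.5)
  # a landscape with no neighbour lowers the fraction, not the count
  ev3 <- evolvability(pop, focal, list(hit1, hit2, miss))
  expect_equal(ev3$count, 2)
  expect_equal(ev3$fraction, 2 / 3)
  # neighbours inside the focal landscape do not count
  ev0 <- evolvability(pop, focal, list(mk("AAAAAAAC", 0.4)))
  expect_equal(ev0$count, 0)
  expect_error(evolvability(pop, focal, list()), "empty")
})
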