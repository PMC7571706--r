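chain3_table <- function() {
  score_table(c("AAAAAAAA", "AAAAAAAC", "AAAAAACC"),
              c(0.36, 0.40, 0.47), tf_name = "chain3")
}

test_that("score tables canonicalise and reject conflicting duplicates", {
  tab <- score_table(c("AAAACGTT", "AACGTTTT"), c(0.41, 0.41))
  expect_equal(nrow(tab), 1L)  # two orientations of one site
  expect_equal(tab$escore, 0.41)
  expect_error(score_table(c("AAAACGTT", "AACGTTTT"), c(0.41, 0.10)),
               "conflicting")
})

test_that("the TSV reader handles orientations, headers and bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "kmer\tkmer_rc\tescore",
               "AAAACGTT\tAACGTTTT\t0.41",
               "AACGTTTT\tAAAACGTT\t0.41",
               "AAAAAAAC\tGTTTTTTT\t0.20"), path)
  tab <- read_score_table(path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$escore[tab$genotype == "AAAACGTT"], 0.41)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("AAAAAAAA\t0.30", "AAAAAAAC\tNA"), bad)
  expect_error(read_score_table(bad), "line 2")

  # round trip through the writer
  out <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(tab, out)
  back <- read_score_table(out)
  expect_equal(back$genotype, tab$genotype)
  expect_equal(back$escore, tab$escore)
})

test_that("landscape construction thresholds, connects and keeps the dominant component", {
  L <- build_landscape(chain3_table(), min_component = 3)
  expect_s3_class(L, "tf_landscape")
  expect_equal(length(L$genotype), 3L)
  expect_equal(nrow(L$edges), 2L)
  expect_equal(L$peak, "AAAAAACC")
  expect_error(build_landscape(score_table("AAAAAAAA", 0.30)), "no bound")

  # two components: sizes 4 and 2; dominant kept, discarded size recorded
  tab <- score_table(
    c("AAAAAAAA", "AAAAAAAC", "AAAAAACC", "AAAAACCC",
      "GGGGGGGG", "CGGGGGGG"),
    c(0.40, 0.41, 0.42, 0.43, 0.45, 0.44))
  L2 <- build_landscape(tab, min_component = 4)
  expect_equal(length(L2$genotype), 4L)
  expect_equal(L2$discarded_components, 2L)
  expect_error(build_landscape(tab, min_component = 5), "too small")
})

test_that("every landscape edge joins genotypes at canonical distance 1", {
  L <- synth_landscape(synth_config(target_bound_size = 60, seed = 21,
                                    noise_sd = 0))
  expect_true(all(vapply(seq_len(nrow(L$edges)), function(i) {
    nb <- genotype_neighbors(L$edges$from[i])
    hit <- nb[nb$genotype == L$edges$to[i], ]
    nrow(hit) == 1L && hit$class == L$edges$class[i]
  }, logical(1))))
  # dominant-component extraction is idempotent
  tab2 <- score_table(L$genotype, unname(L$score[L$genotype]))
  L3 <- build_landscape(tab2, min_component = 1)
  expect_identical(L3$genotype, L$genotype)
  expect_identical(nrow(L3$edges), nrow(L$edges))
})

test_that("delta is the residual standard error of the replicate regression", {
  tab1 <- chain3_table()
  expect_equal(estimate_delta(tab1, tab1), 0)
  shifted <- score_table(tab1$genotype, tab1$escore + 0.02)
  expect_equal(estimate_delta(tab1, shifted), 0)  # intercept absorbs shift
  # closed-form OLS on three points: slope = Sxy/Sxx = 0 here, so
  # SSR = Syy = 1/150 and delta = sqrt(SSR / (n - 2))
  r1 <- score_table(c("AAAAAAAA", "AAAAAAAC", "AAAAAACC"),
                    c(0.40, 0.45, 0.50))
  r2 <- score_table(c("AAAAAAAA", "AAAAAAAC", "AAAAAACC"),
                    c(0.40, 0.50, 0.40))
  x <- r1$escore; y <- r2$escore
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ssr <- sum((y - mean(y) - slope * (x - mean(x)))^2)
  expect_equal(slope, 0)
  expect_equal(estimate_delta(r1, r2), sqrt(ssr / 1), tolerance = 1e-12)
  expect_equal(estimate_delta(r1, r2), 0.0816497, tolerance = 1e-6)
  expect_error(estimate_delta(r1, score_table("AAAAAAAA", 0.4)), "fewer than 3")
})

test_that("peak location breaks ties lexicographically with a warning", {
  L <- build_landscape(chain3_table(), min_component = 1)
  expect_equal(global_peak(L), "AAAAAACC")
  nbL <- L$score[genotype_neighbors(L$peak)$genotype]
  expect_true(all(nbL[!is.na(nbL)] <= L$score[L$peak]))
  tied <- score_table(c("AAAAAAAA", "AAAAAAAC"), c(0.40, 0.40))
  expect_warning(Lt <- build_landscape(tied, min_component = 1), "tied")
  expect_equal(Lt$peak, "AAAAAAAA")
})

test_that("landscape summaries aggregate size, GC, degree and robustness", {
  single <- build_landscape(score_table("AAAAAAAA", 0.4), min_component = 1)
  s1 <- landscape_summary(single)
  expect_equal(s1$mean_degree, 0)
  expect_equal(s1$mean_robustness, 0)
  expect_equal(s1$mean_gc, 0)
  gcL <- build_landscape(score_table("GGGGCCCC", 0.4), min_component = 1)
  expect_equal(landscape_summary(gcL)$mean_gc, 1)
  s3 <- landscape_summary(build_landscape(chain3_table(), min_component = 1))
  expect_equal(s3$mean_degree, 4 / 3)
  expect_equal(s3$n, 3L)
})
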