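test_that("the counting-lemma threshold takes the classical clamped form", {
  expect_equal(lemma_threshold(50, 0, 12), 39L)  # e = 0: l - k + 1
  expect_equal(lemma_threshold(50, 5, 12), 0L)   # 51 - 72 clamped at 0
  expect_error(lemma_threshold(10, 1, 11), "exceed")
})

test_that("lemma_threshold(50, 2, 16) matches exhaustive enumeration", {
  # minimum surviving 16-mers over all C(50, 2) substitution placements
  best <- Inf
  for (i in 1:49) for (j in (i + 1):50) {
    best <- min(best, survivors_of(50, c(i, j), 16))
  }
  expect_equal(best, 3)
  expect_equal(lemma_threshold(50, 2, 16), 3L)
})

test_that("the lemma is a valid lower bound on small cases", {
  for (l in c(12, 17)) for (e in 1:3) for (k in c(4, 6)) {
    cfgs <- utils::combn(l, e)
    mins <- min(apply(cfgs, 2, function(cc) survivors_of(l, cc, k)))
    expect_gte(mins, lemma_threshold(l, e, k))
    expect_equal(mins, cpp_min_survivors(l, e, k))
  }
})

test_that("maximum lossless word sizes for 50 bp matches are 25/16/12/10/8", {
  expect_equal(vapply(1:5, function(e) max_lossless_word_size(50, e),
                      integer(1)),
               c(25L, 16L, 12L, 10L, 8L))
  # every returned k still guarantees a k-mer; k + 1 does not
  for (e in 1:5) {
    k <- max_lossless_word_size(50, e)
    expect_gte(lemma_threshold(50, e, k), 1)
    expect_equal(lemma_threshold(50, e, k + 1), 0L)
  }
})

test_that("expected canonical k-mer occurrences follow 2(L-k+1)/4^k", {
  e <- expected_occurrences(143e6, 11)
  expect_equal(ceiling(e), 69)
  expect_equal(expected_occurrences(11, 11), 2 / 4^11)
  occ <- vapply(8:20, function(k) expected_occurrences(1e6, k), numeric(1))
  expect_true(all(diff(occ) < 0))
})

test_that("spurious k-mer probability caps at 1 and scales by 1/s_e", {
  m <- kmer_stats_model(143e6, bin_length = 143e6, s_e = 1)
  expect_equal(spurious_kmer_prob(m, 11), 1)
  # E(x) = 0.13 with s_e 0.65 gives 0.2
  m2 <- kmer_stats_model(1e9, bin_length = 0.13 * 4^16 / 2 + 16 - 1,
                         s_e = 0.65)
  expect_equal(spurious_kmer_prob(m2, 16), 0.2, tolerance = 1e-6)
  m3 <- kmer_stats_model(1e9, bin_length = 0.13 * 4^16 / 2 + 16 - 1, s_e = 1)
  expect_equal(spurious_kmer_prob(m3, 16), 0.13, tolerance = 1e-6)
})

test_that("fnr handles the degenerate thresholds exactly", {
  expect_equal(fnr(30, 3, 8, 0), 0)
  expect_equal(fnr(30, 0, 8, 23), 0)   # t <= l - k + 1, single configuration
  expect_equal(fnr(30, 0, 8, 24), 1)   # t > l - k + 1
})

test_that("the FNR dynamic program equals brute-force enumeration", {
  for (l in c(14, 19, 22)) for (e in c(1, 2, 4)) for (k in c(5, 9)) {
    for (t in c(1, 3, 6)) {
      expect_equal(fnr(l, e, k, t, "dp"), fnr(l, e, k, t, "enumerate"),
                   info = sprintf("l=%d e=%d k=%d t=%d", l, e, k, t))
    }
  }
})

test_that("fnr is monotone in t and k; fpr is antitone in t", {
  f_t <- vapply(1:8, function(t) fnr(40, 3, 10, t), numeric(1))
  expect_true(all(diff(f_t) >= 0))
  f_k <- vapply(6:13, function(k) fnr(40, 3, k, 4), numeric(1))
  expect_true(all(diff(f_k) >= 0))
  p_t <- vapply(0:8, function(t) fpr(30, 0.2, t), numeric(1))
  expect_true(all(diff(p_t) <= 0))
  expect_equal(fpr(30, 0.2, 0), 1)
  expect_equal(fpr(30, 0, 3), 0)
  expect_equal(fpr(2, 0.5, 2), 0.25)
})

test_that("deduction takes the lossless path on small references", {
  m <- kmer_stats_model(1e4, bin_length = 1e4)
  p <- deduce_params(m, epsilon_spec(50, 1))
  expect_true(p$lossless)
  expect_equal(p$shape$weight, 25L)
  expect_equal(p$threshold, lemma_threshold(50, 1, 25))
  # lossless params have FNR 0 by the survivor model
  expect_equal(fnr(50, 1, p$shape$span, p$threshold), 0)
})

test_that("deduction falls back to the cost grid for epsilon(50,5) at 50 Mb", {
  m <- kmer_stats_model(50e6, bin_length = 50e6 / 64)
  p <- deduce_params(m, epsilon_spec(50, 5))
  expect_false(p$lossless)
  expect_true(all(c("k", "t", "fnr", "fpr", "cost") %in% names(p$grid)))
  expect_true(all(p$grid$cost >= 0 & p$grid$cost <= 2))
  expect_equal(p$grid$cost, p$grid$fnr + p$grid$fpr)
  g <- glance(p)
  expect_equal(g$k, p$shape$weight)
})

test_that("a singleton grid returns its only cell", {
  m <- kmer_stats_model(50e6, bin_length = 1e6)
  p <- deduce_params(m, epsilon_spec(50, 5), k_range = 12, t_range = 5)
  expect_equal(p$shape$weight, 12L)
  expect_equal(p$threshold, 5L)
})

test_that("deduction rejects an empty grid", {
  m <- kmer_stats_model(1e6)
  expect_error(deduce_params(m, epsilon_spec(50, 5), k_range = integer(0)),
               "empty")
})

test_that("distinct k-mer statistics: degenerate and random sequences", {
  expect_equal(distinct_kmer_stats(strrep("A", 100), seed_shape(5))$distinct,
               1)
  one <- distinct_kmer_stats(dna(9, seed = 5), seed_shape(9))
  expect_equal(one$distinct, 1)
  expect_equal(one$c_max, 1)
  expect_equal(one$effective, 1)
  # uniform random sequence against the birthday-style expectation
  L <- 1e6
  st <- distinct_kmer_stats(dna(L, seed = 17), seed_shape(11))
  expected <- (4^11 / 2) * (1 - (1 - 2 / 4^11)^(L - 11 + 1))
  expect_equal(st$distinct, expected, tolerance = 0.01)
})
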