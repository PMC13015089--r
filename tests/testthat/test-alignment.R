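test_that("the epsilon acceptance test uses exact integer arithmetic", {
  spec <- epsilon_spec(50, 5)
  expect_true(is_epsilon_match(50, 5, spec))    # boundary of the definition
  expect_false(is_epsilon_match(49, 0, spec))   # length bound
  expect_false(is_epsilon_match(100, 11, spec)) # rate bound
  expect_true(is_epsilon_match(100, 10, spec))
  expect_equal(is_epsilon_match(c(50, 49), c(0, 0), spec), c(TRUE, FALSE))
  expect_error(epsilon_spec(50, 50), "smaller")
})

test_that("identical sequences align to one full-span exact match", {
  withr::with_seed(101, {
    r <- random_dna(60)
    reg <- list(qstart = 0, qend = 60, dmin = 0, dmax = 0)
    m <- align_region(r, r, reg, epsilon_spec(50, 5))
    expect_equal(nrow(m), 1)
    expect_equal(m$length, 60L)
    expect_equal(m$errors, 0L)
    expect_equal(c(m$rstart, m$rend, m$qstart, m$qend), c(0L, 60L, 0L, 60L))
  })
})

test_that("error rates above the bound exclude the full span", {
  withr::with_seed(103, {
    r <- random_dna(60)
    chars <- strsplit(r, "")[[1]]
    pos <- c(5, 14, 23, 32, 41, 50, 58)  # 7 spread substitutions
    for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    q <- paste(chars, collapse = "")
    m <- align_region(r, q, list(qstart = 0, qend = 60, dmin = 0, dmax = 0),
                      epsilon_spec(50, 5))
    # 7/60 > 0.1: no reported match may span all 60 columns with 7 errors
    expect_true(all(m$errors * 50 <= m$length * 5))
    expect_true(all(m$length >= 50))
  })
})

test_that("reported path stats re-verify against an independent aligner", {
  withr::with_seed(107, {
    sim <- simulate_pair(2000, density = 600, error_rate = 0.04, seed = 17)
    res <- search_epsilon_matches(sim$seqA, sim$seqB, 50, 2, evalues = FALSE)
    expect_gt(nrow(res), 0)
    for (i in seq_len(nrow(res))) {
      a <- substr(sim$seqA[[1]], res$rstart[i] + 1, res$rend[i])
      b <- substr(sim$seqB[[1]], res$qstart[i] + 1, res$qend[i])
      ref_al <- biostrings_global(a, b)
      # the stored path restricted to this interval is one global alignment
      # of the substrings: the optimal global score bounds it
      expect_gte(ref_al$score, res$score[i])
      expect_true(is_epsilon_match(ref_al$n, ref_al$e, epsilon_spec(50, 2)))
      expect_true(is_epsilon_match(res$length[i], res$errors[i],
                                   epsilon_spec(50, 2)))
      # edit distance cannot exceed the path's error count
      expect_lte(adist(a, b)[1, 1], res$errors[i])
    }
  })
})

test_that("consolidation removes duplicates and keeps disjoint matches", {
  m <- tibble::tibble(
    ref_id = "r", rstart = c(10L, 10L, 500L), rend = c(120L, 120L, 620L),
    query_id = "q", qstart = c(5L, 5L, 700L), qend = c(115L, 115L, 820L),
    strand = "+", length = c(111L, 111L, 121L), errors = c(3L, 3L, 2L),
    score = c(99L, 99L, 113L))
  out <- consolidate(m)
  expect_equal(nrow(out), 2)
  expect_identical(as.data.frame(consolidate(out)), as.data.frame(out))
})

test_that("contained matches with more errors are dropped", {
  m <- tibble::tibble(
    ref_id = "r", rstart = c(100L, 110L), rend = c(400L, 300L),
    query_id = "q", qstart = c(100L, 110L), qend = c(400L, 300L),
    strand = "+", length = c(300L, 190L), errors = c(5L, 8L),
    score = c(280L, 150L))
  out <- consolidate(m)
  expect_equal(nrow(out), 1)
  expect_equal(out$rstart, 100L)
})

test_that("a long match split by segmentation consolidates to one match", {
  withr::with_seed(109, {
    sim <- simulate_pair(4000, density = 3999, error_rate = 0.04,
                         min_length = 300, max_length = 300, seed = 23)
    # force segments much shorter than the implant
    res <- search_epsilon_matches(sim$seqA, sim$seqB, 50, 2, bins = 20,
                                  evalues = FALSE)
    tr <- sim$truth[1, ]
    inside <- res$qstart <= tr$b_start + 25 & res$qend >= tr$b_end - 25
    expect_equal(sum(inside), 1)
  })
})

test_that("pipeline output equals the exhaustive enumerator on seeded pairs", {
  withr::with_seed(113, {
    specs <- list(c(50, 2), c(50, 3))
    for (i in 1:12) {
      sp <- specs[[(i %% 2) + 1]]
      sim <- simulate_pair(2000, density = 600,
                           error_rate = sp[2] / sp[1] * 0.9,
                           min_length = 50, max_length = 180,
                           seed = sample.int(2^30, 1))
      spec <- epsilon_spec(sp[1], sp[2])
      res <- search_epsilon_matches(sim$seqA, sim$seqB, sp[1], sp[2],
                                    evalues = FALSE)
      oracle <- enumerate_epsilon_matches(sim$seqA[[1]], sim$seqB[[1]], spec)
      # one match for one match, identical up to the co-optimal-path
      # boundary ambiguity of at most e_max columns
      expect_true(match_sets_equivalent(res, oracle, tol = sp[2]),
                  info = sprintf("pair %d", i))
    }
  })
})

test_that("searching the reverse-complemented query swaps strand labels", {
  withr::with_seed(127, {
    sim <- simulate_pair(3000, density = 1000, error_rate = 0.04, seed = 29)
    fw <- search_epsilon_matches(sim$seqA, sim$seqB, 50, 2, evalues = FALSE)
    rc <- search_epsilon_matches(sim$seqA, revcomp(sim$seqB[[1]]), 50, 2,
                                 evalues = FALSE)
    L <- nchar(sim$seqB[[1]])
    expect_equal(nrow(fw), nrow(rc))
    expect_true(all(fw$strand == "+"))
    expect_true(all(rc$strand == "-"))
    back <- data.frame(rstart = rc$rstart, rend = rc$rend,
                       qstart = L - rc$qend, qend = L - rc$qstart,
                       strand = "+")
    expect_true(match_sets_equivalent(back, fw, tol = 2))
  })
})

test_that("E-values scale with the search space and fall with score", {
  em <- evalue_model(1e4, 1e4)
  em2 <- evalue_model(2e4, 1e4, calibrate_pairs = 2, calibrate_len = 100)
  expect_gt(em$lambda, 0)
  expect_gt(em$K, 0)
  # doubling m doubles E at equal K/lambda
  expect_equal(evalue(40, em) * 2,
               em$K * 2 * em$m * em$n * exp(-em$lambda * 40))
  scores <- seq(20, 120, by = 20)
  ev <- evalue(scores, em)
  expect_true(all(diff(ev) < 0))
  # identical 100 bp self-match in a 10 kb x 10 kb space is essentially
  # impossible by chance
  expect_lt(evalue(100, em), 1e-20)
  expect_error(evalue(50, list(lambda = 1)), "uncalibrated")
})
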