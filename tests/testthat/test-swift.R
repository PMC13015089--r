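test_that("the q-gram index is exact", {
  idx <- build_qgram_index("ACGTACGT", q = 4)
  expect_equal(nrow(idx), 5)
  acgt <- idx$position[idx$value == idx$value[1]]
  expect_equal(sort(acgt), c(0L, 4L))
  expect_equal(nrow(build_qgram_index(character(0), 4)), 0)
  expect_error(build_qgram_index("ACGT", 3))
})

test_that("index lookups agree with a naive substring scan", {
  withr::with_seed(81, {
    q <- 6
    a <- random_dna(1000)
    idx <- build_qgram_index(a, q)
    # every recorded position really holds that q-gram, and all positions
    # of a probe q-gram are recovered
    for (probe in c("ACGTAC", substr(a, 11, 16), substr(a, 501, 506))) {
      naive <- integer(0)
      for (p in 1:(nchar(a) - q + 1)) {
        if (substr(a, p, p + q - 1) == probe) naive <- c(naive, p - 1)
      }
      packed <- sum(4^((q - 1):0) *
                      (match(strsplit(probe, "")[[1]],
                             c("A", "C", "G", "T")) - 1))
      expect_equal(sort(idx$position[idx$value == packed]), sort(naive))
    }
    expect_equal(nrow(idx), nchar(a) - q + 1)
  })
})

test_that("identical sequences give one merged region spanning diagonal 0", {
  withr::with_seed(83, {
    r <- random_dna(200)
    sw <- swift_scan(r, r, epsilon_spec(50, 5), q = 8)
    expect_equal(nrow(sw), 1)
    expect_lte(sw$dmin, 0)
    expect_gte(sw$dmax, 0)
    expect_lte(sw$qstart, 5)
    expect_gte(sw$qend, 195)
  })
})

test_that("sequences without shared q-grams give no regions", {
  sw <- swift_scan(strrep("A", 300), strrep("C", 300), epsilon_spec(50, 2))
  expect_equal(nrow(sw), 0)
})

test_that("implanted matches are always covered by an emitted region", {
  # 100 random pairs, one implanted epsilon(50,3)-match each
  withr::with_seed(87, {
    spec <- epsilon_spec(50, 3)
    covered <- 0L
    for (i in 1:100) {
      sim <- simulate_pair(2000, density = 1999, error_rate = 0.06,
                           min_length = 50, max_length = 250,
                           seed = sample.int(2^30, 1))
      tr <- sim$truth[1, ]
      sw <- swift_scan(sim$seqA[[1]], sim$seqB[[1]], spec)
      hit <- any(sw$qstart < tr$b_end & sw$qend > tr$b_start &
                   # diagonal band of the region intersects the implant's
                   sw$dmin <= (tr$a_end - tr$b_start) &
                   sw$dmax >= (tr$a_start - tr$b_end))
      covered <- covered + hit
    }
    expect_equal(covered, 100L)
  })
})

test_that("losslessness at the lemma threshold on exhaustive small fixtures", {
  # every true epsilon-match in 300 bp pairs intersects an emitted region
  withr::with_seed(91, {
    spec <- epsilon_spec(50, 2)
    for (i in 1:60) {
      sim <- simulate_pair(300, density = 299, error_rate = 0.04,
                           min_length = 50, max_length = 150,
                           seed = sample.int(2^30, 1))
      truth <- enumerate_epsilon_matches(sim$seqA[[1]], sim$seqB[[1]], spec,
                                         both_strands = FALSE)
      sw <- swift_scan(sim$seqA[[1]], sim$seqB[[1]], spec)
      for (j in seq_len(nrow(truth))) {
        expect_true(any(sw$qstart < truth$qend[j] &
                          sw$qend > truth$qstart[j]),
                    info = sprintf("pair %d match %d", i, j))
      }
    }
  })
})

test_that("emitted regions are disjoint after merging", {
  withr::with_seed(93, {
    for (i in 1:10) {
      sim <- simulate_pair(3000, density = 600, error_rate = 0.06,
                           min_length = 50, max_length = 200,
                           seed = sample.int(2^30, 1))
      sw <- swift_scan(sim$seqA[[1]], sim$seqB[[1]], epsilon_spec(50, 3))
      if (nrow(sw) > 1) {
        for (a in 1:(nrow(sw) - 1)) for (b in (a + 1):nrow(sw)) {
          q_ov <- sw$qstart[a] < sw$qend[b] & sw$qstart[b] < sw$qend[a]
          d_ov <- sw$dmin[a] <= sw$dmax[b] + 1 & sw$dmin[b] <= sw$dmax[a] + 1
          expect_false(q_ov && d_ov)
        }
      }
    }
  })
})
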