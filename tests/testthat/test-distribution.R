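make_prefilter_fixture <- function(seed, bins = 6, bin_len = 2000) {
  withr::with_seed(seed, {
    ref_seqs <- vapply(seq_len(bins), function(i) random_dna(bin_len),
                       character(1))
    shape <- seed_shape(16)
    vals <- lapply(ref_seqs, function(s) {
      ks <- kmer_stream(s, shape)
      ks$value[ks$valid]
    })
    list(ref_seqs = ref_seqs, shape = shape,
         ibf = ibf_build(vals, target_fpr = 0.001, h = 2, shape = shape))
  })
}

test_that("a verbatim copy of a bin's content flags that bin", {
  fx <- make_prefilter_fixture(131)
  spec <- epsilon_spec(50, 2)
  params <- list(shape = fx$shape, threshold = lemma_threshold(50, 2, 16))
  qseg <- substr(fx$ref_seqs[4], 301, 800)
  cand <- prefilter_query_segment(fx$ibf, qseg, params, spec)
  expect_true(4 %in% cand)
})

test_that("random queries rarely pass the lossless threshold", {
  fx <- make_prefilter_fixture(137)
  spec <- epsilon_spec(50, 2)
  params <- list(shape = fx$shape, threshold = lemma_threshold(50, 2, 16))
  withr::with_seed(139, {
    n_hit <- 0L
    for (i in 1:100) {
      cand <- prefilter_query_segment(fx$ibf, random_dna(1000), params, spec)
      n_hit <- n_hit + (length(cand) > 0)
    }
    expect_lte(n_hit, 5)
  })
})

test_that("threshold one fires on a single shared k-mer", {
  fx <- make_prefilter_fixture(149)
  spec <- epsilon_spec(50, 2)
  params <- list(shape = fx$shape, threshold = 1L)
  withr::with_seed(151, {
    # a random query carrying one 16-mer copied from bin 2
    qseg <- paste0(random_dna(200), substr(fx$ref_seqs[2], 101, 116),
                   random_dna(200))
    cand <- prefilter_query_segment(fx$ibf, qseg, params, spec)
    expect_true(2 %in% cand)
  })
})

test_that("segments shorter than the shape yield no candidates", {
  fx <- make_prefilter_fixture(157)
  params <- list(shape = fx$shape, threshold = 1L)
  expect_equal(prefilter_query_segment(fx$ibf, "ACGT", params,
                                       epsilon_spec(50, 2)),
               integer(0))
})

test_that("the repeat rule keeps the most variable half when abundant", {
  stats <- tibble::tibble(repetitiveness = c(0.9, 0.1, 0.5, 0.2, 0.8, 0.3,
                                             0.05, 0.6))
  # few candidates: untouched
  expect_equal(repeat_filter(c(1L, 5L), stats, 8), c(1L, 5L))
  expect_equal(repeat_filter(integer(0), stats, 8), integer(0))
  expect_equal(repeat_filter(1:4, stats, 8), 1:4)  # exactly b/2: untouched
  # all bins hit: ceil(b/2) most variable kept
  kept <- repeat_filter(1:8, stats, 8)
  expect_length(kept, 4)
  expect_setequal(kept, c(7L, 2L, 4L, 6L))  # smallest repetitiveness
  # fraction respected
  expect_length(repeat_filter(1:8, stats, 8, fraction = 0.25), 2)
})

test_that("empty query sets give empty results", {
  withr::with_seed(163, {
    ref <- c(r = random_dna(2000))
    res <- search_epsilon_matches(ref, c(q = strrep("N", 200)), 50, 2,
                                  evalues = FALSE)
    expect_equal(nrow(res), 0)
  })
})

test_that("results are invariant to batching and worker knobs", {
  sim <- implant_fixture(8000, 6, c(50, 200), 0.04, seed = 167)
  base <- search_epsilon_matches(sim$seqA, sim$seqB, 50, 2, evalues = FALSE)
  cols <- c("ref_id", "rstart", "rend", "query_id", "qstart", "qend",
            "strand", "length", "errors", "score")
  df <- function(x) {
    x <- as.data.frame(x)[, cols]
    rownames(x) <- NULL
    x
  }
  for (args in list(list(cart_capacity = 1),
                    list(cart_capacity = 64, max_full_carts = 1),
                    list(workers = 4))) {
    alt <- do.call(search_epsilon_matches,
                   c(list(sim$seqA, sim$seqB, 50, 2, evalues = FALSE), args))
    expect_equal(df(alt), df(base))
  }
})

test_that("every surviving (segment, bin) pair is processed exactly once", {
  sim <- implant_fixture(8000, 6, c(50, 200), 0.04, seed = 173)
  res <- search_epsilon_matches(sim$seqA, sim$seqB, 50, 2, evalues = FALSE,
                                cart_capacity = 3)
  processed <- attr(res, "processed")
  expect_gt(nrow(processed), 0)
  expect_equal(anyDuplicated(processed[, c("query_segment", "bin")]), 0L)
  # the funnel's candidate count equals the processed multiset size
  expect_equal(attr(res, "funnel")[["candidate_pairs"]], nrow(processed))
})

test_that("end-to-end sensitivity is complete with lossless parameters", {
  sim <- implant_fixture(30000, 15, c(50, 250), 0.04, seed = 179)
  res <- search_epsilon_matches(sim$seqA, sim$seqB, 50, 2, evalues = FALSE)
  ev <- evaluate_matches(res, sim$truth, 10)
  expect_true(isTRUE(attr(res, "params")$lossless))
  expect_equal(ev$missed, 0L)
})
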