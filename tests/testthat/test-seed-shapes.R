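test_that("shape parsing validates the pattern and derives span/weight", {
  s <- seed_shape("111010101101010111")
  expect_equal(s$span, 18L)
  expect_equal(s$weight, 12L)
  expect_equal(seed_shape("1")$span, 1L)
  expect_equal(seed_shape("1")$weight, 1L)
  expect_equal(seed_shape("11011")$span, 5L)
  expect_equal(seed_shape("11011")$weight, 4L)
  expect_equal(seed_shape(7)$pattern, "1111111")

  expect_error(seed_shape(""), "nonempty")
  expect_error(seed_shape("11012"), "0.*1|1.*0")
  expect_error(seed_shape("0110"), "care position")
  expect_error(seed_shape("110"), "care position")
  expect_error(seed_shape(0), "positive integer")
})

test_that("symmetry is pattern reversal invariance", {
  expect_true(is_symmetric(seed_shape("111010101101010111")))
  expect_false(is_symmetric(seed_shape("111010010100110111")))
  expect_true(is_symmetric(seed_shape("1")))
  expect_true(is_symmetric(seed_shape(9)))
})

test_that("adjacent k-mers of the default shape share 5 care positions", {
  # symmetric default: worst case over strands equals the same-strand AND
  expect_equal(adjacent_shared_positions(seed_shape("111010101101010111")),
               5L)
})

test_that("the asymmetric PatternHunter shape overlaps 8 positions with the
           adjacent forward k-mer in the canonical worst case", {
  expect_equal(adjacent_shared_positions(seed_shape("111010010100110111")),
               8L)
})

test_that("ungapped shapes share k-1 positions with their neighbour", {
  for (k in 1:8) {
    expect_equal(adjacent_shared_positions(seed_shape(k), "same_strand"),
                 max(0L, k - 1L))
  }
  # the gapped default beats the equal-weight ungapped shape: 5 < 11
  expect_lt(adjacent_shared_positions(seed_shape("111010101101010111")),
            adjacent_shared_positions(seed_shape(12)))
})

test_that("canonical k-mer stream matches a string-algebra reimplementation", {
  shp <- seed_shape("1101")
  seq <- dna(60, seed = 301)
  ks <- kmer_stream(seq, shp)
  expect_equal(nrow(ks), 60 - 4 + 1)
  # same canonical representative => same value; different => different
  canon <- vapply(ks$position, function(p) {
    canon_window(substr(seq, p + 1, p + shp$span), shp$pattern)
  }, character(1))
  expect_equal(anyDuplicated(ks$value) > 0, anyDuplicated(canon) > 0)
  grp_cpp <- split(seq_along(ks$value), ks$value)
  grp_str <- split(seq_along(canon), canon)
  expect_setequal(lapply(unname(grp_cpp), sort), lapply(unname(grp_str), sort))
})

test_that("a window and its reverse complement share one canonical value", {
  ks <- kmer_stream("ACGT", seed_shape("11"))
  expect_equal(nrow(ks), 3)
  expect_equal(ks$value[1], ks$value[3])  # AC and GT are reverse complements
  ks2 <- kmer_stream("AAAAA", seed_shape("11"))
  expect_equal(nrow(ks2), 4)
  expect_length(unique(ks2$value), 1)
})

test_that("windows covering non-ACGT residues are invalid", {
  ks <- kmer_stream("ACGNACGT", seed_shape("111"))
  expect_equal(ks$valid, c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(is.na(ks$value[!ks$valid])))
})

test_that("for symmetric shapes the value multiset is strand-invariant", {
  shp <- default_shape()
  withr::with_seed(99, {
    for (i in 1:100) {
      s <- random_dna(50)
      v1 <- kmer_stream(s, shp)$value
      v2 <- kmer_stream(revcomp(s), shp)$value
      expect_equal(rev(v2), v1)
    }
  })
})

test_that("the default shape family extends the gapped base seed", {
  expect_equal(shape_for_weight(12)$pattern, "111010101101010111")
  expect_equal(shape_for_weight(14)$pattern, "11101010110101011111")
  expect_equal(shape_for_weight(9)$pattern, "111111111")
  expect_equal(shape_for_weight(14)$weight, 14L)
})
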