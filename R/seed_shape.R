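#' Seed shapes for gapped k-mers
#'
#' A seed shape is a pattern of care (`1`) and do-not-care (`0`) positions
#' laid over a window of DNA. Only care positions contribute to the k-mer
#' value, so edits falling on the gaps do not destroy the k-mer. The number
#' of `1`s is the *weight* (the k-mer size in the statistical models), the
#' pattern length is the *span*. The default shape used throughout the
#' package is the symmetric 18-span, weight-12 shape
#' `111010101101010111`, whose adjacent canonical k-mers share only 5
#' positions.
#'
#' @param x either a string of `1`/`0` characters (first and last must be
#'   `1`), or a single positive integer giving an ungapped k-mer size.
#' @return an object of class `seed_shape` with fields `pattern`, `span`,
#'   `weight` and the 0-based care-position offsets `care`.
#' @examples
#' seed_shape("111010101101010111")
#' seed_shape(12) # ungapped 12-mer
#' @export
seed_shape <- function(x) {
  if (is.numeric(x)) {
    if (length(x) != 1 || is.na(x) || x < 1 || x != round(x)) {
      stop("ungapped shape size must be a single positive integer")
    }
    x <- strrep("1", x)
  }
  if (!is.character(x) || length(x) != 1 || !nzchar(x)) {
    stop("shape must be a nonempty string of 1s and 0s")
  }
  if (grepl("[^01]", x)) {
    stop("shape may only contain the characters '0' and '1'")
  }
  if (substr(x, 1, 1) != "1" || substr(x, nchar(x), nchar(x)) != "1") {
    stop("shape must start and end with a care position '1' ",
         "(a do-not-care border is a shorter shape)")
  }
  flags <- strsplit(x, "")[[1]] == "1"
  structure(
    list(pattern = x, span = nchar(x), weight = sum(flags),
         care = which(flags) - 1L),
    class = "seed_shape"
  )
}

#' @export
print.seed_shape <- function(x, ...) {
  cat("<seed_shape> ", x$pattern, " (span ", x$span, ", weight ", x$weight,
      if (is_symmetric(x)) ", symmetric" else ", asymmetric", ")\n", sep = "")
  invisible(x)
}

#' The package's default symmetric gapped seed
#'
#' @return the weight-12, span-18 symmetric [seed_shape()]
#'   `111010101101010111`.
#' @export
default_shape <- function() seed_shape("111010101101010111")

#' Default shape of a given weight
#'
#' The package's shape family: ungapped shapes below weight 12, the
#' symmetric 18-span gapped seed at weight 12, and its ungapped extensions
#' (care positions appended) above.
#'
#' @param weight k-mer weight (number of care positions).
#' @return a [seed_shape()].
#' @export
shape_for_weight <- function(weight) {
  base <- default_shape()
  if (weight < base$weight) {
    seed_shape(as.integer(weight))
  } else if (weight == base$weight) {
    base
  } else {
    seed_shape(paste0(base$pattern, strrep("1", weight - base$weight)))
  }
}

as_seed_shape <- function(x) {
  if (inherits(x, "seed_shape")) x else seed_shape(x)
}

#' Is a seed shape symmetric?
#'
#' A shape equal to its reversal places its gaps at the same offsets on both
#' strands, so the canonical (strand-minimum) k-mer of a window samples the
#' same genomic positions regardless of which strand wins.
#'
#' @param shape a [seed_shape()] (or a string/integer accepted by it).
#' @return `TRUE` iff the pattern equals its reversal.
#' @export
is_symmetric <- function(shape) {
  shape <- as_seed_shape(shape)
  p <- strsplit(shape$pattern, "")[[1]]
  identical(p, rev(p))
}

#' Care positions shared by adjacent k-mers
#'
#' Computes the number of care positions that two k-mers whose windows start
#' one residue apart read from the same sequence position, i.e. the weight
#' of the bitwise AND of the pattern with itself shifted by one. In
#' `canonical_worst_case` mode the first window may have been canonicalised
#' to the reverse strand, so the maximum over the pattern and its reversal
#' is taken. Fewer shared positions mean an edit is less likely to destroy
#' both k-mers, which is the rationale for gapped over ungapped seeds.
#'
#' @param shape a [seed_shape()].
#' @param mode `"canonical_worst_case"` (default) or `"same_strand"`.
#' @return a non-negative integer count of shared care positions.
#' @examples
#' adjacent_shared_positions(seed_shape("111010101101010111")) # 5
#' adjacent_shared_positions(seed_shape(12), "same_strand")    # 11
#' @export
adjacent_shared_positions <- function(shape,
                                      mode = c("canonical_worst_case",
                                               "same_strand")) {
  shape <- as_seed_shape(shape)
  mode <- match.arg(mode)
  p <- strsplit(shape$pattern, "")[[1]] == "1"
  span <- shape$span
  if (span == 1) return(0L)
  overlap <- function(first) {
    # first window at offset 0, second at offset +1; overlap columns are
    # window columns 1..span-1 of the first = columns 0..span-2 of the second
    sum(first[2:span] & p[1:(span - 1)])
  }
  if (mode == "same_strand") {
    as.integer(overlap(p))
  } else {
    as.integer(max(overlap(p), overlap(rev(p))))
  }
}

#' Canonical gapped k-mer stream of a sequence
#'
#' Slides the shape over the sequence and, at each window, 2-bit packs the
#' care-position residues of the window and of its reverse complement,
#' takes the smaller of the two (the canonical k-mer, making the stream
#' strand-symmetric) and passes it through a fixed 64-bit avalanche mixer.
#' Windows covering any non-ACGT residue are flagged invalid and carry an
#' `NA` value; downstream counting and indexing skip them.
#'
#' @param seq a single DNA string.
#' @param shape a [seed_shape()]; defaults to the package's symmetric
#'   18-span shape.
#' @return a tibble with one row per window: `position` (0-based window
#'   start), `value` (53-bit integer-valued double), `valid`.
#' @examples
#' kmer_stream("ACGT", seed_shape("11"))
#' @export
kmer_stream <- function(seq, shape = default_shape()) {
  shape <- as_seed_shape(shape)
  as_tibble(cpp_kmer_stream(seq, shape$pattern))
}
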