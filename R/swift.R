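#' Exact q-gram index over query segments
#'
#' Positions of every ungapped q-gram of the query segments, by value.
#' Exact (not probabilistic): this is the second, more specific filter
#' level that verifies Interleaved Bloom Filter hits.
#'
#' @param seqs character vector of query segment residues.
#' @param q word size (4 to 26).
#' @return a tibble with columns `segment` (1-based index into `seqs`),
#'   `position` (0-based), `value` (2-bit packed q-gram).
#' @export
build_qgram_index <- function(seqs, q) {
  stopifnot(q >= 4, q <= 26)
  as_tibble(cpp_qgram_positions(seqs, as.integer(q)))
}

#' Default q-gram size for the diagonal filter
#'
#' The largest lossless word size for the epsilon-match definition, capped
#' to the packable range. Short words (below 14, where chance q-gram hits
#' are plentiful at desk scale) are only used with a vote threshold of at
#' least 2, so the largest q whose counting-lemma threshold is >= 2 is
#' preferred there; a threshold of 1 would emit a candidate region around
#' every chance word hit.
#'
#' @param spec an [epsilon_spec()].
#' @return an integer word size.
#' @export
default_q <- function(spec) {
  spec <- as_epsilon_spec(spec)
  q_max <- max(4L, min(max_lossless_word_size(spec$l_min, spec$e_max), 26L))
  if (q_max >= 14L) return(q_max)
  for (q in seq(q_max, 5L)) {
    if (lemma_threshold(spec$l_min, spec$e_max, q) >= 2L) return(q)
  }
  q_max
}

#' Diagonal q-gram filter scan (SWIFT-style parallelogram counting)
#'
#' Every q-gram shared between the reference and a query segment votes at
#' (diagonal \eqn{d = ref\_pos - query\_pos}, query position). Votes are
#' counted inside parallelograms: query windows of `2 l_min` residues
#' crossed with diagonal buckets of power-of-two width at two half-offset
#' phases. A parallelogram reaching `threshold` votes is emitted as a
#' candidate region; qualifying parallelograms sharing hits and
#' overlapping regions are unioned. At the counting-lemma threshold the
#' filter is lossless: every epsilon-match contains an `l_min`-stretch
#' with at most `e_max` errors, whose surviving q-grams stay within
#' `e_max + 1` adjacent diagonals and fall whole into one window and one
#' bucket phase.
#'
#' @param ref_seq reference bin residues (a single string).
#' @param query_seqs character vector of query segment residues.
#' @param spec an [epsilon_spec()].
#' @param q word size; default [default_q()] of the spec.
#' @param threshold vote threshold; default
#'   `max(1, lemma_threshold(l_min, e_max, q))`.
#' @param e_band diagonal drift allowance per `l_min`-stretch; default
#'   `e_max`.
#' @param window query window length; default `2 * l_min`.
#' @return a tibble of candidate regions with columns `segment`, `qstart`,
#'   `qend` (0-based half-open query interval), `dmin`, `dmax` (diagonal
#'   band), `votes`.
#' @export
swift_scan <- function(ref_seq, query_seqs, spec, q = NULL, threshold = NULL,
                       e_band = NULL, window = NULL) {
  spec <- as_epsilon_spec(spec)
  if (is.null(q)) q <- default_q(spec)
  stopifnot(q >= 4, q <= 26)
  if (is.null(threshold)) {
    threshold <- max(1L, lemma_threshold(spec$l_min, spec$e_max, q))
  }
  if (is.null(e_band)) e_band <- spec$e_max
  if (is.null(window)) window <- 2L * spec$l_min
  as_tibble(cpp_swift_scan(ref_seq, query_seqs, as.integer(q),
                           as.integer(threshold), as.integer(e_band),
                           as.integer(window)))
}
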