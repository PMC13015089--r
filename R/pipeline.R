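#' Prefilter one query segment against the reference bins
#'
#' Slides a counting window of `2 * l_min` residues (stride
#' `ceil(l_min / 2)`) over the segment's canonical k-mer stream, counts
#' shared k-mers per bin through the Interleaved Bloom Filter, and reports
#' every bin whose count reaches the threshold in some window. Every
#' epsilon-match contains an `l_min`-stretch with at most `e_max` errors
#' (pigeonhole over its blocks), that stretch lies whole inside at least
#' one window, and it preserves at least the counting-lemma threshold of
#' k-mers -- so with lossless parameters and negligible index FPR the
#' result is a superset of the bins containing a true epsilon-match.
#'
#' @param ibf an [ibf_build()] index whose bins are reference segments.
#' @param seq query segment residues.
#' @param params a [deduce_params()] result, or a list with elements
#'   `shape` and `threshold`.
#' @param spec an [epsilon_spec()].
#' @param stride window stride; default `ceiling(l_min / 2)`.
#' @param window counting window length; default `2 * l_min`.
#' @return integer vector of candidate bin ids (1-based).
#' @export
prefilter_query_segment <- function(ibf, seq, params, spec, stride = NULL,
                                    window = NULL) {
  stopifnot(inherits(ibf, "ibf"))
  spec <- as_epsilon_spec(spec)
  shape <- as_seed_shape(params$shape)
  if (nchar(seq) < shape$span) return(integer(0))
  if (is.null(stride)) stride <- ceiling(spec$l_min / 2)
  if (is.null(window)) window <- 2L * spec$l_min
  ks <- cpp_kmer_stream(seq, shape$pattern)
  ok <- ks$valid
  counts <- cpp_ibf_window_max(ibf$bits, ibf$bin_count, ibf$bits_per_bin,
                               ibf$hash_count, ks$value[ok],
                               ks$position[ok], as.integer(window),
                               as.integer(stride), shape$span,
                               nchar(seq))
  which(counts >= params$threshold)
}

#' Repeat-aware bin selection
#'
#' When a query segment matches more than `fraction` of all reference
#' bins it is treated as repeat-derived and only the
#' \eqn{\lceil fraction \cdot b \rceil} most variable (least repetitive)
#' candidate bins are kept; queries matching few bins are searched in all
#' of them.
#'
#' @param candidates integer vector of candidate bin ids.
#' @param stats a tibble with one row per bin (in bin order) holding a
#'   `repetitiveness` column, as built from [segment_stats()].
#' @param bin_count total number of bins `b`.
#' @param fraction the abundance cutoff (default 0.5).
#' @return the filtered candidate bin ids.
#' @export
repeat_filter <- function(candidates, stats, bin_count, fraction = 0.5) {
  if (length(candidates) <= fraction * bin_count) return(candidates)
  keep_n <- ceiling(fraction * bin_count)
  rep_i <- stats$repetitiveness[candidates]
  rep_i[is.na(rep_i)] <- 1  # undefined stats treated as fully repetitive
  candidates[order(rep_i, candidates)][seq_len(keep_n)]
}

#' Search two sequence sets for all epsilon-matches
#'
#' The full four-stage workflow: split both sequence sets into overlapping
#' segments, index the reference segments in an Interleaved Bloom Filter,
#' prefilter each query segment into candidate bins (with repeat-aware bin
#' selection), batch the surviving (query segment, bin) pairs into carts,
#' verify each cart with the diagonal q-gram filter and align its candidate
#' regions with banded Waterman-Eggert on both strands, and finally
#' consolidate duplicates and segment-split fragments. The scheduler
#' processes carts in first-in-first-out order; results are deterministic
#' and independent of `workers`, `cart_capacity` and `max_full_carts`,
#' which only shape batching.
#'
#' @param ref,query named character vectors of DNA sequences (or paths or
#'   `DNAStringSet`s accepted by [read_fasta()]).
#' @param l_min,e_max the epsilon-match definition.
#' @param shape optional [seed_shape()] (string or integer k); when `NULL`
#'   the k-mer weight and threshold are deduced from the reference model
#'   via [deduce_params()].
#' @param bins number of reference segments / IBF bins; when `NULL` one
#'   bin per ~8 kb of reference (clamped to \[4, 1024\]), which keeps the
#'   per-bin spurious-candidacy probability of the deduced filter small at
#'   desk scale.
#' @param overlap segment overlap; default `2 * l_min`.
#' @param target_fpr,h IBF construction parameters.
#' @param repeat_fraction abundance cutoff for [repeat_filter()].
#' @param cart_capacity,max_full_carts,workers,chunk_size batching knobs
#'   (results are invariant to them).
#' @param q q-gram size for the second filter level; default
#'   [default_q()].
#' @param config an [align_config()].
#' @param evalues annotate matches with E-values (default `TRUE`).
#' @param verbose log the resolved configuration and the filter funnel.
#' @return a tibble of consolidated matches with columns `ref_id`,
#'   `rstart`, `rend`, `query_id`, `qstart`, `qend`, `strand`, `length`,
#'   `errors`, `score` and optionally `evalue` (coordinates 0-based
#'   half-open on the forward strands). Attributes: `params`
#'   (the filter parameters used), `funnel` (per-stage candidate counts),
#'   `processed` (the exactly-once (segment, bin) work list).
#' @export
search_epsilon_matches <- function(ref, query, l_min, e_max, shape = NULL,
                                   bins = NULL, overlap = NULL,
                                   target_fpr = 0.001, h = 2,
                                   repeat_fraction = 0.5,
                                   cart_capacity = 8, max_full_carts = 16,
                                   workers = 1, chunk_size = 1e6,
                                   q = NULL, config = align_config(),
                                   evalues = TRUE, verbose = FALSE) {
  spec <- epsilon_spec(l_min, e_max)
  ref <- as_seq_set(ref)
  query <- as_seq_set(query)
  if (is.null(overlap)) overlap <- 2L * spec$l_min
  if (is.null(bins)) {
    bins <- min(1024L, max(4L, floor(sum(nchar(ref)) / 8000)))
  }
  stopifnot(workers >= 1, cart_capacity >= 1, max_full_carts >= 1)

  ref_segments <- split_segments(ref, bins, overlap)
  ref_seqs_seg <- segment_sequences(ref, ref_segments)
  b <- nrow(ref_segments)

  # filter parameters: deduced from the reference model unless a shape is
  # given, in which case the lossless lemma threshold for its span is used
  model <- kmer_stats_model(sum(nchar(ref)),
                            bin_length = max(nchar(ref_seqs_seg)))
  if (is.null(shape)) {
    seg_len <- max(nchar(ref_seqs_seg))
    n_windows <- max(1, ceiling((seg_len - 2 * spec$l_min) /
                                  ceiling(spec$l_min / 2)) + 1)
    params <- deduce_params(model, spec, ibf_fpr = target_fpr,
                            windows_per_segment = n_windows)
  } else {
    sh <- as_seed_shape(shape)
    thr <- max(1L, lemma_threshold(spec$l_min, spec$e_max,
                                   min(sh$span, spec$l_min)))
    params <- list(shape = sh, threshold = thr,
                   lossless = lemma_threshold(spec$l_min, spec$e_max,
                                              min(sh$span, spec$l_min)) >= 1)
  }
  shape_used <- as_seed_shape(params$shape)
  if (is.null(q)) q <- default_q(spec)

  if (verbose) {
    message(sprintf(
      "epsmatch search: l_min=%d e_max=%d | shape %s (weight %d, t=%d, %s) | %d ref bins, overlap %d | IBF fpr %g h=%d | q=%d | carts cap=%d max=%d workers=%d chunk=%g",
      spec$l_min, spec$e_max, shape_used$pattern, shape_used$weight,
      params$threshold, if (isTRUE(params$lossless)) "lossless" else "heuristic",
      b, overlap, target_fpr, h, q, cart_capacity, max_full_carts, workers,
      chunk_size))
  }

  # reference index + per-bin repeat statistics
  bin_values <- lapply(ref_seqs_seg, function(s) {
    ks <- cpp_kmer_stream(s, shape_used$pattern)
    ks$value[ks$valid]
  })
  ibf <- ibf_build(bin_values, target_fpr = target_fpr, h = h,
                   shape = shape_used, segments = ref_segments)
  bin_stats <- dplyr::bind_rows(lapply(ref_seqs_seg, segment_stats,
                                       shape = shape_used))

  # query segments sized like reference bins, read in chunks
  seg_len_target <- max(nchar(ref_seqs_seg))
  n_query_segs <- max(1, ceiling(sum(nchar(query)) / seg_len_target))
  query_segments <- split_segments(query, n_query_segs, overlap)
  query_seqs_seg <- segment_sequences(query, query_segments)

  # Producer stage: prefilter + repeat rule -> (segment, bin) work list.
  # The abundance heuristic assumes many bins; with only a handful, a few
  # genuine matches already exceed half of them, so it is only armed from
  # 16 bins upward.
  candidates <- purrr::map(seq_len(nrow(query_segments)), function(i) {
    cand <- prefilter_query_segment(ibf, query_seqs_seg[i], params, spec)
    if (b >= 16) cand <- repeat_filter(cand, bin_stats, b, repeat_fraction)
    cand
  })
  processed <- tibble(
    query_segment = rep(seq_along(candidates),
                        vapply(candidates, length, integer(1))),
    bin = unlist(candidates, use.names = FALSE)
  )

  # cart queue: per-bin batches of query segments, FIFO, capacity-bounded
  carts <- build_carts(processed, cart_capacity)

  min_s <- min_match_score(config, spec)
  raw_matches <- list()
  funnel <- c(query_segments = nrow(query_segments),
              candidate_pairs = nrow(processed), carts = length(carts),
              regions = 0L, raw_matches = 0L)
  for (cart in carts) {
    bin <- cart$bin
    segs <- cart$segments
    bin_seq <- ref_seqs_seg[bin]
    bin_row <- ref_segments[bin, ]
    for (strand in c("+", "-")) {
      batch <- query_seqs_seg[segs]
      if (strand == "-") batch <- revcomp(batch)
      regions <- swift_scan(bin_seq, batch, spec, q = q)
      funnel["regions"] <- funnel["regions"] + nrow(regions)
      if (nrow(regions) == 0) next
      for (ri in seq_len(nrow(regions))) {
        reg <- regions[ri, ]
        seg_id <- segs[reg$segment]
        qrow <- query_segments[seg_id, ]
        qseq <- batch[reg$segment]
        loc <- align_region(bin_seq, qseq, reg, spec, config)
        if (nrow(loc) == 0) next
        funnel["raw_matches"] <- funnel["raw_matches"] + nrow(loc)
        seg_n <- nchar(qseq)
        if (strand == "+") {
          qs <- qrow$start + loc$qstart
          qe <- qrow$start + loc$qend
        } else {
          qs <- qrow$start + (seg_n - loc$qend)
          qe <- qrow$start + (seg_n - loc$qstart)
        }
        raw_matches[[length(raw_matches) + 1]] <- tibble(
          ref_id = bin_row$seq_id, rstart = bin_row$start + loc$rstart,
          rend = bin_row$start + loc$rend, query_id = qrow$seq_id,
          qstart = qs, qend = qe, strand = strand, length = loc$length,
          errors = loc$errors, score = loc$score)
      }
    }
  }
  matches <- if (length(raw_matches)) {
    dplyr::bind_rows(raw_matches)
  } else {
    tibble(ref_id = character(), rstart = integer(), rend = integer(),
           query_id = character(), qstart = integer(), qend = integer(),
           strand = character(), length = integer(), errors = integer(),
           score = integer())
  }
  matches <- consolidate(matches, ref, query, spec, config)
  if (evalues && nrow(matches) > 0) {
    em <- evalue_model(sum(nchar(ref)), sum(nchar(query)), config)
    matches$evalue <- evalue(matches$score, em)
  }
  if (verbose) {
    message(sprintf(
      "funnel: %d query segments -> %d (segment, bin) pairs -> %d carts -> %d regions -> %d raw -> %d consolidated matches",
      funnel["query_segments"], funnel["candidate_pairs"], funnel["carts"],
      funnel["regions"], funnel["raw_matches"], nrow(matches)))
  }
  structure(sort_local_matches(matches), params = params, funnel = funnel,
            processed = processed,
            class = c("epsmatch_result", class(matches)))
}

# FIFO cart construction: candidates arrive in query-segment order; a cart
# for a bin is closed once it holds `capacity` segments, and partial carts
# are flushed at end of input in bin order.
build_carts <- function(processed, capacity) {
  carts <- list()
  open <- list()
  for (i in seq_len(nrow(processed))) {
    bin <- processed$bin[i]
    key <- as.character(bin)
    open[[key]] <- c(open[[key]], processed$query_segment[i])
    if (length(open[[key]]) >= capacity) {
      carts[[length(carts) + 1]] <- list(bin = bin, segments = open[[key]])
      open[[key]] <- NULL
    }
  }
  for (key in as.character(sort(as.integer(names(open))))) {
    if (length(open[[key]]) > 0) {
      carts[[length(carts) + 1]] <- list(bin = as.integer(key),
                                         segments = open[[key]])
    }
  }
  carts
}

as_seq_set <- function(x) {
  if (is.character(x) && length(x) == 1 && !grepl("[ACGTNacgtn]{10}", x) &&
      file.exists(x)) {
    return(read_fasta(x))
  }
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(toupper(out))
  }
  stopifnot(is.character(x))
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  toupper(x)
}

#' @export
glance.epsmatch_result <- function(x, ...) {
  funnel <- attr(x, "funnel")
  tibble(matches = nrow(x), query_segments = funnel[["query_segments"]],
         candidate_pairs = funnel[["candidate_pairs"]],
         regions = funnel[["regions"]],
         total_errors = sum(x$errors), mean_length = mean(x$length))
}

#' Dotplot of an epsilon-match result
#'
#' @param object a [search_epsilon_matches()] result.
#' @param ... unused.
#' @return a ggplot: matches as segments in (reference, query) coordinate
#'   space, coloured by strand.
#' @export
autoplot.epsmatch_result <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$rstart, xend = .data$rend,
      y = ifelse(.data$strand == "+", .data$qstart, .data$qend),
      yend = ifelse(.data$strand == "+", .data$qend, .data$qstart),
      colour = .data$strand)) +
    ggplot2::facet_grid(.data$query_id ~ .data$ref_id) +
    ggplot2::labs(x = "reference (bp)", y = "query (bp)")
}
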