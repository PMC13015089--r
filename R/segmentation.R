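#' Split sequences into overlapping segments
#'
#' Splits each parent sequence into approximately equal segments that
#' overlap by `overlap` bp, so any local match of length up to
#' `overlap + 1` lies whole inside at least one segment; longer matches
#' split into pieces that consolidation re-merges. Segments never span
#' parent boundaries. The per-parent segment length is
#' \eqn{\lceil (L + (n - 1) \cdot overlap) / n \rceil}. Parents shorter
#' than the overlap become a single whole-parent segment. The total
#' segment budget is allocated to parents proportionally to length (at
#' least one each).
#'
#' @param parents a tibble/data.frame with columns `id` and `length`, or a
#'   named numeric vector of lengths, or a named character vector of
#'   sequences.
#' @param target_segments total number of segments to aim for (>= 1).
#' @param overlap overlap between consecutive segments in bp (>= 0).
#' @return a tibble with columns `bin` (1-based global segment index),
#'   `seq_id`, `segment` (1-based index within the parent), `start`, `end`
#'   (0-based half-open parent coordinates).
#' @examples
#' split_segments(c(chr1 = 100), target_segments = 2, overlap = 10)
#' @export
split_segments <- function(parents, target_segments, overlap) {
  stopifnot(target_segments >= 1, overlap >= 0)
  if (is.character(parents)) {
    parents <- tibble(id = names(parents), length = nchar(unname(parents)))
  } else if (is.numeric(parents)) {
    parents <- tibble(id = names(parents), length = unname(parents))
  } else {
    parents <- as_tibble(parents)
  }
  stopifnot(all(c("id", "length") %in% names(parents)),
            all(parents$length >= 1))
  np <- nrow(parents)
  # proportional allocation with largest remainders, at least 1 per parent
  share <- target_segments * parents$length / sum(parents$length)
  n_i <- pmax(1L, floor(share))
  rem <- target_segments - sum(n_i)
  if (rem > 0) {
    ord <- order(share - floor(share), decreasing = TRUE)
    take <- head(ord, rem)
    n_i[take] <- n_i[take] + 1L
  }
  rows <- purrr::map(seq_len(np), function(p) {
    L <- parents$length[p]
    n <- n_i[p]
    if (L <= overlap) n <- 1L
    # shrink n until segments are longer than the overlap
    repeat {
      len <- ceiling((L + (n - 1) * overlap) / n)
      if (n == 1 || len > overlap) break
      n <- n - 1L
    }
    start <- (seq_len(n) - 1L) * (len - overlap)
    end <- pmin(start + len, L)
    tibble(seq_id = parents$id[p], segment = seq_len(n),
           start = as.integer(start), end = as.integer(end))
  })
  out <- dplyr::bind_rows(rows)
  out$bin <- seq_len(nrow(out))
  out[, c("bin", "seq_id", "segment", "start", "end")]
}

#' Extract segment residues from a sequence set
#'
#' @param seqs named character vector of parent sequences.
#' @param segments a segment table from [split_segments()].
#' @return character vector of segment residues, in segment-table order.
#' @export
segment_sequences <- function(seqs, segments) {
  stopifnot(all(segments$seq_id %in% names(seqs)))
  vapply(seq_len(nrow(segments)), function(i) {
    substr(seqs[[segments$seq_id[i]]], segments$start[i] + 1, segments$end[i])
  }, character(1))
}

#' Variability and repetitiveness of a segment
#'
#' The variability of a segment is the fraction of distinct canonical
#' k-mers among all its k-mer windows,
#' \eqn{V_i = C_i / (L_i - span + 1)}; repetitiveness is
#' \eqn{R_i = 1 - V_i}, ranging from 0 (all k-mers unique) to close to 1
#' (a single repeated k-mer, e.g. an N stretch or homopolymer).
#'
#' @param seq segment residues (a single string).
#' @param shape a [seed_shape()].
#' @return a one-row tibble with `windows`, `distinct`, `variability`,
#'   `repetitiveness`, `defined` (`FALSE` when the segment is shorter than
#'   the shape span, in which case the stats are `NA`).
#' @export
segment_stats <- function(seq, shape = default_shape()) {
  shape <- as_seed_shape(shape)
  L <- nchar(seq)
  if (L < shape$span) {
    return(tibble(windows = 0L, distinct = NA_real_, variability = NA_real_,
                  repetitiveness = NA_real_, defined = FALSE))
  }
  windows <- L - shape$span + 1L
  C <- cpp_distinct_count(seq, shape$pattern)
  V <- C / windows
  tibble(windows = windows, distinct = C, variability = V,
         repetitiveness = 1 - V, defined = TRUE)
}

#' Write a segment table as BED
#'
#' @param segments a segment table from [split_segments()].
#' @param path output path (0-based half-open BED intervals).
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(segments$seq_id, segments$start, segments$end,
                    paste0("bin", segments$bin))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
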