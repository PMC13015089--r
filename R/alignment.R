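#' Alignment configuration
#'
#' Scoring and extension parameters for the banded Waterman-Eggert step.
#' Scores are edit-distance compatible linear gap costs: +1 match, -2
#' mismatch, -2 per gap column by default. The X-drop value bounds the
#' extension of each alignment path beyond its score-optimal core: the
#' outward extension stops once every cell of a row falls more than
#' `xdrop` below the best score seen. When `NULL` it defaults to
#' \eqn{2 |mismatch| \lceil e_{max}/2 \rceil} at alignment time.
#' `band_padding` widens the diagonal band around a candidate region;
#' when `NULL` it defaults to `2 e_max + 8`.
#'
#' @param match match reward (positive).
#' @param mismatch mismatch penalty (negative).
#' @param gap linear gap penalty per column (negative).
#' @param xdrop X-drop score, or `NULL` to derive it from the match definition at alignment time.
#' @param band_padding extra diagonals each side of a candidate band, or
#'   `NULL` to derive it from the match definition.
#' @return an object of class `align_config`.
#' @export
align_config <- function(match = 1, mismatch = -2, gap = -2, xdrop = NULL,
                         band_padding = NULL) {
  stopifnot(match > 0, mismatch < 0, gap < 0,
            is.null(xdrop) || xdrop > 0,
            is.null(band_padding) || band_padding >= 0)
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 xdrop = xdrop, band_padding = band_padding),
            class = "align_config")
}

config_xdrop <- function(config, spec) {
  if (!is.null(config$xdrop)) return(config$xdrop)
  max(1, 2 * abs(config$mismatch) * ceiling(spec$e_max / 2))
}

config_band_padding <- function(config, spec) {
  if (!is.null(config$band_padding)) return(config$band_padding)
  # a candidate region flanked by extensions can drift about 2 e_max
  # diagonals beyond the seeded band
  2L * spec$e_max + 8L
}

# lowest possible score of an epsilon-match: n = l_min columns of which
# e_max are gap columns
min_match_score <- function(config, spec) {
  (spec$l_min - spec$e_max) * config$match + spec$e_max * config$gap
}

#' Is (n, e) an epsilon-match?
#'
#' Integer-arithmetic test of the epsilon-match acceptance criterion:
#' \eqn{n \ge l_{min}} and \eqn{e \cdot l_{min} \le e_{max} \cdot n}.
#'
#' @param n alignment length in columns (vectorised).
#' @param e edit column count (vectorised).
#' @param spec an [epsilon_spec()].
#' @return logical vector.
#' @examples
#' is_epsilon_match(c(50, 49, 100, 100), c(5, 0, 10, 11), epsilon_spec(50, 5))
#' @export
is_epsilon_match <- function(n, e, spec) {
  spec <- as_epsilon_spec(spec)
  stopifnot(all(n >= 1), all(e >= 0))
  n >= spec$l_min & e * spec$l_min <= spec$e_max * n
}

#' Banded local alignment of a candidate region
#'
#' Runs the Waterman-Eggert multiple local alignment restricted to the
#' diagonal band of a candidate region (padded by `band_padding` diagonals
#' and by `l_min` + X-drop residues along the query axis), then cuts every
#' reported path into its maximal epsilon-feasible sub-alignments: each
#' reported match starts and ends on a match column, has
#' \eqn{n \ge l_{min}}, \eqn{e \, l_{min} \le e_{max} n}, and cannot be
#' extended to a longer feasible interval on its path.
#'
#' @param ref_seq reference residues (a single string).
#' @param query_seq query residues (a single string).
#' @param region a list or one-row data frame with `qstart`, `qend`,
#'   `dmin`, `dmax` (as produced by [swift_scan()]).
#' @param spec an [epsilon_spec()].
#' @param config an [align_config()].
#' @return a tibble of matches with 0-based half-open `rstart`, `rend`,
#'   `qstart`, `qend`, plus `length` (columns), `errors`, `score`.
#' @export
align_region <- function(ref_seq, query_seq, region, spec,
                         config = align_config()) {
  spec <- as_epsilon_spec(spec)
  region <- as.list(region)
  pad_q <- spec$l_min + config_xdrop(config, spec)
  pad_d <- config_band_padding(config, spec)
  dlo <- region$dmin - pad_d
  dhi <- region$dmax + pad_d
  if (dhi < dlo) return(empty_local_matches())
  out <- cpp_banded_we(ref_seq, query_seq,
                       as.integer(region$qstart - pad_q),
                       as.integer(region$qend + pad_q),
                       as.integer(dlo), as.integer(dhi),
                       spec$l_min, spec$e_max,
                       as.integer(config$match), as.integer(config$mismatch),
                       as.integer(config$gap),
                       as.integer(min_match_score(config, spec)),
                       256L, as.integer(config_xdrop(config, spec)))
  as_tibble(out)
}

empty_local_matches <- function() {
  tibble(rstart = integer(), rend = integer(), qstart = integer(),
         qend = integer(), length = integer(), errors = integer(),
         score = integer())
}

#' Exhaustive epsilon-match enumeration (reference implementation)
#'
#' Full-matrix Waterman-Eggert over the complete dynamic-programming
#' matrix, without any seeding, banding or filtering: successive
#' non-intersecting local alignments are reported in score order and cut
#' into maximal epsilon-feasible intervals exactly as the production
#' pipeline does. Quadratic in the sequence lengths, so only usable on
#' small inputs, where it serves as the ground truth the filter pipeline
#' is compared against.
#'
#' @param ref_seq reference residues.
#' @param query_seq query residues.
#' @param spec an [epsilon_spec()].
#' @param config an [align_config()].
#' @param both_strands also scan the reverse complement of the query and
#'   report minus-strand matches in forward query coordinates.
#' @return a tibble of matches (`rstart`, `rend`, `qstart`, `qend`,
#'   `length`, `errors`, `score`, `strand`).
#' @export
enumerate_epsilon_matches <- function(ref_seq, query_seq, spec,
                                      config = align_config(),
                                      both_strands = TRUE) {
  spec <- as_epsilon_spec(spec)
  ms <- min_match_score(config, spec)
  run1 <- function(qseq, strand) {
    out <- as_tibble(cpp_full_we(ref_seq, qseq, spec$l_min, spec$e_max,
                                 as.integer(config$match),
                                 as.integer(config$mismatch),
                                 as.integer(config$gap), as.integer(ms),
                                 1024L,
                                 as.integer(config_xdrop(config, spec))))
    if (strand == "-" && nrow(out) > 0) {
      L <- nchar(qseq)
      qs <- L - out$qend
      qe <- L - out$qstart
      out$qstart <- qs
      out$qend <- qe
    }
    out$strand <- rep(strand, nrow(out))
    out
  }
  res <- run1(query_seq, "+")
  if (both_strands) {
    res <- dplyr::bind_rows(res, run1(revcomp(query_seq), "-"))
  }
  # report the canonical maximal-match set (shadow re-alignments dropped)
  res$ref_id <- rep("ref", nrow(res))
  res$query_id <- rep("query", nrow(res))
  res <- dominant_matches(res, ceiling(spec$l_min / 2))
  res$ref_id <- NULL
  res$query_id <- NULL
  sort_local_matches(res)
}

sort_local_matches <- function(x) {
  if (nrow(x) == 0) return(x)
  x[order(x$rstart, x$qstart, x$rend, x$qend,
          if ("strand" %in% names(x)) x$strand else rep("", nrow(x))), ,
    drop = FALSE]
}

#' Consolidate matches from distributed search jobs
#'
#' Removes exact duplicates (the same match found via overlapping segments
#' or regions), drops matches whose reference and query intervals are both
#' contained in another match with no more errors, and re-merges fragments
#' of one long match that segmentation split: same-strand matches of one
#' (reference, query) pair whose intervals overlap or abut within
#' `join_gap` bp on compatible diagonals are re-aligned jointly over the
#' banded union region and replaced by the resulting maximal matches.
#' Idempotent.
#'
#' @param matches a match tibble in parent coordinates with columns
#'   `ref_id`, `rstart`, `rend`, `query_id`, `qstart`, `qend`, `strand`,
#'   `length`, `errors`, `score`.
#' @param ref_seqs,query_seqs named character vectors of parent sequences
#'   (needed for the re-merge step; may be omitted to skip merging).
#' @param spec an [epsilon_spec()].
#' @param config an [align_config()].
#' @param join_gap maximum gap between fragments to merge; default `l_min`.
#' @return the consolidated match tibble, sorted.
#' @export
consolidate <- function(matches, ref_seqs = NULL, query_seqs = NULL,
                        spec = NULL, config = align_config(),
                        join_gap = NULL) {
  if (nrow(matches) == 0) return(matches)
  matches <- dplyr::distinct(matches)
  # coordinate-equal duplicates that differ only in path stats: keep the
  # lowest-error (then best-score) record
  coord_cols <- intersect(c("ref_id", "rstart", "rend", "query_id",
                            "qstart", "qend", "strand"), names(matches))
  matches <- matches[order(matches$errors, -matches$score), , drop = FALSE]
  matches <- dplyr::distinct(matches, dplyr::across(dplyr::all_of(coord_cols)),
                             .keep_all = TRUE)
  if (!is.null(spec)) {
    spec <- as_epsilon_spec(spec)
    if (is.null(join_gap)) join_gap <- spec$l_min
    if (!is.null(ref_seqs) && !is.null(query_seqs)) {
      matches <- merge_fragments(matches, ref_seqs, query_seqs, spec, config,
                                 join_gap)
      matches <- dplyr::distinct(matches)
    }
    matches <- dominant_matches(matches, ceiling(spec$l_min / 2))
  }
  drop_contained(matches)
}

# Shadow suppression: successive Waterman-Eggert rounds emit progressively
# worse re-alignments of an already-reported match on nearby cells.  A match
# is a shadow of a better-scoring match when both its intervals lie inside
# the better match's intervals extended by `tol` bp.  Keeping only dominant
# matches makes the reported set the canonical maximal-match set; the same
# rule is applied to the exhaustive enumerator so the two are comparable.
dominant_matches <- function(m, tol) {
  if (nrow(m) <= 1) return(m)
  grp <- paste(m$ref_id, m$query_id, m$strand)
  keep <- rep(TRUE, nrow(m))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    mm <- m[idx, ]
    ord <- order(-mm$score, mm$rstart, mm$qstart, mm$rend, mm$qend)
    kept <- integer(0)
    for (a in ord) {
      dominated <- FALSE
      for (b in kept) {
        if (mm$rstart[a] >= mm$rstart[b] - tol &&
            mm$rend[a] <= mm$rend[b] + tol &&
            mm$qstart[a] >= mm$qstart[b] - tol &&
            mm$qend[a] <= mm$qend[b] + tol) {
          dominated <- TRUE
          break
        }
      }
      if (dominated) keep[idx[a]] <- FALSE else kept <- c(kept, a)
    }
  }
  m[keep, , drop = FALSE]
}

# containment rule: drop a match whose ref and query intervals both lie
# inside another match's, with at least as many errors
drop_contained <- function(m) {
  if (nrow(m) <= 1) return(sort_local_matches(m))
  keep <- rep(TRUE, nrow(m))
  grp <- paste(m$ref_id, m$query_id, m$strand)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    mm <- m[idx, ]
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a == b || !keep[idx[a]]) next
        contained <- mm$rstart[b] <= mm$rstart[a] && mm$rend[b] >= mm$rend[a] &&
          mm$qstart[b] <= mm$qstart[a] && mm$qend[b] >= mm$qend[a] &&
          (mm$rend[b] - mm$rstart[b] > mm$rend[a] - mm$rstart[a] ||
             mm$qend[b] - mm$qstart[b] > mm$qend[a] - mm$qstart[a])
        if (contained && mm$errors[a] >= mm$errors[b] && keep[idx[b]]) {
          keep[idx[a]] <- FALSE
        }
      }
    }
  }
  sort_local_matches(m[keep, , drop = FALSE])
}

merge_fragments <- function(m, ref_seqs, query_seqs, spec, config, join_gap) {
  grp <- paste(m$ref_id, m$query_id, m$strand)
  out <- list()
  d_join <- 2 * spec$e_max + 8
  for (g in unique(grp)) {
    mm <- m[grp == g, , drop = FALSE]
    n <- nrow(mm)
    if (n == 1) {
      out[[length(out) + 1]] <- mm
      next
    }
    # union-find over the joinable relation
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    # forward matches advance along d = r - q; minus-strand matches pair a
    # rising r with a falling forward-q, so their invariant is r + q
    strand <- mm$strand[1]
    diag_of <- function(i) {
      if (strand == "+") mm$rstart[i] - mm$qstart[i]
      else mm$rstart[i] + mm$qend[i]
    }
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        q_gap_ok <- mm$qstart[j] <= mm$qend[i] + join_gap &&
          mm$qstart[i] <= mm$qend[j] + join_gap
        r_gap_ok <- mm$rstart[j] <= mm$rend[i] + join_gap &&
          mm$rstart[i] <= mm$rend[j] + join_gap
        if (q_gap_ok && r_gap_ok &&
            abs(diag_of(i) - diag_of(j)) <= d_join) {
          ri <- find(i)
          rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      cl <- mm[roots == r, , drop = FALSE]
      if (nrow(cl) == 1) {
        out[[length(out) + 1]] <- cl
        next
      }
      out[[length(out) + 1]] <- realign_cluster(cl, ref_seqs, query_seqs,
                                                spec, config)
    }
  }
  dplyr::bind_rows(out)
}

# jointly re-align the bounding region of a fragment cluster
realign_cluster <- function(cl, ref_seqs, query_seqs, spec, config) {
  rid <- cl$ref_id[1]
  qid <- cl$query_id[1]
  strand <- cl$strand[1]
  pad <- spec$l_min
  Lr <- nchar(ref_seqs[[rid]])
  Lq <- nchar(query_seqs[[qid]])
  r0 <- max(0, min(cl$rstart) - pad)
  r1 <- min(Lr, max(cl$rend) + pad)
  q0 <- max(0, min(cl$qstart) - pad)
  q1 <- min(Lq, max(cl$qend) + pad)
  rsl <- substr(ref_seqs[[rid]], r0 + 1, r1)
  qsl <- substr(query_seqs[[qid]], q0 + 1, q1)
  if (strand == "-") qsl <- revcomp(qsl)
  # fragment corner diagonals in slice-local coordinates
  loc_q <- function(qs, qe) {
    if (strand == "+") c(qs - q0, qe - q0) else c(q1 - qe, q1 - qs)
  }
  ds <- unlist(lapply(seq_len(nrow(cl)), function(i) {
    ql <- loc_q(cl$qstart[i], cl$qend[i])
    c((cl$rstart[i] - r0) - ql[1], (cl$rend[i] - r0) - ql[2])
  }))
  pad_d <- config_band_padding(config, spec) + spec$e_max
  res <- cpp_banded_we(rsl, qsl, 0L, nchar(qsl),
                       as.integer(min(ds) - pad_d),
                       as.integer(max(ds) + pad_d),
                       spec$l_min, spec$e_max,
                       as.integer(config$match), as.integer(config$mismatch),
                       as.integer(config$gap),
                       as.integer(min_match_score(config, spec)), 256L,
                       as.integer(config_xdrop(config, spec)))
  res <- as_tibble(res)
  if (nrow(res) == 0) return(cl)  # keep fragments rather than lose a match
  if (strand == "+") {
    qs <- q0 + res$qstart
    qe <- q0 + res$qend
  } else {
    qs <- q1 - res$qend
    qe <- q1 - res$qstart
  }
  tibble(ref_id = rid, rstart = r0 + res$rstart, rend = r0 + res$rend,
         query_id = qid, qstart = qs, qend = qe, strand = strand,
         length = res$length, errors = res$errors, score = res$score)
}
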