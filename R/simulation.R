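#' Simulate a benchmark sequence pair with implanted local alignments
#'
#' Generates two i.i.d. uniform random DNA sequences of length `L`,
#' samples `floor(L / density)` substrings of sequence A with lengths
#' uniform in `[min_length, max_length]`, mutates each with exactly
#' `floor(error_rate * length)` edits (substitutions, insertions and
#' deletions equiprobable; substitution/deletion columns drawn uniformly
#' without replacement from the source, insertion positions uniformly
#' among the columns of the mutated string), and implants the mutated
#' substrings into sequence B at random non-overlapping positions (by
#' replacement, so B keeps length `L`). The planned error count is a hard
#' upper bound on the edit distance between source and implant, so every
#' implant of length `l` is an epsilon(l_min, ceiling(error_rate * l_min))
#' -match between A and B for any `l_min` up to `min_length`. Fully
#' reproducible from `seed`.
#'
#' @param L length of each sequence in bp.
#' @param density average bp of sequence per implanted alignment (one
#'   implant per `density` bp); must exceed the maximum match length.
#' @param error_rate edit fraction per implant in \[0, 1).
#' @param min_length,max_length implant length range in bp (50-250 by
#'   default).
#' @param seed RNG seed.
#' @return an object of class `epsmatch_sim`: a list with `seqA`, `seqB`
#'   (named character vectors of length 1) and `truth`, a tibble with one
#'   row per implant (`a_start`, `a_end`, `b_start`, `b_end` 0-based
#'   half-open, `length` of the implanted string, `errors` planned).
#' @export
simulate_pair <- function(L, density = 2000, error_rate = 0.05,
                          min_length = 50, max_length = 250, seed = 1) {
  stopifnot(L >= min_length, density > max_length, error_rate >= 0,
            error_rate < 1, min_length >= 1, max_length >= min_length)
  n_impl <- floor(L / density)
  with_seed(seed, {
    seqA <- random_dna(L)
    seqB_chars <- strsplit(random_dna(L), "")[[1]]
    lens <- if (n_impl > 0) {
      min_length + sample.int(max_length - min_length + 1, n_impl,
                              replace = TRUE) - 1L
    } else integer(0)
    rows <- vector("list", n_impl)
    occupied <- matrix(numeric(0), ncol = 2)  # placed b-intervals
    for (i in seq_len(n_impl)) {
      len <- lens[i]
      a_start <- sample.int(L - len + 1, 1) - 1L
      src <- substr(seqA, a_start + 1, a_start + len)
      mut <- mutate_sequence(src, floor(error_rate * len))
      mlen <- nchar(mut)
      b_start <- place_interval(L, mlen, occupied)
      occupied <- rbind(occupied, c(b_start, b_start + mlen))
      seqB_chars[(b_start + 1):(b_start + mlen)] <- strsplit(mut, "")[[1]]
      rows[[i]] <- tibble(a_start = a_start, a_end = a_start + len,
                          b_start = b_start, b_end = b_start + mlen,
                          length = mlen,
                          errors = as.integer(floor(error_rate * len)))
    }
    structure(
      list(seqA = c(A = seqA), seqB = c(B = paste(seqB_chars, collapse = "")),
           truth = if (n_impl > 0) dplyr::bind_rows(rows) else
             tibble(a_start = integer(), a_end = integer(),
                    b_start = integer(), b_end = integer(),
                    length = integer(), errors = integer()),
           L = L, density = density, error_rate = error_rate, seed = seed),
      class = "epsmatch_sim")
  })
}

# Apply exactly n_e edits to a DNA string: substitution and deletion
# columns are distinct interior source columns and insertions land between
# interior columns.  Border columns stay intact because a local alignment
# never starts or ends on an edit column -- an implant with a border edit
# would really be a shorter implant with fewer errors.
mutate_sequence <- function(src, n_e) {
  if (n_e == 0) return(src)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(src, "")[[1]]
  types <- sample(c("sub", "ins", "del"), n_e, replace = TRUE)
  n_sub <- sum(types == "sub")
  n_del <- sum(types == "del")
  n_ins <- sum(types == "ins")
  interior <- length(chars) - 2L
  if (n_sub + n_del > interior) {
    # degenerate tiny-source case: cap column edits at the interior size
    n_del <- max(0, interior - n_sub)
    n_sub <- min(n_sub, interior)
  }
  cols <- 1L + sample.int(interior, n_sub + n_del)
  sub_cols <- cols[seq_len(n_sub)]
  del_cols <- cols[setdiff(seq_len(n_sub + n_del), seq_len(n_sub))]
  for (p in sub_cols) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  if (n_del > 0) chars <- chars[-del_cols]
  for (j in seq_len(n_ins)) {
    pos <- sample.int(length(chars) - 1L, 1)  # after columns 1..len-1
    chars <- append(chars, sample(bases, 1), after = pos)
  }
  paste(chars, collapse = "")
}

# uniform non-overlapping placement by rejection; explicit failure when the
# packing is infeasible
place_interval <- function(L, len, occupied, max_tries = 10000) {
  for (try in seq_len(max_tries)) {
    s <- sample.int(L - len + 1, 1) - 1L
    if (nrow(occupied) == 0 ||
        all(s + len <= occupied[, 1] | s >= occupied[, 2])) {
      return(s)
    }
  }
  stop("could not place implant without overlap: density too small ",
       "for the requested match lengths")
}

#' @export
print.epsmatch_sim <- function(x, ...) {
  cat(sprintf(
    "<epsmatch_sim> %g bp pair, %d implants (error rate %.2f, seed %d)\n",
    x$L, nrow(x$truth), x$error_rate, x$seed))
  invisible(x)
}

#' Evaluate reported matches against the implant truth
#'
#' A truth record counts as found iff some reported match's query-side
#' (sequence B) interval overlaps its implant interval by at least
#' `min_overlap` bp (strict `>=`).
#'
#' @param found a match tibble with `qstart`, `qend` columns in sequence-B
#'   coordinates (e.g. from [search_epsilon_matches()] run with A as
#'   reference and B as query).
#' @param truth the truth tibble of [simulate_pair()].
#' @param min_overlap minimum overlap in bp (default 10).
#' @return an object of class `epsmatch_eval`: list with `records` (the
#'   truth tibble plus `found` and `best_overlap` columns), `total`,
#'   `missed` and `missed_fraction`. [tidy()] returns the per-record
#'   table, [glance()] the summary row.
#' @export
evaluate_matches <- function(found, truth, min_overlap = 10) {
  stopifnot(min_overlap >= 1)
  best <- vapply(seq_len(nrow(truth)), function(i) {
    if (nrow(found) == 0) return(0)
    ov <- pmin(found$qend, truth$b_end[i]) - pmax(found$qstart, truth$b_start[i])
    max(0, ov)
  }, numeric(1))
  records <- truth
  records$best_overlap <- best
  records$found <- best >= min_overlap
  missed <- sum(!records$found)
  structure(list(records = records, total = nrow(truth), missed = missed,
                 missed_fraction = if (nrow(truth) == 0) 0 else
                   missed / nrow(truth),
                 min_overlap = min_overlap),
            class = "epsmatch_eval")
}

#' @export
print.epsmatch_eval <- function(x, ...) {
  cat(sprintf("<epsmatch_eval> %d/%d implants missed (%.2f%%) at >= %d bp overlap\n",
              x$missed, x$total, 100 * x$missed_fraction, x$min_overlap))
  invisible(x)
}

#' @export
tidy.epsmatch_eval <- function(x, ...) x$records

#' @export
glance.epsmatch_eval <- function(x, ...) {
  tibble(total = x$total, missed = x$missed,
         missed_fraction = x$missed_fraction, min_overlap = x$min_overlap)
}
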