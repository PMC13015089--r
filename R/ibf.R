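#' Build an Interleaved Bloom Filter over reference bins
#'
#' One Bloom filter per reference bin, with the bits of all bins for each
#' hash position stored contiguously, so a single lookup yields the whole
#' bin-membership bit vector. The per-bin filter is sized as
#' \eqn{m = \lceil -h \cdot n_{max} / \ln(1 - fpr^{1/h}) \rceil} bits, with
#' `n_max` the largest per-bin k-mer set, which bounds the per-query false
#' positive probability by `target_fpr` at full occupancy. Inserted values
#' are always reported (no false negatives).
#'
#' @param bin_kmer_sets list of numeric vectors of canonical k-mer values
#'   (as produced by [kmer_stream()]), one per bin; `NA` values (invalid
#'   windows) are skipped.
#' @param target_fpr per-k-mer false positive bound in (0, 0.5].
#' @param h number of hash functions (default 2).
#' @param shape optional [seed_shape()] recorded for provenance checks.
#' @param segments optional segment table recorded alongside the index.
#' @return an object of class `ibf`.
#' @export
ibf_build <- function(bin_kmer_sets, target_fpr = 0.001, h = 2,
                      shape = NULL, segments = NULL) {
  if (!is.list(bin_kmer_sets) || length(bin_kmer_sets) == 0) {
    stop("bin_kmer_sets must be a nonempty list of k-mer value vectors")
  }
  if (!is.numeric(target_fpr) || target_fpr <= 0 || target_fpr > 0.5) {
    stop("target_fpr must lie in (0, 0.5]")
  }
  stopifnot(h >= 1, h <= 8)
  sets <- lapply(bin_kmer_sets, function(v) unique(as.numeric(v[!is.na(v)])))
  n_max <- max(1, vapply(sets, length, integer(1)))
  m <- ceiling(-h * n_max / log(1 - target_fpr^(1 / h)))
  bits <- cpp_ibf_build(sets, m, as.integer(h))
  structure(
    list(bits = bits, bin_count = length(sets), bits_per_bin = m,
         hash_count = as.integer(h), n_max = n_max,
         target_fpr = target_fpr,
         shape = if (is.null(shape)) NULL else as_seed_shape(shape),
         segments = segments),
    class = "ibf"
  )
}

#' @export
print.ibf <- function(x, ...) {
  cat(sprintf(
    "<ibf> %d bins x %s bits, %d hashes, target FPR %g (n_max %d)\n",
    x$bin_count, format(x$bits_per_bin, big.mark = ","), x$hash_count,
    x$target_fpr, x$n_max))
  invisible(x)
}

#' Query bin membership of one k-mer value
#'
#' @param ibf an [ibf_build()] index.
#' @param value a single canonical k-mer value.
#' @return a logical vector of length `bin_count`; bit i is set iff all
#'   hash positions of `value` are set in bin i (a superset of true
#'   containment).
#' @export
ibf_query <- function(ibf, value) {
  stopifnot(inherits(ibf, "ibf"), length(value) == 1)
  cpp_ibf_counts(ibf$bits, ibf$bin_count, ibf$bits_per_bin, ibf$hash_count,
                 as.numeric(value)) == 1L
}

#' Per-bin shared k-mer counts of a window of values
#'
#' @param ibf an [ibf_build()] index.
#' @param values ordered k-mer values of one query window (`NA`s skipped).
#' @return integer vector of per-bin counts; an upper bound on the true
#'   shared counts (one-sided error).
#' @export
ibf_count_window <- function(ibf, values) {
  stopifnot(inherits(ibf, "ibf"))
  cpp_ibf_counts(ibf$bits, ibf$bin_count, ibf$bits_per_bin, ibf$hash_count,
                 as.numeric(values))
}

IBF_MAGIC <- "EPSMIBF1"

#' Save / load an Interleaved Bloom Filter index
#'
#' Binary format: magic, version, bin count, bits per bin, hash count,
#' target FPR, shape string, segment table, then the raw bit store.
#'
#' @param ibf an [ibf_build()] index.
#' @param path file path.
#' @return `ibf_load()` returns the index; `ibf_save()` returns `path`
#'   invisibly.
#' @export
ibf_save <- function(ibf, path) {
  stopifnot(inherits(ibf, "ibf"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(IBF_MAGIC, con, eos = NULL)
  writeBin(1L, con)  # version
  writeBin(as.integer(ibf$bin_count), con)
  writeBin(as.numeric(ibf$bits_per_bin), con)
  writeBin(as.integer(ibf$hash_count), con)
  writeBin(as.integer(ibf$n_max), con)
  writeBin(as.numeric(ibf$target_fpr), con)
  shape_str <- if (is.null(ibf$shape)) "" else ibf$shape$pattern
  writeBin(nchar(shape_str), con)
  if (nzchar(shape_str)) writeChar(shape_str, con, eos = NULL)
  seg <- ibf$segments
  if (is.null(seg)) {
    writeBin(0L, con)
  } else {
    writeBin(nrow(seg), con)
    for (i in seq_len(nrow(seg))) {
      id <- as.character(seg$seq_id[i])
      writeBin(nchar(id), con)
      writeChar(id, con, eos = NULL)
      writeBin(as.integer(c(seg$segment[i], seg$start[i], seg$end[i])), con)
    }
  }
  writeBin(length(ibf$bits), con)
  writeBin(ibf$bits, con)
  invisible(path)
}

#' @rdname ibf_save
#' @export
ibf_load <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(IBF_MAGIC))
  if (!identical(magic, IBF_MAGIC)) stop("not an epsmatch IBF index: ", path)
  version <- readBin(con, integer(), 1)
  if (version != 1L) stop("unsupported index version ", version)
  b <- readBin(con, integer(), 1)
  m <- readBin(con, numeric(), 1)
  h <- readBin(con, integer(), 1)
  n_max <- readBin(con, integer(), 1)
  target_fpr <- readBin(con, numeric(), 1)
  ns <- readBin(con, integer(), 1)
  shape <- if (ns > 0) seed_shape(readChar(con, ns)) else NULL
  nseg <- readBin(con, integer(), 1)
  segments <- NULL
  if (nseg > 0) {
    rows <- purrr::map(seq_len(nseg), function(i) {
      nid <- readBin(con, integer(), 1)
      id <- readChar(con, nid)
      v <- readBin(con, integer(), 3)
      tibble(seq_id = id, segment = v[1], start = v[2], end = v[3])
    })
    segments <- dplyr::bind_rows(rows)
  }
  nbytes <- readBin(con, integer(), 1)
  bits <- readBin(con, raw(), nbytes)
  structure(
    list(bits = bits, bin_count = b, bits_per_bin = m, hash_count = h,
         n_max = n_max, target_fpr = target_fpr, shape = shape,
         segments = segments),
    class = "ibf"
  )
}
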