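#' Read a (possibly wrapped) FASTA file
#'
#' Residues are case-folded to upper case; sequence ids are the first
#' whitespace-delimited token of each header. IUPAC ambiguity codes other
#' than N are mapped to N (default) or rejected.
#'
#' @param path FASTA file path.
#' @param other how to treat ambiguity codes other than ACGTN: `"N"` maps
#'   them to N, `"error"` rejects the file.
#' @return a named character vector of sequences.
#' @export
read_fasta <- function(path, other = c("N", "error")) {
  other <- match.arg(other)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  has_other <- grepl("[^ACGTN]", seqs)
  if (any(has_other)) {
    if (other == "error") {
      stop("sequences contain ambiguity codes other than N: ",
           paste(names(seqs)[has_other], collapse = ", "))
    }
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write a match table
#'
#' `"tsv"` keeps the package's 0-based half-open coordinates; `"gff"`
#' writes GFF3-style 1-based closed intervals on the reference with the
#' query placement in the attributes column.
#'
#' @param matches a match tibble from [search_epsilon_matches()].
#' @param path output path.
#' @param format `"tsv"` or `"gff"`.
#' @export
write_matches <- function(matches, path, format = c("tsv", "gff")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(matches, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    ev <- if ("evalue" %in% names(matches)) {
      sprintf(";evalue=%.3g", matches$evalue)
    } else ""
    gff <- data.frame(
      seqid = matches$ref_id, source = "epsmatch", type = "match",
      start = matches$rstart + 1L, end = matches$rend,  # 1-based closed
      score = matches$score, strand = matches$strand, phase = ".",
      attributes = sprintf(
        "query=%s;qstart=%d;qend=%d;length=%d;errors=%d%s",
        matches$query_id, matches$qstart + 1L, matches$qend,
        matches$length, matches$errors, ev))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    utils::write.table(gff, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a match table written by [write_matches()]
#'
#' @param path TSV path.
#' @return a match tibble.
#' @export
read_matches <- function(path) {
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read the truth table of a simulated benchmark
#'
#' BED-like 0-based half-open TSV.
#'
#' @param truth the truth tibble of [simulate_pair()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
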