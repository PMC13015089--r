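# deterministic random DNA
dna <- function(n, seed = NULL) {
  if (is.null(seed)) return(random_dna(n))
  withr::with_seed(seed, random_dna(n))
}

# independent R-side survivor count for an error configuration: k-mer
# windows of an l-column alignment that avoid every error column
survivors_of <- function(l, err_cols, k) {
  runs <- diff(c(0L, sort(err_cols), l + 1L)) - 1L
  sum(pmax(0L, runs - k + 1L))
}

# independent R-side canonical gapped k-mer of one window (string algebra,
# no bit packing): used to cross-check the compiled stream
canon_window <- function(win, pattern) {
  care <- which(strsplit(pattern, "")[[1]] == "1")
  extract <- function(s) paste(strsplit(s, "")[[1]][care], collapse = "")
  f <- extract(win)
  r <- extract(revcomp(win))
  if (grepl("[^ACGT]", win)) NA_character_ else min(f, r)
}

# alignment stats (columns, edit columns) of a Biostrings global alignment
# under the package's default scoring; the independent alignment oracle
biostrings_global <- function(a, b, match = 1, mismatch = -2, gap = 2) {
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  al <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = sub,
                                      gapOpening = 0, gapExtension = gap,
                                      type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sbj <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  list(n = length(pat), e = sum(pat != sbj), score = Biostrings::score(al))
}

# One-to-one correspondence between two match sets: every match of one set
# pairs with exactly one match of the other on the same strand with every
# endpoint within `tol` bp.  Co-optimal Waterman-Eggert paths (same score,
# different error placement) can shift a maximal epsilon-interval boundary
# by up to about e_max columns depending on band clipping, so coordinate
# equality holds up to that ambiguity; tol = 0 demands exact equality.
match_sets_equivalent <- function(a, b, tol) {
  if (nrow(a) != nrow(b)) return(FALSE)
  if (nrow(a) == 0) return(TRUE)
  used <- rep(FALSE, nrow(b))
  for (i in seq_len(nrow(a))) {
    found <- FALSE
    for (j in which(!used)) {
      if (a$strand[i] == b$strand[j] &&
          abs(a$rstart[i] - b$rstart[j]) <= tol &&
          abs(a$rend[i] - b$rend[j]) <= tol &&
          abs(a$qstart[i] - b$qstart[j]) <= tol &&
          abs(a$qend[i] - b$qend[j]) <= tol) {
        used[j] <- TRUE
        found <- TRUE
        break
      }
    }
    if (!found) return(FALSE)
  }
  TRUE
}

# a reference/query pair with implanted epsilon-matches and known truth
implant_fixture <- function(L, n_implants, len_range, rate, seed,
                            density = NULL) {
  if (is.null(density)) density <- floor(L / n_implants)
  simulate_pair(L, density = density, error_rate = rate,
                min_length = len_range[1], max_length = len_range[2],
                seed = seed)
}
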