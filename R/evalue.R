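#' E-value model for local alignment scores
#'
#' Karlin-Altschul model \eqn{E = K m n e^{-\lambda S}} for the expected
#' number of chance local alignments scoring at least `S` in an
#' `m` x `n` search space. \eqn{\lambda} is solved exactly from the
#' ungapped lattice equation
#' \eqn{\sum_i p_i e^{\lambda s_i} = 1} for uniform DNA (match probability
#' 1/4). `K` has no closed form for these lattice scores with gaps folded
#' in, so it is calibrated once per model by counting maximal local
#' alignments above a low score cutoff on fixed-seed random sequence pairs
#' and inverting the model equation; E-values are annotation only (no
#' filtering is ever applied on them), so order-of-magnitude accuracy
#' suffices.
#'
#' @param m,n search space sizes (total reference and query lengths, bp).
#' @param config an [align_config()] providing the scoring.
#' @param calibrate_pairs,calibrate_len Monte Carlo calibration effort.
#' @return an object of class `evalue_model` with fields `lambda`, `K`,
#'   `m`, `n`.
#' @export
evalue_model <- function(m, n, config = align_config(),
                         calibrate_pairs = 20, calibrate_len = 300) {
  stopifnot(m > 0, n > 0)
  lambda <- ka_lambda(config)
  K <- ka_calibrate_K(config, lambda, calibrate_pairs, calibrate_len)
  structure(list(lambda = lambda, K = K, m = m, n = n, config = config),
            class = "evalue_model")
}

# solve sum p_i exp(lambda s_i) = 1 for the positive root
ka_lambda <- function(config) {
  f <- function(lam) {
    0.25 * exp(lam * config$match) + 0.75 * exp(lam * config$mismatch) - 1
  }
  uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

ka_calibrate_K <- function(config, lambda, pairs, len) {
  s0 <- 6L  # low cutoff so chance alignments are plentiful but maximal
  counts <- with_seed(423771L, {
    vapply(seq_len(pairs), function(i) {
      a <- random_dna(len)
      b <- random_dna(len)
      nrow(cpp_full_we(a, b, 1L, 0L, as.integer(config$match),
                       as.integer(config$mismatch), as.integer(config$gap),
                       s0, 100000L, 10L))
    }, numeric(1))
  })
  mean_count <- max(mean(counts), 1e-9)
  # the expected number of maximal alignments scoring >= s0 is
  # K m n exp(-lambda s0); invert for K
  mean_count / (as.numeric(len)^2 * exp(-lambda * s0))
}

#' @export
print.evalue_model <- function(x, ...) {
  cat(sprintf("<evalue_model> lambda = %.4f, K = %.4g, space %g x %g\n",
              x$lambda, x$K, x$m, x$n))
  invisible(x)
}

#' E-value of an alignment score
#'
#' @param score alignment score(s) under the model's scoring scheme.
#' @param model an [evalue_model()].
#' @return expected chance alignment count(s), \eqn{K m n e^{-\lambda S}}.
#' @export
evalue <- function(score, model) {
  if (!inherits(model, "evalue_model")) stop("uncalibrated E-value model")
  model$K * model$m * model$n * exp(-model$lambda * score)
}
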