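#' Epsilon-match specification
#'
#' An \eqn{\varepsilon(l_{min}, e_{max})}-match is a pairwise local
#' alignment of length \eqn{n \ge l_{min}} whose count of edit columns
#' \eqn{e} (substitutions, insertions or deletions) satisfies
#' \eqn{e/n \le e_{max}/l_{min}}.
#'
#' @param l_min minimum alignment length in bp (positive integer).
#' @param e_max maximum error count at length `l_min` (non-negative integer,
#'   strictly less than `l_min`).
#' @return an object of class `epsilon_spec`.
#' @examples
#' epsilon_spec(50, 5)
#' @export
epsilon_spec <- function(l_min, e_max) {
  stopifnot(length(l_min) == 1, length(e_max) == 1,
            l_min >= 1, e_max >= 0, l_min == round(l_min),
            e_max == round(e_max))
  if (e_max >= l_min) stop("e_max must be smaller than l_min")
  structure(list(l_min = as.integer(l_min), e_max = as.integer(e_max)),
            class = "epsilon_spec")
}

#' @export
print.epsilon_spec <- function(x, ...) {
  cat(sprintf("<epsilon_spec> l_min = %d, e_max = %d (error rate <= %.4f)\n",
              x$l_min, x$e_max, x$e_max / x$l_min))
  invisible(x)
}

as_epsilon_spec <- function(x) {
  if (inherits(x, "epsilon_spec")) return(x)
  if (is.numeric(x) && length(x) == 2) return(epsilon_spec(x[1], x[2]))
  stop("expected an epsilon_spec or a (l_min, e_max) pair")
}

#' k-mer counting lemma threshold
#'
#' Two sequences sharing a local alignment of length `l` with `e` edits
#' share at least \eqn{l + 1 - k(e + 1)} ungapped k-mers: each of the
#' \eqn{l - k + 1} windows is destroyed by at most one of the `e` edits,
#' and each edit destroys at most `k` windows. The value is clamped at 0.
#'
#' @param l alignment length in bp.
#' @param e number of edits.
#' @param k k-mer size (must not exceed `l`).
#' @return the lossless lower bound on the shared k-mer count.
#' @examples
#' lemma_threshold(50, 2, 16) # 3
#' @export
lemma_threshold <- function(l, e, k) {
  stopifnot(l >= 1, e >= 0, k >= 1)
  if (any(k > l)) stop("k must not exceed the alignment length l")
  pmax(0L, as.integer(l - k + 1 - k * e))
}

#' Largest k-mer size with a positive lossless threshold
#'
#' The largest word size `k` for which [lemma_threshold()] still guarantees
#' at least one shared k-mer, i.e. for which an exact-word filter is
#' guaranteed to find every match of length `l` with up to `e` edits.
#'
#' @inheritParams lemma_threshold
#' @return a positive integer word size.
#' @examples
#' max_lossless_word_size(50, 2) # 16
#' @export
max_lossless_word_size <- function(l, e) {
  # l + 1 - k(e + 1) >= 1  <=>  k <= l / (e + 1)
  max(1L, as.integer(floor(l / (e + 1))))
}

#' Expected occurrences of a canonical k-mer in random sequence
#'
#' Under an i.i.d. uniform model, a sequence of length `L` holds
#' \eqn{L - k + 1} k-mer draws from \eqn{4^k} words, of which half can be
#' observed as the canonical representative, giving
#' \eqn{E(x) = 2(L - k + 1)/4^k} expected occurrences per canonical k-mer.
#'
#' @param L sequence length in bp.
#' @param k k-mer weight.
#' @return expected occurrence count (non-negative real).
#' @examples
#' expected_occurrences(143e6, 11) # about 68.2
#' @export
expected_occurrences <- function(L, k) {
  stopifnot(all(L >= k))
  2 * (L - k + 1) / 4^k
}

#' Statistical model of a reference k-mer set
#'
#' Collects the quantities the spurious-match (false positive) model needs:
#' the total reference length, the bin (segment) length over which shared
#' k-mers are counted, and the effective-size coefficient `s_e` that
#' shrinks the assumed distinct k-mer diversity of real genomes relative to
#' random sequence (fewer distinct k-mers means each occurs more often, so
#' the per-k-mer spurious match probability rises).
#'
#' @param reference_length total reference length in bp.
#' @param bin_length length in bp of one reference bin; defaults to the full
#'   reference length.
#' @param sigma alphabet size (4 for DNA).
#' @param s_e effective-size coefficient in (0, 1]; default 0.65.
#' @return an object of class `kmer_stats_model`.
#' @export
kmer_stats_model <- function(reference_length, bin_length = reference_length,
                             sigma = 4, s_e = 0.65) {
  stopifnot(reference_length >= 1, bin_length >= 1,
            bin_length <= reference_length, s_e > 0, s_e <= 1)
  structure(list(reference_length = reference_length,
                 bin_length = bin_length, sigma = sigma, s_e = s_e),
            class = "kmer_stats_model")
}

#' Spurious k-mer match probability
#'
#' \eqn{P(x) = \min(1, E(x)/s_e)} where `E(x)` is the expected occurrence
#' count of a canonical k-mer in one reference bin. Dividing by the
#' effective-size coefficient raises the estimate for repeat-rich
#' references.
#'
#' @param model a [kmer_stats_model()].
#' @param k k-mer weight.
#' @return a probability in \[0, 1\].
#' @export
spurious_kmer_prob <- function(model, k) {
  stopifnot(inherits(model, "kmer_stats_model"))
  pmin(1, expected_occurrences(model$bin_length, k) / model$s_e)
}

#' Filter false negative rate over error configurations
#'
#' Fraction of the \eqn{C(l, e)} placements of `e` error columns among `l`
#' alignment columns that preserve fewer than `t` error-free ungapped
#' k-mer windows (a window survives iff all of its `k` columns are
#' error-free; the surviving count is the sum of
#' \eqn{\max(0, g - k + 1)} over the \eqn{e + 1} error-free runs of
#' lengths \eqn{g}). Computed by a dynamic program over (run index, columns
#' used, survivor budget); `method = "enumerate"` walks all configurations
#' and is the brute-force cross-check.
#'
#' @param l alignment length (columns).
#' @param e number of error columns.
#' @param k k-mer size.
#' @param t count threshold.
#' @param method `"dp"` (default) or `"enumerate"`.
#' @return the false negative probability in \[0, 1\].
#' @examples
#' fnr(50, 5, 12, 5) # about 0.198
#' @export
fnr <- function(l, e, k, t, method = c("dp", "enumerate")) {
  method <- match.arg(method)
  stopifnot(k >= 1, k <= l, e >= 0, e <= l, t >= 0)
  if (method == "dp") cpp_fnr_dp(l, e, k, t) else cpp_fnr_enum(l, e, k, t)
}

#' Filter false positive rate
#'
#' Upper binomial tail \eqn{P(X \ge t)} for \eqn{X \sim Bin(w, p)}: the
#' probability that a query window with `w` k-mer slots reaches the count
#' threshold `t` by chance when each k-mer matches spuriously with
#' probability `p`.
#'
#' @param w number of k-mer windows in the query region.
#' @param p spurious per-k-mer match probability.
#' @param t count threshold.
#' @return a probability in \[0, 1\].
#' @export
fpr <- function(w, p, t) {
  stopifnot(w >= 0, p >= 0, p <= 1, t >= 0)
  if (t == 0) return(1)
  pbinom(t - 1, w, p, lower.tail = FALSE)
}

#' Deduce k-mer weight and count threshold
#'
#' Picks the filter parameters for an epsilon-match search. If the largest
#' lossless word size \eqn{k^\* = \lfloor l_{min}/(e_{max}+1) \rfloor} has a
#' spurious match probability below 1 in the reference model, the lossless
#' path is taken: `k = k*` with the counting-lemma threshold (the filter
#' then has false negative rate 0 by construction). Otherwise no word size
#' is both lossless and specific, and the heuristic path minimises
#' \eqn{Cost(k, t) = FNR(l_{min}, e_{max}, k, t) + FPR(w, p(k), t)} over the
#' grid, breaking ties toward smaller `k`, then smaller `t`.
#'
#' @param model a [kmer_stats_model()] describing the reference.
#' @param spec an [epsilon_spec()].
#' @param k_range candidate k-mer weights for the heuristic grid.
#' @param t_range candidate count thresholds for the heuristic grid.
#' @param window_kmers number of k-mer slots per query window for the FPR
#'   model; defaults to `l_min - k + 1`.
#' @param ibf_fpr per-k-mer false positive probability of the membership
#'   index, added to the content-based spurious match probability when
#'   screening lossless candidates (0 = pure sequence-content model).
#' @param windows_per_segment number of count windows per query segment;
#'   the lossless screen requires the chance of a spurious bin candidacy
#'   across all windows of a segment to stay below `fpr_budget`.
#' @param fpr_budget acceptable per-segment spurious candidacy probability
#'   for the lossless path (default 0.1).
#' @return an object of class `filter_params` with fields `shape` (ungapped
#'   [seed_shape()] of the chosen weight), `threshold`, `lossless`, and the
#'   full cost `grid` tibble (columns `k`, `t`, `fnr`, `fpr`, `cost`).
#'   [tidy()] returns the grid, [glance()] the chosen cell, [autoplot()]
#'   draws the cost surface.
#' @examples
#' m <- kmer_stats_model(1e4, bin_length = 1e4)
#' deduce_params(m, epsilon_spec(50, 1))
#' @export
deduce_params <- function(model, spec, k_range = 7:23, t_range = 1:25,
                          window_kmers = NULL, ibf_fpr = 0,
                          windows_per_segment = 1, fpr_budget = 0.1) {
  stopifnot(inherits(model, "kmer_stats_model"))
  spec <- as_epsilon_spec(spec)
  if (length(k_range) == 0 || length(t_range) == 0) {
    stop("empty parameter grid")
  }
  # Lossless path: walk k down from the largest lossless word size and take
  # the first k whose lemma threshold the spurious-match model cannot reach:
  # the per-window false positive rate (counting window of 2 l_min residues,
  # see prefilter_query_segment) must keep the probability of a spurious
  # bin candidacy anywhere in a query segment below fpr_budget.
  k_star <- max_lossless_word_size(spec$l_min, spec$e_max)
  lossless_k <- NA_integer_
  for (k in seq(k_star, min(4L, k_star), by = -1)) {
    t_k <- lemma_threshold(spec$l_min, spec$e_max, k)
    if (t_k < 1) break
    p_k <- min(1, spurious_kmer_prob(model, k) + ibf_fpr)
    if (p_k >= 1) next
    w2 <- 2 * spec$l_min - k + 1
    seg_fpr <- 1 - (1 - fpr(w2, p_k, t_k))^windows_per_segment
    if (seg_fpr <= fpr_budget) {
      lossless_k <- k
      break
    }
  }
  lossless_ok <- !is.na(lossless_k)
  grid <- purrr::map_dfr(sort(unique(as.integer(k_range))), function(k) {
    if (k > spec$l_min) return(NULL)
    w <- if (is.null(window_kmers)) spec$l_min - k + 1 else window_kmers
    p <- spurious_kmer_prob(model, k)
    tmax <- max(t_range)
    counts <- cpp_fnr_counts(spec$l_min, spec$e_max, k, tmax)
    cum <- cumsum(counts)[seq_len(tmax)] / choose(spec$l_min, spec$e_max)
    ts <- sort(unique(as.integer(t_range)))
    tibble(k = k, t = ts,
           fnr = ifelse(ts == 0, 0, cum[pmax(ts, 1)]),
           fpr = vapply(ts, function(t) fpr(w, p, t), numeric(1)))
  })
  grid$cost <- grid$fnr + grid$fpr
  if (lossless_ok) {
    chosen <- list(k = lossless_k,
                   t = lemma_threshold(spec$l_min, spec$e_max, lossless_k),
                   lossless = TRUE)
    shape <- seed_shape(chosen$k)  # the lossless guarantee needs span = k
  } else {
    # Heuristic path: the reported grid keeps the plain FNR + FPR cost over
    # l_min-windows (the model's canonical form), but the cell actually
    # selected also has to survive deployment: its per-segment spurious
    # candidacy probability (counting windows of 2 l_min, index FPR folded
    # into p) is added to the FNR before taking the argmin.
    sel <- vapply(seq_len(nrow(grid)), function(i) {
      k <- grid$k[i]
      span_k <- shape_for_weight(k)$span
      w2 <- max(1, 2 * spec$l_min - span_k + 1)
      p_k <- min(1, spurious_kmer_prob(model, k) + ibf_fpr)
      1 - (1 - fpr(w2, p_k, grid$t[i]))^windows_per_segment
    }, numeric(1))
    ord <- order(grid$fnr + sel, grid$k, grid$t)
    best <- grid[ord[1], ]
    chosen <- list(k = best$k, t = best$t, lossless = FALSE)
    shape <- shape_for_weight(chosen$k)
  }
  structure(
    list(shape = shape, threshold = as.integer(chosen$t),
         lossless = chosen$lossless, grid = grid, model = model, spec = spec),
    class = "filter_params"
  )
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf("<filter_params> k-mer weight %d, threshold %d (%s path)\n",
              x$shape$weight, x$threshold,
              if (x$lossless) "lossless lemma" else "heuristic cost"))
  invisible(x)
}

#' @export
tidy.filter_params <- function(x, ...) x$grid

#' @export
glance.filter_params <- function(x, ...) {
  k <- x$shape$weight
  cell <- x$grid[x$grid$k == k & x$grid$t == x$threshold, ]
  tibble(k = k, t = x$threshold, lossless = x$lossless,
         fnr = if (x$lossless) 0 else cell$fnr[1],
         fpr = if (nrow(cell)) cell$fpr[1] else NA_real_,
         cost = if (x$lossless || !nrow(cell)) NA_real_ else cell$cost[1])
}

#' @export
autoplot.filter_params <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$k, y = .data$t,
                               fill = pmin(.data$cost, 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Cost", direction = -1) +
    ggplot2::labs(x = "k-mer weight", y = "count threshold",
                  title = "Cost(k, t) = FNR + FPR")
}

#' Distinct canonical k-mer statistics of a sequence
#'
#' Counts the distinct canonical k-mer values `C` of a sequence under a
#' shape and relates it to the maximum possible
#' \eqn{C_{max} = \min(L - span + 1, 4^{weight}/2)}; the ratio
#' `L_e = C / C_max` is the effective sequence size, below 1 for
#' repeat-rich sequences.
#'
#' @param seq a single DNA string.
#' @param shape a [seed_shape()].
#' @return a one-row tibble with columns `distinct`, `c_max`, `effective`.
#' @export
distinct_kmer_stats <- function(seq, shape = default_shape()) {
  shape <- as_seed_shape(shape)
  L <- nchar(seq)
  if (L < shape$span) stop("sequence shorter than the shape span")
  C <- cpp_distinct_count(seq, shape$pattern)
  c_max <- min(L - shape$span + 1, 4^shape$weight / 2)
  tibble(distinct = C, c_max = c_max, effective = C / c_max)
}
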