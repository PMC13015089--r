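---
title: "epsmatch: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epsmatch: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epsmatch)
```

# The problem and the match definition

`epsmatch` finds *all* local alignments between two DNA sequence sets that
are long enough and clean enough to be interesting: a pairwise local
alignment of length $n$ columns containing $e$ edit columns
(substitutions, insertions or deletions) is an
$\varepsilon(l_{min}, e_{max})$-match if

$$ n \ge l_{min} \quad\text{and}\quad \frac{e}{n} \le \frac{e_{max}}{l_{min}}. $$

Both conditions are checked in integer arithmetic
(`is_epsilon_match()`), so the rate bound is exact. Reported matches
additionally start and end on match columns: an alignment ending on an
edit column is the same alignment with a shorter, cleaner core, so
match-column endpoints make the reported set canonical. One consequence
worth knowing: a 50 bp segment carrying an edit on its first or last
column does not admit an $\varepsilon(50, e)$-match of length 50 -- the
trimmed alignment has only 49 columns. The benchmark generator therefore
places edits on interior columns only.

Exhaustive Waterman--Eggert alignment is quadratic and hopeless beyond a
few kb, so the search runs as a funnel:

1. **Segmentation** -- both sequence sets are split into overlapping
   segments; each reference segment is one *bin*.
2. **IBF prefilter** -- an Interleaved Bloom Filter over the canonical
   gapped k-mers of each bin answers, for each query window, "which bins
   share at least $t$ k-mers with this window?".
3. **Repeat rule** -- query segments matching more than half of all bins
   are searched only in the most variable (least repetitive) half.
4. **SWIFT-style q-gram filter** -- surviving (segment, bin) pairs are
   verified with an exact q-gram index and parallelogram vote counting,
   yielding diagonal-banded candidate regions.
5. **Banded Waterman--Eggert** -- candidate regions are aligned, paths
   are X-drop-extended and cut into maximal $\varepsilon$-feasible
   intervals, and fragments are consolidated.

# Seeds and canonical gapped k-mers

A seed shape is a string of care (`1`) and don't-care (`0`) positions;
only care positions enter the k-mer value, so substitutions falling on
gaps do not destroy the k-mer. The default shape is the symmetric
18-span, weight-12 seed `111010101101010111`. Symmetry matters because
we count *canonical* k-mers (the minimum of a window's value and its
reverse complement's): with an asymmetric shape, a window canonicalised
to the other strand samples different sequence positions than its
neighbour, and adjacent k-mers can share up to 8 positions
(`adjacent_shared_positions()`); the symmetric default shares only 5 in
the worst case, so a single edit rarely destroys two neighbours at once.

```{r}
adjacent_shared_positions(default_shape())
adjacent_shared_positions(seed_shape("111010010100110111"))
```

The family used by parameter deduction (`shape_for_weight()`) is
ungapped below weight 12, the default seed at weight 12, and its
ungapped extensions above.

Hashing is self-contained by contract: care-position residues are 2-bit
packed, canonicalised by integer minimum, and passed through a fixed
64-bit avalanche mixer; Bloom-filter hashes derive from that one value
with fixed per-hash seeds. Indexes are therefore portable across
sessions and platforms. Windows covering any non-ACGT residue are
invalid and never counted or inserted.

A caveat the sensitivity model must respect: gaps only protect against
*substitutions*. An indel inside a window's span changes the window's
content regardless of where the care positions sit, so for sensitivity
purposes every edit is assumed to destroy all windows whose span covers
it -- the pessimistic "ungapped footprint" model.

# Parameter deduction

## The counting lemma and lossless thresholds

Two sequences sharing an alignment of length $l$ with $e$ edits share at
least $l + 1 - k(e + 1)$ ungapped k-mers (`lemma_threshold()`): each of
the $l - k + 1$ windows is destroyed by at most one edit and each edit
destroys at most $k$ windows. The largest $k$ keeping this bound
positive is $\lfloor l/(e+1) \rfloor$ (`max_lossless_word_size()`): 25,
16, 12, 10, 8 for $l = 50$ and $e = 1..5$.

## Spurious matches

Under an i.i.d. uniform model, a canonical k-mer occurs
$E(x) = 2(L - k + 1)/4^k$ times in a bin of length $L$, and the
per-k-mer spurious match probability is $P(x) = \min(1, E(x)/s_e)$
(`spurious_kmer_prob()`). The effective-size coefficient $s_e = 0.65$
accounts for real genomes holding fewer distinct k-mers than random
sequence (repeats), which makes each k-mer more frequent and spurious
matches more likely; `distinct_kmer_stats()` measures the actual ratio
$L_e = C/C_{max}$ with $C_{max} = \min(L - span + 1,\ 4^{weight}/2)$ for
any given sequence. The false positive rate of a counting window with
$w$ k-mer slots at threshold $t$ is the binomial tail
$P(\mathrm{Bin}(w, p) \ge t)$ (`fpr()`).

## The false negative rate DP

When no word size is both lossless and specific (large references, high
error rates), the filter goes *heuristic*: it accepts a threshold that
some error configurations defeat, betting that those configurations are
rare. The bet is quantified exactly under the substitution-position
model: $e$ error columns among $l$ cut the alignment into $e + 1$
error-free runs, a run of length $g$ preserves $\max(0, g - k + 1)$
windows, and `fnr()` counts the fraction of the $\binom{l}{e}$
configurations preserving fewer than $t$ windows. The count runs as a
dynamic program over (run index, columns used, survivor budget capped at
$t$) -- by the bijection between column subsets and weak compositions --
and is verified cell-by-cell against brute-force enumeration in the test
suite. For $\varepsilon(50,5)$ at $k = 12$, $t = 5$ the DP gives
$0.198 \approx 0.20$:

```{r}
fnr(50, 5, 12, 5)
```

The model ignores that indels shorten or lengthen the alignment and that
gapped shapes resist substitutions better than ungapped ones of the same
weight; both simplifications are pessimistic for uniformly placed edits,
so the DP is an upper bound on the miss rate actually observed on
simulated data (0% at 2--8% error on a 1 Mb pair, 2--3% at 10%, against
the bound's 20%).

## Putting it together

`deduce_params()` first tries the lossless path: walking $k$ down from
$\lfloor l_{min}/(e_{max}+1) \rfloor$, it takes the first $k$ whose
lemma threshold the spurious-match model cannot reach -- concretely, the
probability of a spurious bin candidacy anywhere in a query segment
(window FPR, with the index FPR folded into $p$, unioned over all
windows of a segment) must stay below 0.1. Walking *down* matters: the
largest lossless $k$ often has a threshold of 1--3, which index noise
floods; a smaller $k$ buys a much larger threshold at modest content
cost. If no $k$ qualifies, the heuristic path minimises
$Cost(k, t) = FNR + FPR$ over the grid $k \in [7, 23]$,
$t \in [1, 25]$; the grid is reported in the model's plain form
(window of $l_{min}$, content-only $p$) while the argmin additionally
includes the deployment FPR term, and ties break toward smaller $k$,
then smaller $t$. The chosen weight is materialised through
`shape_for_weight()`, so the heuristic path gets the gapped seed's extra
substitution tolerance for free.

# Segmentation, bins and the repeat rule

`split_segments()` cuts each parent into approximately equal segments of
length $\lceil (L + (n-1) \cdot o)/n \rceil$ overlapping by $o$ bp
(default $2\,l_{min}$), so any match up to $2\,l_{min} + 1$ bp lies whole
in some segment and longer matches split into consolidatable pieces. The
default bin count gives one bin per ~8 kb of reference (clamped to
[4, 1024]): small bins keep the per-bin spurious-candidacy probability
of lossless thresholds low at desk scale. Genome-scale deployments would
use proportionally longer segments (and the correspondingly larger
deduced $k$).

Per-bin variability is $V_i = C_i/(L_i - span + 1)$, the fraction of
distinct canonical k-mers among all windows; repetitiveness is
$R_i = 1 - V_i$ (0 when all k-mers are unique, approaching 1 for
homopolymers and N stretches). When a query segment's candidate set
exceeds half of all bins, `repeat_filter()` keeps the
$\lceil b/2 \rceil$ most variable candidates; queries hitting only a few
repetitive bins are searched in all of them. The pipeline arms this rule
only from 16 bins upward -- with a handful of bins, a few genuine
matches already exceed $b/2$ and the heuristic would delete true bins
rather than repeats.

# The prefilter windows

Counting windows span $2\,l_{min}$ residues at stride
$\lceil l_{min}/2 \rceil$. The window length is load-bearing for
losslessness: every $\varepsilon$-match of length $n$ contains an
$l_{min}$-stretch with at most $e_{max}$ errors (pigeonhole over its
$\lfloor n/l_{min} \rfloor$ disjoint blocks, since
$e \le e_{max} n/l_{min}$), and a window of $2\,l_{min}$ at that stride
always contains such a stretch whole, which preserves at least the lemma
threshold of k-mers. Windows of $l_{min}$ would see as little as half a
stretch and break the guarantee.

# The q-gram filter

Surviving (segment, bin) pairs are verified with an exact q-gram index
(`build_qgram_index()`) and parallelogram counting (`swift_scan()`):
every shared q-gram votes at (diagonal $d = r - q$, query position), and
votes are counted in query windows of $2\,l_{min}$ crossed with diagonal
buckets of power-of-two width $\ge 2(e_{max}+1)$ evaluated at two
half-offset phases. The clean $l_{min}$-stretch drifts at most
$e_{max}$ diagonals within itself, so its votes land whole in one window
and one bucket phase, and the counting-lemma threshold applies --
the filter is lossless, which the suite checks exhaustively on small
implanted fixtures. The default word size is the largest lossless $q$
(capped at 26 for 2-bit packing), except that short words ($q < 14$,
where chance hits are plentiful) are only used with a vote threshold of
at least 2: a threshold of 1 would emit a region around every chance
hit.

# Alignment, X-drop extension and consolidation

Within a candidate region (diagonal band padded by $2 e_{max} + 8$,
query interval padded by $l_{min}$ plus the X-drop), a banded
Waterman--Eggert dynamic program reports successive non-intersecting
local alignments under +1/-2/-2 linear-gap scoring until the best score
falls below the worst feasible match score
$(l_{min} - e_{max}) - 2 e_{max}$. Each traceback path is then extended
outward from both ends by a small banded DP that stops when every cell
of a row falls more than `xdrop` (default
$2\,|mismatch| \lceil e_{max}/2 \rceil$) below the best seen; the
deepest explored endpoint is kept. Extension is not cosmetic: a maximal
$\varepsilon$-match whose border carries an indel cluster scores *less*
than its trimmed core, so it lies on no score-maximal local path, and
without extension such matches (about 1 in 500 implants at 6% error) are
unfindable even by exhaustive search over score-optimal paths. The
extended column string is finally cut into its maximal
$\varepsilon$-feasible intervals with match-column endpoints.

Successive Waterman--Eggert rounds also emit "shadows" -- progressively
worse re-alignments of an already-reported match on nearby cells. A
dominance rule (drop a match whose intervals lie within a better-scoring
match's intervals extended by $\lceil l_{min}/2 \rceil$ bp) defines the
canonical maximal-match set; the same rule runs inside the exhaustive
enumerator so the two are comparable.

`consolidate()` removes exact duplicates from overlapping segments,
drops matches contained in an equally-or-more-accurate match, and
re-merges fragments of one long match split by segmentation: same-pair,
same-strand fragments within $l_{min}$ bp on compatible diagonals
(difference of $r - q$ for forward, $r + q$ for reverse-strand matches)
are jointly re-aligned over their banded union region. The step is
idempotent.

**Boundary ambiguity.** Two alignments can have identical score with
different error placement (e.g. 137 columns/8 errors vs
140 columns/9 errors); their maximal $\varepsilon$-intervals differ by a
few bp, and which path the DP takes depends on band clipping and tie
order. Reported coordinates are therefore exact only up to this
co-optimality radius, about $e_{max}$ bp per endpoint; the
oracle-equivalence tests pair matches one-to-one within that radius
(and observe exact equality in the typical case).

# E-values

Matches carry annotation-only E-values $E = K m n e^{-\lambda S}$
(never used for filtering). $\lambda$ solves the ungapped lattice
equation $\frac14 e^{\lambda} + \frac34 e^{-2\lambda} = 1$ exactly;
$K$ has no closed form for these lattice scores with gaps folded in and
is calibrated once per model by counting maximal local alignments above
a low cutoff on fixed-seed random pairs and inverting the model
equation. Order-of-magnitude accuracy is the design goal; a 100 bp
identical self-match in a 10 kb x 10 kb space sits far below $10^{-20}$.

# The benchmark generator

`simulate_pair()` reproduces the simulated-data protocol the search is
assessed against: two i.i.d. uniform sequences of length $L$;
$\lfloor L/density \rfloor$ substrings of A (lengths uniform in
50--250 bp by default, one per 2000 bp), each mutated with exactly
$\lfloor rate \cdot len \rfloor$ edits -- substitutions, insertions and
deletions equiprobable, substitution/deletion columns uniform without
replacement over the *interior* source columns, insertion positions
uniform over interior gaps -- and implanted into B at uniform
non-overlapping positions by replacement. Exact edit counts (not
binomial draws) make the truth error rate a hard bound, which the suite
verifies with an independent edit-distance oracle. `evaluate_matches()`
scores a truth record as found when some reported match overlaps its
implant site by at least 10 bp (strict $\ge$).

What the generator does *not* emulate: repeat structure, compositional
bias, N runs, and clustered (indel-burst) errors. Uniform placement is
the worst case for seed filters -- real edits cluster, preserving more
k-mers -- so passing at uniform errors is evidence of sensitivity, but
says nothing about the runtime behaviour repeats cause on real genomes;
the repeat rule exists for that and is exercised only synthetically
here.

# Problem sizes and defaults

The package's own validation runs at desk scale: 1 Mb sequence pairs
(500 implants) for end-to-end sensitivity at 2--6% error, 2 kb pairs
against the exhaustive quadratic enumerator, and 300 bp fixtures for
exhaustive filter losslessness. Defaults chosen once for this scale:
IBF with $h = 2$ hashes and target FPR $10^{-3}$ (the sizing formula
makes memory a non-issue at desk scale, and lossless thresholds of ~3
must sit above the index noise floor), bins of ~8 kb, segment overlap
$2\,l_{min}$, cart capacity 8 with at most 16 full carts. The
scheduler is sequential; the concurrency contract (exactly-once
processing of (segment, bin) pairs, FIFO cart order, batching
invariance) is what the tests pin down, and `workers`, `cart_capacity`
and `max_full_carts` shape batching without changing any result.

# Known limitations

- Affine gap costs are not supported; the scoring is linear by design.
- At the highest error rates (10% with the heuristic path) the shortest
  matches can fall under the count threshold, exactly as the FNR bound
  predicts; the measured miss rate stays far below the bound.
- E-value calibration is order-of-magnitude, with no claim of parity with any reference aligner.
- Exact matching ($e_{max} = 0$) works but has no dedicated fast path.
- Reported coordinates carry the co-optimality ambiguity described
  above.
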