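---
title: "Methods: models, statistics and design choices in motifkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and design choices in motifkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifkit)
```

# Scope and data model

`motifkit` analyses unaligned DNA, RNA or protein sequences for fixed-width
motifs. A motif is a `w × K` letter-probability matrix over the `K` core
symbols of its alphabet; no insertions or deletions are representable.
Sequences are validated against the core symbols plus the IUPAC ambiguity
codes, uppercased on ingest (repeat-masked input commonly arrives as
lowercase or `N`-masked text), and ambiguity letters are scored everywhere
as the background-weighted average over their expansion — so `N`-masked
stretches are neutral rather than silently dropped. All information measures
and scores use log base 2 (bits), matching sequence-logo conventions.

Background models are order-0 letter distributions. Frequencies are
estimated with an additive pseudocount (default 1) and must be strictly
positive, which every downstream log-odds computation relies on.
Higher-order Markov backgrounds are out of scope.

# Probabilistic discovery by EM

`run_em()` implements expectation–maximization over the latent site
positions of a fixed-width motif, under three site-count models:

* **OOPS** — exactly one site per sequence; window posteriors are a softmax
  of the window log-likelihood ratios and sum to 1 per sequence.
* **ZOOPS** — zero or one site; a per-sequence site probability `γ`
  (initialized at 0.5, an uninformative start) is re-estimated at every
  M-step as the mean posterior site mass.
* **ANR** — any number of repetitions; each window carries an independent
  Bernoulli site prior `γ`, re-estimated as the mean window posterior.

Nucleotide searches include both strands by default (each minus-strand
window enters as an additional admissible offset); protein searches are
single-stranded. The M-step re-estimates motif probabilities from
posterior-weighted letter counts plus background-proportional pseudocounts
(`α·b(a)` with `α = 0.01` total mass per position). Because the M-step
maximizes a Dirichlet-penalized expected complete-data likelihood, the
quantity EM provably never decreases is the penalized objective (log2
likelihood ratio plus the pseudocount log-prior); `run_em()` reports that
objective as its `trace`, and the test suite asserts its monotonicity to
within 1e-9. The unpenalized likelihood ratio of the final parameters is
returned separately as `llr`. Iteration stops at a relative objective change
below `tol` (default 1e-6) or `max_iter` (default 200).

**Seeding.** Every observed width-`w` subsequence (both strands) is a
candidate start: the observed word receives match probability 0.7, the
remainder spread evenly, which keeps seed matrices strictly positive.
Candidates are ranked by their one-pass OOPS likelihood, computed jointly
for all candidates with a sparse one-hot match-count factorization. At
larger problem sizes the candidate list and the evaluation windows are
thinned by deterministic even strides (`max_candidates = 2000`,
`max_eval_windows = 5000`); this is the standard subsampled-starting-point
strategy and keeps seeding linear in practice. Ties are broken by the
canonical (strand-symmetric) word ordering, which makes the whole search
equivariant under reverse complementing the input — the discovered motif is
then reproducible up to an arbitrary strand orientation.

**Multiple motifs.** After each accepted motif, every position covered by a
window with posterior `z` has its weight multiplied by `1 − z` (windows with
`z ≤ 0.01` are skipped as numerically irrelevant); subsequent rounds weight
window priors by the product of their covered positions' weights. This
probabilistic erasing prevents rediscovery without hard-masking sequence.

**Significance.** The E-value estimate is
`E = n_tests · exp(−max(0, LLR − LLR₀))`, with `n_tests` the number of
seeded starts examined. `LLR₀` is the expected best-fit log2 likelihood
ratio on background-only data, fitted once by linear regression on 50
background-only seeded-EM simulations spanning widths 6–15, set sizes 5–31
and both the 4- and 20-letter alphabets:
`LLR₀ = 1.042·w(K−1)/(2 ln 2) + 2.669·w − 0.938·log2(n_windows)`.
The dominant term is the chi-square-like overfitting gain of the `w(K−1)`
free parameters. The estimate is intentionally conservative and is meant
for ranking fits within a search and for planted-versus-null contrasts, not
as an exact tail probability; it is monotone decreasing in the likelihood
ratio and linear in the number of starts tested.

# Discrete discriminative discovery

`discover_words()` enumerates every exact word of length 3–8 (the range
where word enumeration is exhaustive and cheap; configurable) present in
the positive set and scores sequence-level enrichment against a negative
set with the one-sided hypergeometric tail — counting each sequence once,
with or without the word, keeps the 2×2 table exact and robust to repeated
occurrences. When no negatives are supplied, a per-sequence
dinucleotide-preserving Eulerian-path shuffle (random arborescence of last
edges, then random edge orderings) builds the control, preserving each
sequence's length and dinucleotide counts exactly. The best word is
generalized greedily: single-position IUPAC relaxations are accepted while
the p-value strictly improves. E-values are Bonferroni products of the
p-value and the running count of words actually tested; accepted words are
masked with the wildcard before the next round, so no word is reported
twice. The reported motif for each word is estimated from its matching
sites in the positive set.

# Scanning and occurrence statistics

`motif_to_logodds()` maps bit scores affinely onto integers
`0..quantization_bins` (default 1000; the p-value dynamic program costs
`O(w · bins · K)`, and 1000 quanta keep the quantization error below half a
per-mille of the score range). `score_pvalue_table()` convolves the
per-position integer score distributions under the background to get the
exact null distribution of the window score, hence exact p-values up to
quantization. Scanning (`scan_motifs()`) scores every window on every
requested strand; the default report threshold is `p ≤ 1e-4`, the
conventional site-level cutoff for occurrence reports. Minus-strand hits are
reported in forward coordinates with reverse-complemented matched text.
Both-strand scores at one position are counted as two separate tests —
the simplest correct multiple-testing accounting — and q-values are
Benjamini–Hochberg with `m` equal to the number of *scored* windows, not
the number of emitted hits; sub-threshold windows are still tests, and the
calibration property (the fraction of null windows with `p ≤ t` matching
`t`) depends on this. Windows with more than 50% wildcards can be dropped
with `skip_masked = TRUE`; by default masked windows score neutrally rather
than vanishing.

# Sequence-level scoring

For each motif, a sequence's best window p-value is corrected for the
number of windows scanned with the minimum-of-uniforms tail
`1 − (1 − p_min)^n`; both-strand windows are pooled into `n`. The
per-motif values are combined with the exact tail of a product of
independent uniforms, `x · Σ_{k=0}^{n−1} (−ln x)^k / k!`, evaluated in log
space. E-values multiply by the number of sequences scanned. Block diagrams
select non-overlapping sites greedily by p-value below 1e-4 and draw
heights proportional to `−log10 p` truncated at the 1e-10 level, so a
single extreme site does not dominate the rendering.

Two approximations matter here: overlapping windows are positively
dependent, and integer-score p-values are discrete. Both leave a systematic
few-percent deviation from uniformity in null combined p-values (clearly
visible with consensus-like motifs, which have only ~w distinct score
levels). The test suite therefore checks null uniformity with smooth
Dirichlet motifs at a 0.05 Kolmogorov–Smirnov tolerance; treat combined
p-values as well-calibrated rankings rather than exact tail probabilities.

# Motif comparison

`best_alignment()` searches all ungapped offsets with at least
`min_overlap = 4` overlapping columns (the floor suppresses spurious
single-column matches) and both orientations for nucleotide motifs. Column
similarity defaults to the Pearson correlation of the probability columns
(0 for constant columns); non-overlapping query columns contribute the
metric's null value — 0 for Pearson, the negated distance to the background
column for the Euclidean metric — so short overlaps cannot win by default.
Ties break toward larger overlap, then smaller absolute offset, then the
forward orientation. Significance is a Monte-Carlo permutation null: the
observed best score is referred to best scores against 1000 column-shuffled
copies of the target, `p = (1 + #null ≥ obs) / 1001`. The permutation null
is assumption-light and exactly testable; its resolution is bounded below
by 1/1001, so ranks, not magnitudes, carry meaning at the floor.

# Central enrichment

For equal-length sequences (unequal lengths are rejected — positional
enrichment is undefined otherwise), each sequence contributes the center
offset of its best-p window, provided that p passes the site threshold
(default 1e-3, balancing site yield against noise at ChIP-peak scale; ties
resolve to the leftmost start, then the forward strand). Nested centered
windows over the admissible start positions are tested with binomial right
tails, `π` being the window's fraction of admissible positions, and the
smallest p is Bonferroni-multiplied by the number of windows tested.
Centered, symmetric windows keep the family one-dimensional and the
correction simple and conservative; the null-calibration test measures the
realized false-positive rate of the adjusted p directly. Only site
*positions* enter the test — discovery never sees positional information
(the pipeline passes sequences in shuffled order) — so central enrichment
is an independent check on discovered motifs.

# The synthetic-data generator

`generate_planted_dataset()` draws sequences i.i.d. from the background
and writes planted sites over them: each planted column is sampled from the
motif row, mutated back to background at the per-column mutation rate, and
placed uniformly or with a Gaussian centered on the sequence midpoint.
Overlapping plants are re-drawn up to 100 times. The generator emulates the
two features the statistics rely on — a conserved pattern against an
order-0 background, and (optionally) central positional concentration. It
does **not** emulate repeat structure, compositional heterogeneity,
higher-order dependence, or correlated peaks, so green tests here certify
the algorithms and their calibration under their stated assumptions, not
performance on real genomes.

Study-condition defaults used by the tests and the acceptance script, all
chosen once up front: planted-recovery runs use 10 sequences × 100 bp with
an ~13-bit 8-mer motif at mutation level `p_match = 0.95`, 20 replicate
seeds; scan calibration uses 100 000 background windows; centrality uses
200 sequences of length 200 with Gaussian placement `sd = L/10`; the
end-to-end peak pipeline uses 200 peaks × 500 bp with the planted motif in
80% of peaks at `sd = L/10` against a 10-motif database. At pipeline scale
the EM stage runs 5 seeded starts at a single width with `tol = 1e-5` and
at most 60 iterations — converged consensus recovery at a fraction of the
full-precision cost — while module-level calls keep the precise defaults.

# Numerical and degenerate-input choices

* Quantization round trip: integer scores invert to bits within half a
  quantum; an all-equal score matrix degenerates to a single mass at zero
  with p-value 1.
* MEME-format probability rows are printed to 6 decimals with
  largest-remainder rounding so every printed row sums to exactly 1; parsed
  files therefore round-trip byte-identically, and rows are renormalized
  only when they deviate beyond the motif tolerance (1e-6) yet pass the
  format tolerance (0.01).
* Typed motifs parse with no pseudocount, transcribing counts exactly
  (zero probabilities are legal in a motif; only log-odds conversion
  requires positivity and applies its own pseudocount). A 4×4 numeric block
  is orientation-ambiguous; rows-as-positions wins, a documented
  deterministic tie-break. A probability matrix is assigned `nsites = 20`
  so pseudocount arithmetic has an effective site count.
* `combine_pvalues()` and `best_hit_pvalues()` clip to `(0, 1]` and guard
  underflow via log-space evaluation and `expm1`/`log1p`.
* All stochastic components thread one integer seed through named
  sub-streams (`withr::with_seed`), so every stage is independently
  reproducible and whole runs are byte-deterministic.

# Known limitations

* Fixed-width, ungapped motifs only; no position-specific priors; order-0
  backgrounds.
* The EM E-value is a calibrated heuristic bound, not an exact statistic;
  its absolute scale should not be compared across tools.
* Combined sequence p-values inherit window-dependence bias (see above).
* The comparison null has 1/1001 resolution, and word discovery's Bonferroni
  E-values are conservative by construction.
* Word discovery is nucleotide-only; protein discovery goes through the EM
  engine.
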