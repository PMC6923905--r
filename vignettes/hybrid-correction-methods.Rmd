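---
title: "Hybrid long-read error correction: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid long-read error correction: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hylec)
```

## The problem

Third-generation long reads (PacBio-class) run to tens of kilobases but
carry ~13% errors, dominated by insertions and deletions; second-generation
short reads (Illumina-class) carry ~1% errors, almost all substitutions.
`hylec` corrects the long reads with the short reads: it never aligns reads
to each other, only consults the k-mer coverage spectrum of the short-read
set, stored as a coverage-annotated de Bruijn graph (DBG).

The package implements the full method plus a simulator with exact per-base
ground truth and an evaluation suite, so every stage is testable without
external data.

## The de Bruijn graph

Every k-mer window (default k = 21) of every short read becomes a vertex
holding its occurrence count (*coverage*); consecutive windows record
single-character in/out edges, from which neighbor k-mers are reconstructed
by prepending/appending the character to the (k−1)-prefix/suffix. Counts
are exact (hash map, constant-time lookup); at desk scale a genome's
spectrum fits comfortably in memory.

By default k-mers are *canonical*: a k-mer and its reverse complement merge
into one vertex keyed by the lexicographically smaller string. Short reads
sample both genomic strands, so single-strand counting would halve the
effective coverage of every k-mer and make the weak/strong threshold
strand-dependent. `canonical = FALSE` restores literal single-strand
counting. Edges are stored in the canonical orientation and presented in
whichever literal orientation a query uses (complement-swapped masks), so
graph traversal works on literal sequence space.

k is capped at 32 (2-bit packing into one machine word). k = 21 keeps
4^k vastly larger than any desk-scale genome while leaving 80 informative
windows per 100 bp fragment.

## Indel correction: weak regions and widest paths

A long read is profiled against the graph: k-mer index `i` is *weak* when
`coverage(read[i..i+k)) < tau` (default `tau = 3`; windows containing `N`
count as weak), *strong* otherwise. Maximal runs form alternating regions.
With ~13% errors and k = 21 only ~5% of windows are error-free, so strong
k-mers are sparse anchors and weak regions average ~18 windows.

Each weak region flanked by strong regions on both sides is reassembled:
the last k-mer of the left strong region and the first k-mer of the right
strong region become source and destination, and the region between them is
replaced by the spelled sequence of the *widest path* — the path maximizing
the minimum vertex coverage along it, endpoints included. The rationale:
among alternative local assemblies, a path through a sequencing-error
k-mer is betrayed by its low bottleneck coverage, so maximizing the
bottleneck prefers the genuine genomic walk even when error k-mers have
locally high coverage.

The search is a Dijkstra variant on a max-priority queue keyed by
(width descending, length ascending), with lazy deletion and re-expansion
only on a strictly better label; ties break towards the lexicographically
smaller next k-mer, making every correction deterministic. Two ablation
strategies are provided for comparison: `shortest` (plain BFS, the
LoRDEC-style choice) and `greedy` (always descend to the highest-coverage
neighbor, backtracking after `b = 100` successive vertices, aborting when
the reachable space is exhausted).

Numerical/engineering choices:

* **Path length bound.** An unbounded bottleneck search in a cyclic DBG can
  wander; the search is capped at
  `ceiling(max_len_factor * (weak span in k-mers + 2))` vertices
  (`max_len_factor = 2`), enough for deletion-heavy regions whose true path
  is longer than the corrupted span. Under a binding bound the
  vertex-labeled search is no longer guaranteed optimal; the oracle tests
  exercise the non-binding regime, and in practice weak spans are short.
  A hard expansion budget (500k pops) guards against pathological tangles.
* **Width over vertices.** Counts live on vertices, so path width is the
  minimum *vertex* coverage including both endpoints.
* **No trimming.** Regions with no qualifying path, and weak regions at
  read ends (only one anchor), are left unchanged; every input read yields
  exactly one output read and strong-region bases are emitted verbatim.
  Read tips up to the first strong k-mer therefore remain uncorrected —
  visible as the residual ~0.5% error in the evaluation below.
* **Splice arithmetic.** 0-based half-open coordinates in k-mer index
  space; the replacement spans from the start of the source k-mer to the
  end of the destination k-mer, both of which the path reproduces exactly,
  so flanks are preserved by construction.

## Substitution correction: median skew and voting

After indel correction (and from the short reads themselves) residual
substitutions remain. The read is cut into fragments of `frag_len = 100`
bases — a typical short-read length, so k-mer abundances within a fragment
are expected to be homogeneous. A fragment owns the windows *starting*
inside it; each extends up to k−1 bases past the fragment end. (Defining
ownership as "windows fully inside" would orphan the k−1 windows straddling
every boundary, and a substitution at a fragment start would leave at most
one visible error window.) A final fragment shorter than `frag_len` is
ignored — too short for stable statistics.

Each fragment's coverage vector is summarized by Pearson's median skew
coefficient, `3 * (mean − median) / sd` with the population standard
deviation (the fragment is the whole population of its windows; `0` when
`sd = 0`). Three regimes:

* median below `low_factor * spectrum_median` (`low_factor = 0.5`):
  **true_low**, a genuinely low-coverage genomic region. Never treated as
  error, whatever its skew — the skew of small discrete counts jumps past
  ±0.3 on jitter alone, so gating this class on skew would break the
  protection it exists to provide. The cost is a blind spot: substitutions
  inside deeply low-coverage regions are not corrected.
* skew in `[-0.3, 0.3]`: **true_balanced**. The interval is symmetric and
  near zero, matching the "almost zero skew" signature of a balanced
  histogram; it is configurable (`skew_low`, `skew_high`).
* otherwise **error**: the histogram is dominated by high-coverage k-mers
  with a few low outliers dragging the mean below the median. Split into
  `error_high` / `error_low` by fragment median vs spectrum median.

The *spectrum median* used here is instance-weighted
(`spectrum_median(graph, weighted = TRUE)`): with realistic 1%-error short
reads, distinct error k-mers outnumber distinct true k-mers and push the
unweighted median to 1, which is useless as a coverage reference. The
instance-weighted median tracks the typical genomic coverage and is robust
to error k-mers. The unweighted variant remains the exported default of
`spectrum_median()` for spectrum inspection.

One sensitivity fallback: a `true_balanced` fragment that nevertheless
contains windows below `tau_low` is routed into localization anyway. A
read-end substitution leaves ≤ 4 visible error windows out of 100 — it
moves the skew by ~0.03, far inside any usable interval — yet in a
well-covered area a sub-solid window is a near-certain error. The voting
step, not the classifier, is the precision guard.

Within an error fragment, windows with coverage below `tau_low` (default =
`tau`) are error k-mers. A position is a candidate when every owned window
overlapping it is an error k-mer; for maximal error runs of ≤ k windows
(the footprint of an isolated substitution) the intersection of the run's
windows is flagged — for an isolated substitution both rules name exactly
the substituted base. Each candidate is re-voted: all four bases are
substituted in turn and every overlapping window (clipped to the read; the
only option that does not fabricate sequence) is looked up; a base
qualifies when all windows reach the area threshold, and the qualifying
base maximizing the minimum window coverage wins (ties alphabetically).
No qualifying base means no edit. Corrections apply left to right on the
evolving sequence, so a fixed error un-blocks voting at its neighbors.
Output length always equals input length.

Thresholds: `thresh_low = tau_low` in low-coverage areas. In high-coverage
areas `thresh_high = max(tau_low, ceiling(spectrum_median / 4))`: requiring
every voted window to reach the spectrum median itself would reject the
true base almost always (about half of all genuine windows sit below the
median of a Poisson-like spectrum), while a quarter of the median still
separates genuine coverage (~40×) from error k-mers (≤ 2) by an order of
magnitude.

## The simulator

`simulate_reference` draws i.i.d. bases at a target GC (optionally pasting
a substring to extra loci to create repeats and DBG branching);
`simulate_short_reads` places reads uniformly on both strands to a target
coverage with i.i.d. substitutions; `simulate_long_reads` draws lognormal
lengths (sdlog 0.1) and per-base insertion/deletion/substitution events,
defaulting to 6%/5%/2% — the ~13% indel-dominated long-read profile. The
study defaults mirror the conditions used throughout the tests: 50 kb
reference, 100 bp short reads at 50× with 1% substitutions, ~5 kb long
reads at 10×.

Every event is logged with reference coordinates and the replay invariant
(`replay_read` reproduces the emitted read exactly) makes the truth set
exact. Long reads are emitted on the forward strand of their source
interval so truth accounting needs no strand gymnastics; strand symmetry
is exercised by the short reads through canonical counting.

What the simulator does *not* model: homopolymer-biased indels, chimeric
reads, quality values, coverage biases (GC, mappability). Passing tests
therefore demonstrate the machinery under clean i.i.d. conditions; on real
data the coverage signal is noisier and thresholds may need tuning.

## Evaluation

Ground truth gives `E_m`, the set of real errors of a read, keyed by
(reference position, type, read base). The corrected read is globally
aligned to its true source interval (Needleman–Wunsch; match +1, mismatch
−1, gap −2) and the remaining differences form `E_r` under the same keys.
Then `TP = |E_m \ E_r|`, `FP = |E_r \ E_m|`, `FN = |E_r ∩ E_m|` and
`gain = (TP − FP) / (TP + FN)` — the fraction of errors effectively
removed. The FN formula is kept exactly as defined by the gain metric's
source, even though `FP + FN` need not equal `|E_r|`. With `TP + FN = 0`
(error-free input) gain is reported as 1 when `FP = 0`, else as the
sentinel −1 with a `degenerate` flag.

Indel placement inside repeated context is ambiguous, so both key sets are
left-normalized (indels shifted left through equal bases) and co-located
identical events receive deterministic occurrence suffixes; on isolated
substitutions alignment-derived sets reproduce the truth exactly, which
the tests assert. Adjacent substitution clusters can admit equal-scoring
indel representations; the resulting key mismatches enter TP and FP
simultaneously and cancel in the gain numerator.

`global_align` (exported) is `Biostrings::pairwiseAlignment`. Bulk
evaluation instead uses an internal banded aligner (band follows the
diagonal, doubling until the optimal traceback stays clear of the band
edge), cross-checked against the exact aligner in the tests; identity is
matching columns over alignment columns. `n50` and truth-interval-based
aligned fractions (identity ≥ 0.7) complete the metrics; no external
aligner is invoked.

## Problem sizes used by the tests

Unit tests run on tiling fixtures of a few hundred bases. The end-to-end
property tests use the study conditions on 50 kb references (three seeds;
a repeat-bearing genome for the traversal ablation, 500 bp repeat, three
extra copies), where the pipeline reaches mean corrected identity ≥ 0.99
and gain ≥ 0.85, and the strategy ordering
`gain(widest) ≥ gain(shortest) ≥ gain(greedy)` is reproduced. The widest
path and the alignment scores are verified against exhaustive enumeration
on small instances; de Bruijn counts against a brute-force window counter.

## Known limitations

* Read tips before the first / after the last strong k-mer are never
  corrected (no anchor pair); they dominate the residual error.
* Substitutions in regions below half the spectrum median are not
  corrected (true_low protection).
* The length-bounded widest-path search is exact only while the bound is
  not binding.
* Per-base qualities are dropped on indel correction (coordinates change);
  substitution-only correction preserves them.
* The distributed-runtime aspects of the original system (MapReduce
  shuffles, distributed key-value stores) are out of scope; per-read
  independence is retained and exposed as a fork-based worker pool with
  order-independent results.
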