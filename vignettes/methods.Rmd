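---
title: "Methods: blocked progressive alignment in gridalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blocked progressive alignment in gridalign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridalign)
```

# The model

`gridalign` is a progressive multiple-sequence aligner of the Clustal W
family.  Progressive alignment assumes that a good multiple alignment
can be assembled greedily: sequences that are most similar are aligned
first, and already-aligned groups are never revised ("once a gap, always
a gap").  The pipeline therefore has three stages, each with its own
assumptions:

**Stage 1 — pairwise distances.**  Every pair of sequences is aligned
locally under the Gotoh affine-gap model: a gap of length $L$ costs
$g_o + L \cdot g_e$, and three DP states are tracked per cell — the main
value $H$, the horizontal-gap state $E$ and the vertical-gap state $F$:

$$
\begin{aligned}
E(i,j) &= \max\{H(i,j{-}1) - g_o - g_e,\; E(i,j{-}1) - g_e\}\\
F(i,j) &= \max\{H(i{-}1,j) - g_o - g_e,\; F(i{-}1,j) - g_e\}\\
H(i,j) &= \max\{H(i{-}1,j{-}1) + s(i,j),\; E(i,j),\; F(i,j)\;[,\,0]\}
\end{aligned}
$$

with the $0$ term in local mode only.  The alignment is converted to the
uncorrected percent-identity distance
$d = 1 - \mathrm{id}/\mathrm{cols}$ over residue–residue columns; an
empty local alignment has distance 1.  A Kimura multiple-hit correction
$-\ln(1 - d - d^2/5)$ is available behind `kimura = TRUE` but off by
default, since the uncorrected identity is the simplest self-consistent
choice and the correction only matters for deep divergences.

**Stage 2 — guide tree.**  Saitou–Nei neighbor joining on the distance
matrix, with the Q criterion minimized and ties broken to the smallest
index pair so the tree is reproducible.  A negative branch length at a
join is clamped to zero with the deficit transferred to its sister
branch, preserving the joined pair's path length.  The unrooted NJ tree
is midpoint-rooted (the root is placed halfway along the longest
leaf-to-leaf path), and each leaf receives the branch-proportional
weight $w(\ell) = \sum_{b \in \mathrm{path}} \mathrm{len}(b)/n_b$, where
$n_b$ counts the leaves sharing branch $b$, normalized so the largest
weight is 1.  Diverged sequences thus count more in profile columns than
clusters of near-duplicates.

**Stage 3 — progressive merges.**  The rooted tree is traversed
post-order; each internal node merges its two child groups.  A group is
summarized as a $35 \times m$ profile: 33 residue-category rows hold the
weight-averaged substitution scores $M f$ per column ($f$ = the
weighted residue frequencies, normalized by the total member weight, so
gaps dilute a column), and two further rows hold the position-specific
gap-open and gap-extend penalties.  The merge is a *global* alignment of
the two profiles with the column-product score

$$
\mathrm{prf}(i,j) = \tfrac12\left(s_1[,i] \cdot f_2[,j] + s_2[,j] \cdot f_1[,i]\right),
$$

which is symmetric by construction and reduces exactly to the
substitution score for two single-sequence, weight-1 profiles — this is
what makes the $n = 2$ pipeline collapse to one global pairwise
alignment, a property the tests assert.

# The blocked engine and the grid cache

Both alignment stages run on one engine that partitions the DP matrix
into $k \times k$ blocks (block sizes differ by at most one within an
axis; longer blocks first).  The forward pass fills blocks in any order
that respects the wave-front dependency — block $(b_i, b_j)$ after
$(b_i{-}1, b_j)$ and $(b_i, b_j{-}1)$ — and retains only the $H/E/F$
values on the $k{+}1$ boundary rows and $k{+}1$ boundary columns, at most
$(k{+}1)(\mathrm{len}_a + \mathrm{len}_b + 2)$ cells.  The traceback is a
separate job: it walks from the end cell (matrix corner in global mode,
best cell in local mode) back to the origin, recomputing one block
interior at a time from its cached top row and left column, trading
recomputation for memory.  Forward and backward jobs communicate only
through the serialized grid cache, a little-endian byte stream with a
versioned header, so the decoupling is exercised honestly: the pairwise
scheduler always round-trips the cache through its byte stream between
the two phases.

Two cell codecs exist.  The 12-byte codec stores $h$, $e$, $f$ as three
signed 32-bit integers and is always safe; the 6-byte codec stores $h$
plus $e - h$ and $f - h$ as signed bytes and is valid only while both
differences stay below 128 in magnitude — encoding larger differences is
an explicit error instructing a codec upgrade, never a silent wrap.
Because boundary cells in global mode contain large negative sentinels,
the pipeline serializes caches with the 12-byte codec by default and the
6-byte codec remains available for in-range data.

`k` is the *number of blocks per axis*, not the block size, matching the
usual parameterization of boundary-caching DP schemes; `k = 1`
degenerates to plain full-matrix DP.  Optimal `k` values are
hardware-specific, so the engine takes a user-supplied calibration table
of `(length, k)` points and interpolates piecewise-linearly on the longer
input length, rounding to the nearest integer and clamping to
`[1, min(len_a, len_b)]`.  Without a table it uses the portable default
`ceiling(sqrt(max_len / 64))`, clamped to `[1, 16]` — small enough that
block interiors stay cache-friendly at desk scale while the boundary
cache stays negligible.

# Determinism and numerical choices

All DP arithmetic is exact 32-bit integer.  User-scale scores (which may
be fractional, e.g. a gap extension of 6.66) are multiplied by 100 and
rounded once on entry; profile column products are computed in double
precision and rounded half-away-from-zero to the same $\times 100$
integer scale before they enter a cell.  Reported scores divide by 100
again.  The scale constant keeps the 6-byte codec meaningful for
in-range data while making every comparison in the DP a comparison of
integers — the precondition for bit-identical results across block
counts and schedules.

* "Minus infinity" is the sentinel `INT_MIN/4`; subtractions clamp at it
  rather than underflowing.  A cell exceeding `INT_MAX/4` aborts with a
  saturation error; wrapping silently would corrupt alignments.
* Traceback tie-breaks, in order: diagonal, then vertical (gap in the
  second input), then horizontal (gap in the first); within a gap state
  the gap closes as early as possible; among equal-scoring local maxima
  the smallest $(i, j)$ wins (row-major scan).  These rules make the
  alignment — not just the score — a pure function of the inputs.
* The wave-front worker model only chooses the order in which blocks are
  filled: one worker walks the grid row-major, $W$ workers take up to
  $W$ runnable blocks per tick in $(b_i, b_j)$ order.  Every such order
  is topological, and the engine verifies dependencies and rejects
  schedules that violate them.
* Degenerate inputs: empty sequences, gap characters in unaligned input,
  zero-column alignments, alphabet mismatches and cache/input mismatches
  are rejected with informative errors; a local alignment with no
  positive cell returns score 0 and an empty alignment rather than an
  arbitrary anchor.

# Scoring parameters

| Parameter | Default (DNA) | Default (protein) | Notes |
|---|---|---|---|
| match / mismatch | +1 / 0 | BLOSUM62 | nucleotide ambiguity codes score the mean over their base sets |
| gap open $g_o$ | 15 | 10 | per gap, score units |
| gap extend $g_e$ | 6.66 | 0.1 | per residue, score units |
| position-specific scaling | $\times (1 - 0.7\,\mathrm{gapfrac})$ | same | new gaps are cheaper where a column already has gaps |

The DNA defaults are the long-standing Clustal-family settings; BLOSUM62
comes from `Biostrings`.  Custom matrices load from NCBI/EMBOSS
plain-text files via `read_score_matrix()`.  The $1 - 0.7 \cdot
\mathrm{gapfrac}$ penalty scaling is the deliberate, minimal
position-specific rule: it concentrates gaps in columns that already
have them.  Residue-specific gap-attraction rules (hydrophilicity runs
and the like) are out of scope; this scaling hook is where they would
plug in.

The 35-row profile layout is an interpretation of the fixed 35-cell
column structure (all residue categories plus gap information): 33
residue rows cover the padded IUPAC category space of either alphabet
(15 nucleotide categories with U folded into T, 23 amino-acid
categories; unused rows stay zero), and rows 34–35 carry the gap
penalties, excluded from the column product.

# The scheduler model

The two-level parallelism is modelled portably: a *geometry* is a named,
mutually exclusive sub-pool of workers with a rectangular shape and one
controller; forward geometries compute full DP matrices, backward
geometries (one working tile) run tracebacks.  On the reference
60-worker pool the layout follows two empirical rules: four 7×2 forward
plus two 2×1 backward geometries by default — a 56:4 split, since the
forward stage dominates the cost — and eight 7×1 forward geometries when
5–8 jobs are pending, so no geometry idles through a second batch;
backward work then reuses freed forward geometries (the policy chosen
here for the case the layout rules leave open).  Four further workers
are reserved for pool management.  Smaller pools scale the same pattern
down proportionally, preserving the invariants (rectangular shapes, at
least controller + 1 worker, no oversubscription).  Because execution is
modelled rather than pinned to hardware, the scheduler's observable
output is the dispatch ledger — and the package's contract is that no
user-visible result depends on any of it.

# What the synthetic families do and do not emulate

`generate_family()` draws one uniform ancestor and mutates independent
copies: per-site substitutions (default rate 0.05 to a different
residue) and per-site indel events (default rate 0.01; insertion or
deletion with equal probability, geometric lengths with mean 2).  These
defaults produce a moderately diverged family — mean pairwise identity
around 75–85% — typical of the desk-scale test sets this package is
exercised on; the test suite and acceptance script use lengths of
60–2000 bp and 2–10 sequences so the default suite finishes in about a
minute and the full acceptance run in under one minute on one CPU.

The generator is a star phylogeny with i.i.d. sites.  It does *not*
emulate rate heterogeneity across sites, GC skew, repeats or
low-complexity regions, domain shuffling, or tree-structured descent —
so passing tests demonstrate the *mechanics* (optimality of the DP,
determinism, round-trip integrity, tree recovery on additive matrices),
not alignment accuracy on biological families.  One visible consequence:
with the 1/0 nucleotide scoring, dense indels fragment the local
alignments and frame-shifted segments count as mismatches, so
percent-identity distances are conservative (inflated) at high indel
rates.  The guide tree only consumes relative distances, so this affects
interpretability of the matrix more than the resulting alignment.

# Known limitations

* Pairwise distances are uncorrected identities by default; the Kimura
  flag caps distances at 0.75 before correcting instead of using a
  lookup table for deeper divergences.
* No iterative refinement or anchoring heuristics: the progressive
  result is final, and early errors propagate as in any
  Clustal-family aligner.
* Position-specific gap penalties implement only the gap-fraction
  scaling rule; residue-class rules are intentionally absent.
* The engine is quadratic-time per merge; block caching bounds memory,
  not time.  Desk-scale inputs (a few hundred kb) are the design point.
* `k` calibration tables must come from the user's own measurements;
  the built-in default is a portable heuristic, not a tuned optimum.

# Problem sizes used by the checks

The test suite verifies engine-vs-oracle equivalence on 200+ random
pairs of length ≤ 64 across $k \in \{1,2,3,5\}$ in both modes (the
oracle is an independently written full-matrix Gotoh DP in plain R, with
the same tie-break contract); pipeline determinism on a seeded
10-sequence, 2 kb family across worker counts $\{1,4,8\}$, block counts
and both fragment policies; NJ topology recovery on 50 random additive
matrices with up to 12 taxa; and codec round-trips on $10^4$ random
cells per codec.  These sizes were chosen so the whole suite stays fast
enough to run on every change while still exercising multi-block,
multi-worker paths.
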