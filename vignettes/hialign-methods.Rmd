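---
title: "Methods: hierarchical-profile search, template-mapped global alignment, and coupling-based MSA quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical-profile search and alignment quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hialign)
```

# The model

A *hierarchical MSA* is a tree of curated subgroup alignments for one
protein domain superfamily. Each node holds an alignment of member
sequences over that subgroup's match columns; a **template alignment**
stacks the node consensus sequences (root first) and thereby defines, for
every node, which of its columns correspond to which root columns; a
depth-first integer array (`0 1 2 2 1` style: entry k is the depth of node
k) encodes the tree. The package's premise is the same as the toolchain it
reimplements: if the curated subgroup alignments are accurate, then any
database sequence aligned well against *some* subgroup profile can be
projected through the template into root coordinates, and all such
projections are automatically aligned to one another — a global alignment
of arbitrarily many sequences with near-curated accuracy, without ever
running a multiple-alignment heuristic over them.

Alignment state follows the conserved-domain convention throughout:
uppercase = residue at a match column, `-` = deletion at a match column,
lowercase = inserted residue between match columns, and unaligned flanks
stored as counts. Two text formats carry this state: mFASTA (the
distribution format) and a documented line-oriented `cma` dialect
(`[cma]<TAB>name<TAB>accession<TAB>L<TAB>nrows`, then per row a
`><TAB>id<TAB>flank_left<TAB>flank_right<TAB>protected<TAB>desc` line and
the state string, closed by `[end]`). The historical cma grammar is not
documented anywhere usable, so this dialect is the package's own; it is
lossless for everything the pipeline needs and round-trips byte-exactly,
which the test suite checks on seeded random alignments. mFASTA cannot
carry flank counts or the protected flag; they read as 0/`FALSE`.

# Profiles and search

**Sequence weighting.** Redundancy is neutralized with Henikoff
position-based weights: at each column a row holding residue *a* receives
1/(k·n_a), k the number of distinct residues in the column, n_a the count
of rows holding *a*; deletions contribute nothing; row weights are column
sums normalized to mean 1. The weighting scheme behind the published
consensus rule is unspecified, and Henikoff is the standard deterministic
choice.

**Consensus** is the weighted most-frequent residue per match column, ties
broken alphabetically so the result is a pure function of the alignment.
All-gap match columns are rejected — curated inputs must occupy every
match column.

**Profile construction.** For column j with weighted residue frequencies
f, the pseudocount distribution is g = P f with P(a|b) ∝ q_a·2^(s_ab/2)
reconstructed from BLOSUM62 (q = Robinson–Robinson background), mixed as
p = (m_j·f + β·g)/(m_j + β) with observed mass m_j (the summed weights)
and pseudocount mass β = 10. Scores are half-bit log-odds
s(a, j) = 2·log₂(p_aj/q_a), **rounded to integer half-bits**. The rounding
is the conventional PSSM representation; it also makes every dynamic
programming cell an exact small integer in double precision, so traceback
equality tests and the brute-force oracle comparison are exact rather than
tolerance-based.

**Local detection.** Each database sequence is scored against a profile by
affine-gap Smith–Waterman (Gotoh), a gap of length k costing
open + extend·k with defaults 22/2 half-bits (the 11/1 convention doubled).
Unknown residues (X and any non-standard letter) score 0 at every column.
Ties are resolved deterministically: among maximal cells the smallest
sequence end then column end wins, and traceback prefers match over
deletion over insertion; in the enumerable cases this coincides with the
smallest-start alignment. Significance uses the Karlin–Altschul law
E = K·m·n·e^(−λS) with S the raw half-bit score, m the profile length and
n the database residue count; λ = 0.267, K = 0.041 are the standard gapped
BLOSUM62/11/1 constants and are stated per raw score unit (these published
constants only make sense in those units). `calibrate_evalue()` refits
both by the method of moments from shuffled-sequence score distributions
when empirical statistics are preferred.

**Pruned descent and assignment.** The root profile is scored first; a
node's children are evaluated only when the node's score reaches its
*trigger*. Published trigger values are not available, so the default
trigger is the score equivalent of E = 10 at the configured database size,
computed per node; explicit per-node score triggers (including −Inf, which
disables pruning) are accepted. Among evaluated nodes the hit goes to the
highest score, ties to the deeper node and then depth-first order. The
matched region is masked with X and the search repeats (bounded by
`max_copies`), so each copy of a repeated domain is reported; masking
consumes at least one residue per iteration, which guarantees termination.
Colinear same-node matches separated by at most `max_internal_gap` = 50
unaligned residues are merged into one hit whose path bridges the gap with
insert and deletion runs.

**The reported path is glocal.** Detection, assignment and E-values use
the local score, but the path attached to an assigned hit is computed by a
second pass that is global across the profile's columns and local in the
sequence. A purely local path stops extending as soon as terminal columns
score negatively, so sequences with substitutions at weakly conserved ends
would have those residues silently dropped from the global alignment; the
glocal pass instead charges the (cheap) substitution or the (expensive)
deletion explicitly and keeps the domain model fully covered. This is the
package's reading of template-based *global* alignment; it does not
re-optimize residue placement beyond that single pass, and inserts are
never aligned among themselves.

# Globalization and purging

A hit on node v is projected through the node→root column map defined by
template co-occupancy: node column i maps to root column j exactly when
the node's template row has a match-state residue in a template column the
root row also occupies. Residues on unmapped node columns and insert-state
residues become lowercase inserts attached **after the nearest preceding
mapped root column** (left-anchored — a fixed convention is required for
byte-identical output); uncovered root columns become `-`; flanks are kept
as counts. Row order in the assembled global alignment is (node
depth-first order, sequence id, region start), so output is reproducible
and chunk-order independent.

Purging applies two filters in sequence. The fragment filter keeps rows
occupying at least 75 % of the match columns (the boundary itself is
retained; the published rule removes strictly below). The redundancy
filter is greedy: rows visited protected-first, then by decreasing
match-residue count, then id; a row is kept iff protected or below 98 %
identity to every kept row. Identity counts matches at co-occupied columns
divided by the *smaller* of the two rows' residue counts, which makes a
fragment identical to a full-length row fully redundant — the intent of
the published filter. The greedy order keeps the most informative
representative and makes the output deterministic; the all-vs-kept O(n²)
scan is adequate at the package's scales. Insert columns are excluded from
identity (root match columns only). Purging is idempotent and invariant to
how the database was chunked.

# Coupling-based MSA quality

Two alignments are compared like for like before scoring
(`harmonize()`): a user-supplied column correspondence trims terminal and
insertion columns to equal counts; rows with deletions in more than 25 %
of columns are dropped (strictly above); unprotected rows at or above 98 %
identity are deduplicated; the larger alignment's unprotected rows are
randomly subsampled (seeded) to the smaller's count, with protected
structure-bearing rows always retained.

`dca_couplings()` is textbook mean-field direct coupling analysis:
sequences reweighted at 80 % identity (gap counted as a 21st state), 21
single and pair frequencies mixed with a uniform pseudocount of fraction
0.5, couplings from minus the inverse covariance over the 20 residue
states, per-pair 20×20 blocks gauge-fixed to zero sum, Frobenius norm,
average-product correction, negatives clipped to 0 so the matrix is a
nonnegative coupling strength. The clipping only affects pairs already far
below any top-k threshold. A singular covariance (possible only at
pseudocount near 0) raises an error suggesting a larger pseudocount.

Contacts come either from per-column representative-atom coordinates
(Cβ-style; distance ≤ 8 Å, separation ≥ 5 — the standard contact
prediction convention, both configurable) or from a tabulated pair list.
Columns without coordinates leave the eligible universe entirely. The
S-score takes the k most strongly coupled eligible pairs (k defaults to
the column count, capped at the universe size; ranking ties broken by
column indices), counts the overlap x with contacts, and sets
S = −log₁₀ P with P the exact upper-tail hypergeometric probability of at
least x contacts among k draws from N eligible pairs containing M
contacts (`stats::phyper`; no simulation). S is 0 when contacts are
uninformative and grows without bound as the correspondence sharpens;
a permutation of the contact assignment serves as the null cross-check.

# The synthetic benchmark

`simulate_superfamily()` generates the package's standard test conditions:
20 nodes of depth ≤ 3 over a 120-column root, 50 members per node, 500
decoys, all driven by one seed. Subgroup consensus sequences diverge along
each tree edge by conditional (BLOSUM-like, always-changing) substitutions
at rate 0.15 per column plus, with probability 0.6 each, one
subgroup-specific insertion and one deletion of up to 6 columns; members
diverge from their node consensus at rate 0.10 with small indels
(probability 0.08, up to 3 columns). Four 5-column anchor motifs are never
mutated or deleted and indels avoid them, mimicking the conserved motifs
that keep real superfamily alignments anchored. Members are embedded
between 5–30-residue random flanks; decoys are background draws of
80–250 residues. These rates were chosen once as representative of a
diverged but alignable superfamily (members ~90 % identical to their
subgroup consensus, subgroups tens of percent diverged from each other);
the residue-level truth table records every embedded residue's true root
column or insert status.

What the simulator does **not** emulate: phylogenetic rate heterogeneity,
compositional bias, repeats and low-complexity sequence, fragments, or
alignment errors in the "curated" input itself. Passing the recovery tests
therefore demonstrates correctness of the machinery under honest
conditions — profiles estimated from finite members, real indels,
unrelated decoys — not robustness to adversarial real-world data.

`simulate_covariation()` drives the coupling evaluator: independent
uniform columns except planted pairs following a two-state paired model
(each sequence picks a mode; each side reverts to random with probability
1 − strength). The planted-recovery and null-calibration fixture uses 5
strong pairs (strength 0.9, n = 2000, L = 30). The quality-*ordering*
check needs dynamic range rather than saturation, so it plants 15 pairs
with graded strengths 0.3–0.9 at n = 500: the top-k rank threshold then
falls inside the graded band and responds when 20 % of rows are corrupted.
Corruption (`corrupt_msa_rows()`) permutes each window column
independently among the selected rows — destroying their covariation while
preserving every column composition exactly.

# Numerical and engineering choices

- Integer half-bit profile scores make all DP arithmetic exact; the local
  aligner is verified against a gap-run enumeration oracle that shares no
  code with it.
- Coordinates are 1-based and closed everywhere (match columns 1..L,
  residues 1..n).
- Degenerate inputs: empty alignments round-trip; empty hit sets produce
  an empty global alignment that still knows root_L; an all-deletion
  glocal path is reported as an empty alignment; `s_score` refuses k ≤ 0
  or k beyond the eligible universe.
- The per-chunk search is embarrassingly parallel in principle; the
  implementation runs chunks serially and guarantees the contract that
  matters: chunked and unchunked runs produce identical final alignments
  (E-values always use the full-database residue count).
- Problem sizes in the test suite — the default 20-node preset for
  recovery and pruning checks, 200 enumerable oracle cases, 100 round-trip
  alignments, 50 ordering replicates at n = 500, one n = 2000 coupling
  fixture — are the package's chosen benchmark conditions, small enough to
  run routinely while large enough for the measured properties to be
  stable across seeds.

# Known limitations

- No word-hit seeding: every candidate is aligned by full dynamic
  programming. Correct, and fast enough at benchmark scale, but not a
  drop-in for searching the full non-redundant protein database; a seeding
  layer could be added without changing any result contract.
- E-value constants are borrowed from the BLOSUM62 gapped theory rather
  than per-profile calibration unless `calibrate_evalue()` is used;
  absolute E-values are therefore approximate (relative ranking is not
  affected).
- The glocal reported path assumes the detected region really is a
  full-domain instance; a genuinely half-present domain is represented
  with long terminal deletion runs and is expected to be removed by the
  fragment filter rather than re-scored.
- Mean-field DCA with Frobenius/APC scoring is the deterministic
  desk-scale choice; pseudo-likelihood methods rank contacts better on
  real families but are out of scope here.
- Harmonization requires the user to supply the column correspondence
  between the two alignments; the package does not infer it.
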