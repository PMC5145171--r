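---
title: "Chemical-group analysis of protein sequences: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical-group analysis of protein sequences: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemotif)
```

## The model

`chemotif` analyses proteins through a reduced alphabet of eight side-chain
chemistry classes — acidic (D, E), basic (R, H, K), aromatic (Y, F, W),
aliphatic (I, L, V, A, G), cyclic (P), sulfur-containing (M, C),
hydroxyl-containing (S, T) and acidic amide (Q, N) — so each sequence
becomes a digit string over `'1'`–`'8'`. The underlying assumption is that
within-group substitutions (S↔T, Y↔F, D↔E, I↔L, ...) are chemically neutral
for the questions being asked, while between-group substitutions are not.
Everything downstream is exact combinatorics on the digit strings; no
substitution matrix, gap model or statistical significance is involved.

Three analyses are built on the encoding:

1. **Transitions.** The 8×8 matrix of adjacent ordered pairs, and the
   per-group summary of residue total (#G) and non-self pair count (#X).
   The cell total always equals `length − 1`; #G differs from the matrix
   row sum by one exactly when the sequence ends in that group, because the
   final residue starts no pair. Both the matrix and the summary are
   exposed, and their consistency is property-tested.
2. **Common patterns.** The set of length-`L` digit patterns occurring as a
   contiguous substring of *every* sequence in a set. The package's
   canonical definition of this set is the intersection of the per-sequence
   `L`-mer sets, filtered by the mode's constraint (pairwise-distinct
   digits for `norepeat`). Search strategy never changes the answer:
   `method = "grow"` reproduces the enumerate-and-test and seeded
   tetramer-growth procedures and is tested to return exactly the canonical
   set.
3. **Block similarity.** An ungapped sliding window: a block of length `L`
   is scored against every window of the target by the count `m` of
   positions sharing a group, and `(m / L) × 100` is reported for the best
   window together with **all** positions achieving it. Percentages are
   exact rationals rendered to two decimals; nothing is rounded internally,
   so `best_percent × L / 100` is always an integer.

## Parameters that matter

- `policy` (`"strict"`, default, or `"mask"`): how non-standard characters
  (B, J, O, U, X, Z, gaps, `*`) are handled. Strict errors with the record
  and offset; mask replaces them with the break digit `'0'`. Because
  patterns and blocks are defined over `'1'`–`'8'`, a `'0'` can never match
  anything, which guarantees no pattern or similarity window spans a masked
  run — silently dropping the characters instead would fabricate
  adjacencies and shift every downstream position and pair count.
- `L` (pattern length): `norepeat` mode is capped at 8 by pigeonhole. An
  `L` longer than the shortest sequence yields an empty result rather than
  an error, so length sweeps need no special-casing. `L = 1` is accepted as
  the trivial base case although the published procedure starts at 2.
- `mode` (`"norepeat"` / `"repeat"`): repetition-free patterns are a subset
  of the unconstrained ones at equal `L`; both are searched with hit
  positions 1-based and overlapping occurrences counted.
- The alphabet itself is a frozen constant (`chemical_groups()`), the
  method's core. The grouping could in principle be varied (down to 20
  singleton groups, which recovers plain identity comparison), but every
  function in this package uses the fixed 8-group partition.

## Numerical and procedural choices

- **Growth with remainder.** The seeded tetramer growth extends candidates
  in 4-digit chunks. For a target length `L = 4q + r` with `r > 0`, the
  remainder is appended one digit at a time (equivalent to appending all
  `8^r` suffixes and then filtering), and after every round candidates
  absent from any sequence are pruned via per-sequence k-mer sets. Only
  *common* tetramers are used as extension units: the terminal tetramer of
  any common k-mer is itself common, so this smaller extension set provably
  yields the same result as concatenating all 4096 tetramers.
- **Maximal length search.** Grows candidates one digit at a time from
  `L = 1`. Since the length-`L` prefix of a common length-`(L + 1)` pattern
  is itself common, the first length at which extension fails bounds all
  longer lengths, and the last non-empty set is returned. An input sharing
  not even one group returns `L = 0` with an empty set.
- **Discriminating groups.** A group "hits" a bipartition only when *both*
  its #G interval and its #X interval are disjoint between the sides.
  Intervals are closed and touching endpoints count as overlapping — the
  conservative reading. Ranking among hits was a genuinely open design
  point: the package orders by the larger of the two normalized gaps
  (interval distance divided by the midpoint of the union span), with ties
  broken by group id. The comparator is isolated in one place; any
  alternative ranking can replace it without affecting which groups hit.
- **Subgroup classification.** A pattern is "A-only" when it is common to
  every member of subgroup A but not to every member of subgroup B —
  commonality within a subgroup, not absence from the other. The three
  sets (all-common, A-only, B-only) are pairwise disjoint by construction.
- **Ties in block scanning.** All argmax window positions are reported, not
  just the first, since multiple chemically equivalent occurrences of a
  block are precisely what the method is meant to surface.
- **Degenerate inputs.** Empty sequences encode to empty strings; length-1
  sequences have all-zero transition matrices; a block equal to its target
  degrades the scan to the aligned comparison; absent patterns locate to
  empty tables.

## The synthetic generator

`simulate_sequences()` emulates a small protein family: by default 8
sequences of 300–400 residues with a uniform background over the 20
standard residues, desk-scale analogues of a family of ~850-residue motor
domains. Planted digit patterns are realized per occurrence by sampling
each position's residue from its group's members, so the chemical pattern
is exact while the residues vary across sequences — the same S/T- and
Y/F-style conservation the method targets. Plants never overlap, the
manifest records every ground-truth position, and output is a pure function
of the seed.

What the generator does *not* emulate: real amino-acid composition biases,
positional correlation, domain architecture, indels, or homologous
background similarity between family members. Passing tests on fixtures
therefore demonstrate correctness of the algorithms (planted patterns are
recovered exactly, searches equal their brute-force oracles), not that any
particular biological family will contain long common patterns — on real
families the interesting output is empirical.

## Problem sizes used in the test suite

Property-style tests run on randomly generated sets of up to 10 sequences
of up to 200 residues with pattern lengths up to 6 (plus growth checks to
`L = 13` on shorter sequences), sizes at which the brute-force oracles are
instant while still exercising every code path; the full suite runs in
well under a minute. Fixed seeds make every property run reproducible.

## Known limitations

- Matching is exact on groups: there is no mismatch tolerance, no gap
  handling, and no weighting of groups — a single between-group
  substitution interrupts a pattern.
- No statistical significance is attached to patterns or similarity
  percentages; with 8 symbols, short common patterns arise by chance in
  small sets (at `L = 4` and a handful of sequences, dozens of shared
  patterns are expected under the uniform background).
- Pattern discovery scales with the product of sequence count and length
  via per-sequence k-mer sets; it is intended for family-sized sets (tens
  of sequences), not database-wide scans.
- The eight-group partition is one defensible chemistry; proteins whose
  conservation logic follows other properties (size, hydropathy alone)
  may be better served by a different reduced alphabet.
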