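# chemotif

Alignment-free, chemistry-aware comparison of protein sequences.

Conventional sequence comparison treats every amino-acid substitution as a
difference, yet many substitutions (S↔T, Y↔F, D↔E, I↔L/V) swap residues of
the same side-chain chemistry and leave the local chemical character of the
protein intact. `chemotif` is for protein-family analysts who want to find
the blocks of a family — motor domains, kinase domains, pump domains — that
are conserved *chemically* even where the residues themselves have drifted.

## The method

The 20 standard amino acids are partitioned into eight chemical groups:

| digit | group | residues |
|---|---|---|
| 1 | acidic | D, E |
| 2 | basic | R, H, K |
| 3 | aromatic | Y, F, W |
| 4 | aliphatic | I, L, V, A, G |
| 5 | cyclic | P |
| 6 | sulfur-containing | M, C |
| 7 | hydroxyl-containing | S, T |
| 8 | acidic amide | Q, N |

Each sequence becomes a digit string over `1`–`8`. On these encodings the
package computes:

- **Transition analysis** — the 8×8 matrix *G* of adjacent ordered pairs
  (cell (*i*, *j*) counts group-*i* → group-*j* neighbours) and the per-group
  summary *F* with, for each group *i*, the residue total #G*i* and the
  non-self ordered-pair count #X*i* = row-sum(*i*) − *G*(*i*, *i*). Disjoint
  (#G, #X) ranges between two halves of a family ("hitting groups") explain
  what chemically separates the branches.
- **Common chemical patterns** — every digit pattern of length *L* occurring
  in *all* sequences of a set, either without repetition of groups
  (*L* ≤ 8 by pigeonhole) or with repetition (found by seeded tetramer
  growth), plus maximal-length search and the split into family-wide vs
  subgroup-specific patterns.
- **Block similarity** — for a query block of length *L* slid along a
  target, the percentage (*m*/*L*) × 100 of aligned positions whose
  residues share a group, with every best-scoring window position reported.

## A worked example

```r
library(chemotif)

seqs <- tibble::tibble(
  seq_id   = c("seqA", "seqB", "seqC"),
  residues = c("MDRSMYIAKEFPKATDLQ", "MEKTCWVGREFPKASDIN", "ADRSMLVAKDYPRATDLQ"))

encode_sequences(seqs)
#> # A tibble: 3 × 3
#>   seq_id residues           digits
#>   <chr>  <chr>              <chr>
#> 1 seqA   MDRSMYIAKEFPKATDLQ 612763442135247148
#> 2 seqB   MEKTCWVGREFPKASDIN 612763442135247148
#> 3 seqC   ADRSMLVAKDYPRATDLQ 412764442135247148
```

seqA and seqB differ at 14 of 18 residues but encode identically: they are
chemically the same sequence. The longest chemical pattern common to all
three:

```r
seqs |> maximal_common_patterns(mode = "repeat") |> tidy()
#> # A tibble: 3 × 6
#>   pattern          L mode   seq_id position residue_block
#> 1 442135247148    12 repeat seqA          7 IAKEFPKATDLQ
#> 2 442135247148    12 repeat seqB          7 VGREFPKASDIN
#> 3 442135247148    12 repeat seqC          7 VAKDYPRATDLQ
```

A 12-group block is chemically identical in all three sequences even though
its residue realizations differ (`FPKATD` vs `FPKASD` vs `YPRATD` inside
it). Sliding a query block along a target reports the best chemical match
and every position achieving it:

```r
scan_best("DRSMYI", seqs$residues[2], target_id = "seqB")
#> <chem_scan> block 'DRSMYI' (L = 6) vs seqB
#>   best chemical similarity: 100.00% at 1 position(s): 2
```

`DRSMYI` matches `EKTCWV` at position 2 perfectly: D/E, R/K, S/T, M/C, Y/W,
I/V are all within-group swaps. The per-sequence F table (`#G-#X` per
group), used for branch analysis:

```r
summary_table(seqs)
#> # A tibble: 3 × 9
#>   seq_id G1    G2    G3    G4    G5    G6    G7    G8
#> 1 seqA   3-3   3-3   2-2   4-3   1-1   2-2   2-2   1-0
#> 2 seqB   3-3   3-3   2-2   4-3   1-1   2-2   2-2   1-0
#> 3 seqC   3-3   3-3   1-1   6-4   1-1   1-1   2-2   1-0
```

Synthetic families with planted chemical motifs (`simulate_sequences()`),
FASTA input/output (`read_fasta()` / `write_fasta()`), TSV/JSON reports
(`write_report()`) and plots (`autoplot()`, `plot_transitions()`) round out
the toolkit. A command-line interface is available as `exec/chemotif`; see
`?chemotif_cli` for the subcommands (`encode`, `transitions`,
`discriminate`, `motifs`, `classify`, `similarity`, `fixtures`).

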