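---
title: "The move structure: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The move structure: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moveindex)
```

## The model

A DNA reference collection (typically a pangenome: many closely related
genomes) is concatenated, optionally followed by the reverse complement of
every record, and terminated by a sentinel `$` that is unique and
lexicographically smallest. Because the sentinel is unique, the sorted
rotations of the text coincide with its sorted suffixes, so the
Burrows-Wheeler Transform is obtained directly from the suffix array:
`bwt[k] = text[sa[k] - 1]`, wrapping at 0.

Repetition across genomes makes the BWT *run-length compressible*: the number
of maximal same-character runs `r` grows with the amount of *distinct*
sequence rather than total length `n`. The move structure stores one row per
run — `(c, l, p, π, ξ)` with `π = LF[p]` and `ξ` the run containing `π` — and
computes the LF-mapping at any offset `j` in run `i` as

```
j' = π_i + (j − p_i)
i' = fast_forward(ξ_i, j')
```

where `fast_forward` advances over consecutive rows until `j'` falls inside
row `i'`'s interval. All navigation is therefore arithmetic plus short
sequential scans over a single table.

Assumptions worth stating: the alphabet is fixed at `{A, C, G, T}` plus the
sentinel; the text is indexed with a *single* sentinel (see "Record
boundaries" below); offsets are 0-based and half-open internally, while table
rows are 1-based as is natural in R.

## Queries

**Pseudo-matching lengths.** Each read is scanned right-to-left with a running
match length `ell`, starting the cursor at an arbitrary BWT offset (offset 0
by default; any fixed choice gives a valid PML vector, and a shared start
makes runs comparable across modes). If the BWT character at the cursor equals
the query character ("case 1") the match extends: `ell + 1` is recorded and an
LF step taken. Otherwise ("case 2") `ell` resets to 0, 0 is recorded, and the
cursor *repositions* to the nearest offset above (`jup`) or below (`jdn`)
carrying the query character before the LF step — reposition first, then LF.
Characters outside the alphabet, or absent from the BWT entirely, record 0,
reset `ell`, and leave the cursor where it is. PMLs are emitted left-to-right
in read orientation. By construction `PML[i] ≤ MS[i]` (the true matching
statistic): every positive value certifies a real exact match of that length.

**Thresholds.** The up/down decision in case 2 picks the candidate whose
sorted suffix shares the longer common prefix with the suffix at the current
offset. Per run and foreign character, one stored threshold `t` encodes the
decision for the whole run: offsets `j < t` go up, `j ≥ t` go down, with
`t = p` ("always down") and `t = p + l` ("always up") as the one-sided
encodings. `t` is placed at the minimum of the LCP array between the two
surrounding occurrences of the character. When the minimum is attained more
than once we take the **last** position: a short argument shows this makes the
threshold decision reproduce the explicit LCP comparison *exactly* under the
tie rule "prefer `jup`" (for `j` at or past the last minimum, the remaining
downward window contains no minimum, so down is strictly better; before it,
the downward window always contains the minimum, so up is weakly better).
This is why the package can assert byte-identical PML output across the table
modes and the plain-BWT reference implementation, rather than agreement only
up to ties. The landing offset inside the target run is the one nearest the
query row: the run's last offset when moving up, its first when moving down.

**Backward search.** Count queries contract an inclusive `[top, bottom]` BWM
row interval one character at a time. Here no threshold is consulted: the top
pointer always repositions downward and the bottom pointer upward, since the
interval must shrink inward. The final width is the occurrence count; an
empty interval means the pattern does not occur.

**Batching.** `batch_query()` advances up to `B` reads round-robin, one
inner-loop step per turn, loading the next read when one finishes. In
compiled implementations this scheduling is what allows a memory prefetch to
be issued for one read while another computes; here only the scheduling
contract is implemented, and the testable property is exact equality of
results for every `B`. The default `B = 16` matches common practice.

## Run splitting (constant mode)

With unsplit runs, the number of fast-forwards per LF step is unbounded (though
always `< r`). Balancing subdivides runs so that every LF needs fewer than
`2d` fast-forwards while adding at most `⌈r/(d−1)⌉` rows. The rule
implemented: a row whose *output interval* (its π-image `[π, π + l)`)
strictly contains at least `2d` row start points is split at the `d`-th such
start; splits are applied one at a time against the up-to-date row set until
no row qualifies. The output-interval side is the one that bounds the LF
fast-forward scan (the scan walks rows overlapping the source row's π-image);
`verify_balance()` re-measures the bound empirically over every offset, and
the suite checks both bounds for `d ∈ {2, 4, 8}`. Splitting an
already-balanced table adds no rows.

Thresholds are always computed **after** splitting, on the final table, so
sub-runs carry correct threshold and pointer columns. Constant mode
additionally stores, per row and foreign character, the index of the nearest
run above and below with that character (six meaningful pointers per row for
DNA), making each repositioning a single dereference.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `d` | 4 | balancing parameter; `< 2d` fast-forwards vs `≤ ⌈r/(d−1)⌉` extra rows. 4 keeps both small at these scales; any `d ≥ 2` is supported and tested at 2, 4, 8. |
| `include_rc` | `TRUE` | index both strands so reads are queried forward-only |
| `alphabet_policy` | `"strip"` | non-ACGT reference characters are removed with a warning; `"reject"` fails naming record and offset. Stripping keeps the alphabet at four characters, which the threshold/pointer layout relies on. |
| `batch_size` | 16 | concurrent reads in the round-robin loop; results are independent of it |
| `start` | offset 0 | PML start position; arbitrary by design, fixed for determinism |
| `base_len`, `mut_rate`, `indel_rate` | 1000 bp, 0.001, 0 | synthetic pangenome: substitutions to a uniformly random different base; single-base indels optional and off by default |
| `read_len`, `error_rate` | 150 bp, 0 | read sampler; errors are uniform substitutions |

## The synthetic generator: what it does and does not emulate

`simulate_pangenome()` produces one uniform-random base genome plus
independently mutated copies — the simplest model that yields the run-length
compressible BWT structure of a real pangenome, and `r_growth_experiment()`
reproduces the expected trend (`n/r` strictly increasing with copies, distinct
canonical 31-mers growing sub-linearly) in miniature. `sample_reads()` draws
reads uniformly from the record blocks of the indexed text (both strands when
present, never spanning a block boundary or the sentinel), so `error_rate = 0`
guarantees each read is an exact substring.

The generator does **not** model realistic genome evolution (no structural
variation, no repeat families beyond whole-genome copies) nor sequencer error
profiles (no homopolymer or indel-rich error modes typical of nanopore data).
Passing tests therefore demonstrate *algorithmic correctness* — LF, counting,
thresholds, PMLs and their invariants on texts with pangenome-like run
structure — not classification accuracy on real reads, and say nothing about
the cache/latency behaviour that motivates the table layout in compiled
implementations.

## Numerical and degenerate-input choices

- Alphabet order `'$' < 'A' < 'C' < 'G' < 'T'`; the sentinel is a first-class
  character occupying its own run.
- Suffix arrays are built by prefix doubling (radix `order()` per round);
  LCP by Kasai's algorithm. Both are exact integer computations — no
  tolerances anywhere in the package.
- Multi-record references are concatenated with a single terminal sentinel and
  no per-record separators: matches spanning record boundaries are accepted as
  a documented approximation. This keeps one BWT and one threshold layout; it
  is the main deviation risk when comparing counts against indexes that use
  per-record terminators.
- LCP ties in repositioning go to `jup`; the threshold placement (last argmin)
  encodes the same convention, see above.
- Empty reads yield empty PML vectors; patterns with non-ACGT characters count
  0; `d < 2`, empty references, and records that empty out under the strip
  policy are build-time errors.
- Serialization is a versioned text container; loads verify magic, version,
  row counts and the end-of-file sentinel, and reject truncated files.

## Problem sizes used in the verification suite

The exhaustive suites run at sizes where brute-force oracles remain exact and
fast: 50 seeded random texts up to 5,000 bp for the LF sweep (every offset,
both modes); a 2,000 bp text with 2,000 sampled plus 200 absent patterns for
counting; a 4-copy, 1,000 bp-base pangenome (both strands, `n = 8,001`) with
999 mixed reads (error-free, 5%-error, off-target) for the PML identities;
10 texts up to 1,000 bp for the exhaustive repositioning sweep; and copy
counts 1–16 for the compression trend. These were chosen as the largest sizes
at which every property can be checked exhaustively rather than sampled.

## Known limitations

- Pure R: suitable for verification and teaching, not for indexing real
  pangenomes (the table build materialises the full suffix array).
- No locate queries, maximal exact matches or full matching statistics — the
  matching-statistics oracle exists only to bound PMLs in tests.
- No collapsed relative-offset row encoding or other space optimisations; `π`
  and `ξ` are stored explicitly per row for clarity.
- Hardware prefetching and latency measurements are out of scope; batching
  implements the scheduling contract only.
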