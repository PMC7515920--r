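---
title: "Degenerate primer coverage and the parsimony-constrained degeneration search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degenerate primer coverage and the parsimony-constrained degeneration search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primertax)
```

## The model

A degenerate primer is a short IUPAC string: each position denotes a
nonempty subset of {A, C, G, T}, and the primer stands for the pool of all
per-position combinations (its *expansions*). Two quantities drive
everything in this package:

- **Degeneracy** — the pool size, the product of per-position base-set
  sizes. It is the parsimony cost of a primer: every extra expansion
  dilutes the effective concentration of each variant in the pool.
- **Coverage** — for a primer pair and a set of reference sequences, the
  fraction of sequences on which a forward site (plus strand) and a reverse
  site (minus strand) both match, in the correct order, with a product size
  within bounds. Matching is set-intersection per position: primer code and
  subject code match when their base sets intersect. At the default of zero
  allowed mismatches this is exact degenerate matching; allowances up to
  three mismatches are supported for diagnostics and site location.

Coverage is computed per taxon on a six-rank ladder
(kingdom–phylum–class–order–family–genus). Records not annotated at the
queried rank go to an explicit `unclassified` bin: dropping them silently
would corrupt the totals invisibly, and keeping them named preserves the
invariant that per-rank totals sum to the set size. An empty taxon's
coverage is reported as `NA`, never as 0 — a clade with no qualifying
sequences is unknown, not uncovered.

## The degeneration search

Given a base forward primer, a fixed reverse primer, and a target clade,
`propose_degenerations()` enumerates every *strict widening* of the base
primer — each edited position's base set must strictly contain the old one —
at up to `max_positions_changed` positions, subject to a degeneracy cap.
Narrowings and repositionings are never considered: a widened primer's
expansion pool is a superset of the base's, so every record the base pair
covered stays covered. That superset property is what makes the search safe
(global coverage cannot decrease; it is reported, not constrained) and also
what makes it fast: candidates only need re-evaluation on records the base
pair fails to cover, and the unchanged reverse primer's sites are computed
once.

Candidates that gain target coverage are ranked by:

1. target coverage gain, descending (completeness first);
2. degeneracy multiplier, ascending (parsimony as the tiebreak);
3. number of positions changed, ascending;
4. 5'-most edited position, ascending;
5. lexicographic primer string.

The last two rules exist only to make the order total, so identical inputs
always yield identical ranked lists. Completeness is deliberately ranked
ahead of parsimony; a cheaper edit that rescues fewer target records is
never preferred.

Tunable parameters and their defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| `max_positions_changed` | 1 | positions | single-position edits are interpretable and sufficient for allele-type fixes; multi-position search is available but grows combinatorially |
| `max_degeneracy` | 96 | expansions | 4× a typical universal forward primer's degeneracy of ~24; beyond this, pool dilution becomes a practical PCR concern |
| `protect_3prime` | 3 | positions | 3'-terminal mismatches abolish extension, so a 3' widening can look good in coverage terms while failing at the bench; configurable to 0 |
| `max_mismatch` | 0 | mismatches | exact degenerate matching is the selection metric; relaxed matching is for diagnostics |
| `min_len` | 1200 | nt | strictly-greater-than quality filter for near-full-length 16S references |
| `site_search_mismatch` | 3 | mismatches | only for locating the binding site in records the base primer misses, when profiling site alleles |

`verify_proposal()` closes the loop: it recomputes the before/after
coverage tables at every rank and asserts that no taxon lost coverage.

## Coordinates and product size

All coordinates in the R API and in written reports are 1-based inclusive,
the R/Bioconductor convention. Product size is measured from the forward
primer's 5' start to the reverse primer's 5' start on the plus strand,
inclusive of both primer footprints — the convention under which the
341F/805R V3–V4 product is ~465 nt. The default product-size window
(50–2000 nt) exists only to exclude pathological self-priming on long
records; it comfortably contains any real V3–V4 product.

Subject ambiguity codes are treated with the same intersection semantics as
primer codes by default, so an `N` in a reference sequence matches
anything. This is the permissive choice and the only one that preserves
coverage monotonicity under primer widening; a `strict_subject` mode that
counts any non-ACGT subject character as a mismatch is exposed for
comparison, since reference databases differ in how aggressively they mask.

## What the synthetic generator emulates — and what it does not

`generate_refset()` builds clade-structured reference sets: records of
16S-like length (default 1300–1600 nt, drawn uniformly) of i.i.d. uniform
ACGT background, each non-decoy record carrying one planted forward site
and one planted reverse site at a random offset, with per-position
alternative alleles planted at controlled frequencies. The bundled
benchmark clade (`brocadiaceae_benchmark_clade()`) plants the T allele at
position 13 of the Pro341F template at frequency 0.75 — the allele pattern
that motivates the A→W widening, at a frequency chosen to represent a
dominant clade-specific variant that still leaves a minority of
reference-matching records. Ground truth (planted positions, alleles, and
expected coverage flags computed by positionwise base-set arithmetic,
independently of the matcher) is returned with the data.

What the generator does *not* emulate: phylogenetic correlation of the
background (real 16S is highly conserved, so off-target near-sites exist at
rates far above the uniform-background chance rate of ~48/4^17 per window);
indels inside the primer site; chimeras; length/quality artifacts; and any
correlation between taxonomy and site alleles beyond the planted one.
Passing tests on generated data therefore demonstrate the *algorithms* —
matcher correctness against a brute-force oracle, monotonicity, recovery of
planted structure — not field performance against a curated reference
database, which depends on that database's own allele distributions.

`generate_profiles()` likewise emulates a survey download: samples spread
round-robin over studies, genus draws from a shared pool, and
archaea/anammox positivity planted i.i.d. per sample. Defaults describe a
wastewater-survey scale (49 studies, 3433 samples, a ~1465-genus pool,
archaea in 22.5% and anammox taxa in 3.7% of samples). The i.i.d. planting
means per-study clustering of positives — conspicuous in real surveys,
where anammox concentrates in a minority of studies — is not modelled, so
only sample-level prevalences, not study-level breakdowns, are meaningful
recovery targets.

## Numerical choices and degenerate inputs

- Codes are 4-bit masks; matching, complementation and minimal-code lookup
  are table operations, and the minimal code covering a base set is unique
  by the bijection between the 15 codes and the nonempty subsets.
- `U` is accepted on input (rRNA-derived records) and mapped to `T`;
  anything else outside the 15 codes in a *primer* fails loudly with the
  offending symbol and position, while stray characters in *reference
  sequences* are replaced by `N` and counted, because a single corrupt
  record must not abort a whole-database run.
- Expansion enumeration refuses to run past an explicit cap
  (default 10 000) rather than exhaust memory.
- `enumerate_expansions()` output is sorted and duplicate-free, so
  degeneracy equals its length whenever enumerable — the identity the test
  suite exploits.
- Ties in the proposal ranking are broken down to the lexicographic primer
  string, making the optimizer deterministic by construction; the only
  randomness anywhere in the package lives in the generators, each driven
  by a single mandatory seed through a private RNG stream that leaves the
  caller's RNG state untouched.
- An empty reference set is a valid input everywhere and yields empty
  outputs (or `NA` percentages), never errors; a target clade with no
  locatable binding site is an explicit error, because an allele profile of
  nothing is meaningless.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
benchmark sets of 10–80 records of full 16S length, 200 randomized
matcher-oracle fixtures, 100 seeded optimizer replicates, and one
full-scale synthetic survey (3433 samples). These sizes keep every
distributional property of interest measurable while the whole suite runs
in a few minutes on one core. Scanning a real reference database is the
same code path — `read_refset()` streams any FASTA/taxonomy pair — but at
millions of records it is an hours-long batch job and is intentionally not
part of the test suite.

## Known limitations

- No thermodynamics: melting temperature, primer-dimer and 3' ΔG effects
  are out of scope; a proposal here is a *coverage* argument only.
- Specificity against off-target amplification (non-16S genomic background)
  is not evaluated.
- The optimizer widens the forward primer only per call; co-optimizing the
  reverse primer is structurally possible (swap the roles) but not tuned.
- Coverage weights every reference sequence equally; databases
  over-represent well-studied clades, and no abundance or dereplication
  correction is applied.
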