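# primertax

In-silico evaluation and optimization of degenerate 16S rRNA primers against
taxonomically annotated reference sets.

## The problem

Universal 16S primer pairs are chosen for broad prokaryotic coverage, but a
pair can still systematically miss an ecologically critical clade. The
canonical case is the anammox bacteria (family *Candidatus Brocadiaceae*,
order *Candidatus Brocadiales*, phylum *Planctomycetes*), which drive
autotrophic nitrogen removal in wastewater treatment yet are poorly matched
by the widely used V3–V4 forward primer Pro341F (`CCTACGGGNBGCASCAG`).
Widening position 13 from `A` to `W` (= A/T) yields Pro341FB
(`CCTACGGGNBGCWSCAG`), which accommodates the T allele these organisms carry
at that site while — being a strict superset primer — provably never losing a
sequence the original matched.

`primertax` implements the full workflow behind that kind of primer fix, for
anyone evaluating or repairing degenerate primers against a reference
collection:

- **IUPAC algebra** (`expand_code`, `code_for`, `complement_code`,
  `degeneracy`, `enumerate_expansions`): ambiguity codes as base sets; a
  primer's degeneracy is the product of per-position set sizes (Pro341FB:
  4·3·2·2 = 48 expansions, Pro341F: 24, and the 24 are a subset of the 48).
- **Reference-set IO** (`read_refset`, `filter_high_quality`,
  `subset_by_taxon`): FASTA with RDP-style `Lineage=` headers or a
  `seq_id → k__…;p__…;…;g__…` sidecar TSV; the quality rule keeps sequences
  strictly longer than 1200 nt.
- **In-silico PCR** (`find_hits`, `simulate_amplicon`, `covered`): a
  ProbeMatch-style degenerate matcher. A position matches when the primer
  code's base set and the subject code's base set intersect; a record is
  *covered* by a pair when a forward plus-strand site and a reverse
  minus-strand site form a product within the size bounds. Default is exact
  (0-mismatch) matching.
- **Coverage statistics** (`coverage_by_rank`, `compare_primer_pairs`,
  `lineage_drilldown`): per-taxon matched fractions at each rank
  (kingdom…genus), percentage-point deltas between pairs, and drilldowns
  along a lineage path.
- **The degeneration search** (`propose_degenerations`, `verify_proposal`):
  enumerate every strict base-set widening of a base primer (3'-terminal
  positions protected), score pair coverage on the target clade and on the
  full set, and rank by target gain first and parsimony (degeneracy
  multiplier) second. Every proposal is a superset primer, so global
  coverage can only grow — `verify_proposal` audits exactly that.
- **Profile mining** (`read_profiles`, `summarize_prevalence`): genus
  richness, per-kingdom prevalence and anammox prevalence across per-sample
  abundance profile tables (the five anammox genera are built in).
- **Synthetic data** (`synth_clade`, `generate_refset`, `generate_profiles`):
  seeded generators with planted primer-site alleles and planted
  prevalences, returning ground truth alongside the data.

## Worked example

Recover the Pro341F → Pro341FB edit from a synthetic benchmark: a
*Brocadiaceae*-like clade whose forward primer site carries the alternative
T allele at position 13 in 75% of records, plus an off-target background.

```r
library(primertax)

spec <- synth_refset_spec(
  clades = list(brocadiaceae_benchmark_clade(n = 12, allele_freq = 0.7)),
  decoys = list(n = 8, lineage = c(kingdom = "Bacteria",
                                   phylum = "Proteobacteria")),
  seed = 42)
g <- generate_refset(spec)

props <- propose_degenerations(
  primer("Pro341F", primer_registry()[["Pro341F"]]),
  primer("Pro805R", primer_registry()[["Pro805R"]]),
  g$refset,
  optimizer_config("family", "Candidatus Brocadiaceae"))
head(as.data.frame(props)[, c("positions_changed", "old_codes", "new_codes",
                              "proposed_sequence", "degeneracy",
                              "target_gain_pct", "global_delta_pct")], 3)
```

```
  positions_changed old_codes new_codes proposed_sequence degeneracy target_gain_pct global_delta_pct
1                13         A         W CCTACGGGNBGCWSCAG         48        66.66667               40
2                13         A         D CCTACGGGNBGCDSCAG         72        66.66667               40
3                13         A         H CCTACGGGNBGCHSCAG         72        66.66667               40
```

The top proposal is the A→W widening at position 13, producing exactly
`CCTACGGGNBGCWSCAG` (degeneracy 48, twice the base's 24): under this seed it
rescues the 66.7% of clade records the base primer missed, lifting 40% of
the whole set. The `D`/`H` candidates gain the same records but cost a 3×
degeneracy multiplier, so parsimony ranks them below `W`.

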