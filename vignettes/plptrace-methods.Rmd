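---
title: "Methods: cross-species and ancient-genome screening of pathogenic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species and ancient-genome screening of pathogenic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plptrace)
```

## The question and the two screens

Where do the pathogenic and likely-pathogenic (PLP) variants of a human
disease gene come from? Two observations can discriminate between deep
evolutionary conservation and recent, human-specific origin:

1. **Cross-species sharing.** If a human PLP allele is the normal aligned
   base in other vertebrates, the variant site predates the human lineage.
   We read each variant's orthologous column out of a multi-species
   whole-genome alignment (MAF) and classify every (variant, species) pair.
2. **Ancient-genome detection.** If a PLP allele is carried by ancient
   human individuals, its age is bounded below by the specimen's age. We
   screen per-sample read sets with a base-quality-filtered pileup.

`plptrace` implements both screens as reusable, tested components, plus the
cross-tabulations and tests that summarise them, and synthetic-data
generators that produce all inputs with machine-readable truth tables.

## The six-state alignment model

Every (variant, species) cell takes exactly one of six states:

| state | meaning | display code |
|---|---|---|
| `SHARED` | aligned base equals the human alternate allele | `R` |
| `WILDTYPE` | aligned base equals the human reference | `.` |
| `OTHER` | aligned base differs from both alleles (including `N`) | `B` |
| `GAP` | the species row has a gap in the covering block | `G` |
| `NO_ALIGN` | no aligned base (no covering block, or an e-line of status `C`/`M`) | `-` |
| `GAP_UNALIGNED` | gap containing unaligned species sequence (e-line `I`/`n`) | `=` |

The partition is exhaustive and exclusive; a variant's "shared species
count" is the number of `SHARED` cells in its row. Comparison is
case-insensitive because MAF soft-masks repeats with lowercase, and a
species `N` maps to `OTHER` since it matches neither allele. For a species
insertion at the queried column we compare only the single aligned column —
the extra species bases do not change a SNV's state.

**Indels.** A species shares a human indel only when the species row
differs from the human row by a gap run of *exactly* the indel's length,
with aligned bases on both flanks. A run of any other length would shift
the reading frame differently and is never `SHARED`; we map "no gap at the
locus" to `WILDTYPE` and "gap of the wrong length" to `OTHER`. This
length-equality rule is why frameshift indels — which dominate real PLP
panels — essentially never come back shared.

**Ambiguities.** When a species appears twice in one block the first row
is used and a message is logged. Minus-strand species rows keep MAF's
strand-relative start plus the source size, so their genomic coordinates
stay recoverable; their text is already alignment-oriented, so no
complementation happens at comparison time (relabelling a row's strand
representation provably changes no cell — this is a property test).

## Variant catalog

Input tables (VCF 4.x with a configurable significance INFO key, default
`CLNSIG`, or an equivalent TSV) are split per alternate allele and trimmed
to a minimal anchored representation so `(chrom, pos, ref, alt)` is a
stable key. Full left-alignment against a reference genome is out of scope
for table input; the trimming normalization is sufficient for the anchored
spellings the tests and generators produce. The PLP filter keeps exactly
three significance classes — pathogenic, likely pathogenic, and the
combined label — matching case-insensitively over a synonym list because
ClinVar spellings vary by release; records with conflicting
interpretations are always dropped.

The consequence classifier assigns exactly one category with a fixed
precedence: splice site > stopgain > frameshift indel/substitution >
non-frameshift indel/substitution > amino-acid change > UTR > intron.
The splice window is ±2 intronic bases around internal exon boundaries —
the canonical donor/acceptor dinucleotides — and is configurable
(`splice_window`), because published type tables rarely state how "splice
site" was separated from "intron". Coding SNVs are resolved by translating
the mutated codon with the standard genetic code; a synonymous change is
reported honestly as `synonymous SNV` even though real PLP panels contain
none. Domain intervals are closed on both ends in protein coordinates,
matching how domain tables are published; the residue of a variant is that
of its first affected coding base.

All internal interval arithmetic is 1-based and closed — the native
convention of R and of IRanges-style containers. VCF, MAF (0-based
starts) and SAM coordinates are converted once, at their parsers. We chose
this over a 0-based half-open internal convention because in R the
half-open style has to be translated at *every* use of `substr`,
`seq`, and `findInterval`, which multiplies rather than removes off-by-one
opportunities.

## Ancient-sample screen

Reads are walked through their CIGAR strings (`M`/`=`/`X` contribute a
base, `I`/`S` consume only query, `D`/`N` consume only reference), and a
pileup at a panel position counts bases with quality ≥ `min_bq`. The
threshold is inclusive — "minimal base quality 1" reads as a floor, so
quality 1 passes and only quality 0 is excluded. The default match
criterion is ≥ 1 alternate-supporting base at quality ≥ 1, with
`alt_count` and `depth` carried in the output so stricter post-filters
remain possible. Mapping-quality filtering defaults to off and duplicate
reads are not collapsed, since ancient data are typically deduplicated
upstream. Indel panel variants match only through explicit `I`/`D` CIGAR
operations of identical length at the locus, mirroring the alignment-side
length rule.

Summaries count *records* (one row per individual-variant detection) and
*distinct variants* separately; type and domain breakdowns are over
distinct variants. Published tables label the same molecular class both
"stopgain" and "nonsense"; the verbatim labels are preserved and counted
as printed, with a merged `n_stopgain_like` reported alongside.

## Statistics

* **Clade comparison.** The unit is the number of shared variants per
  species, grouped by clade, compared with a Kruskal–Wallis rank test
  (tie-corrected H, chi-squared approximation with `groups − 1` df). This
  is the only reading of a rank test "between clades" in which the groups
  have exchangeable units. The degenerate all-identical case returns
  H = 0, p = 1.
* **Domain distribution.** A 2×2 Pearson chi-squared of (shared vs not) ×
  (inside any domain vs outside), without Yates correction by default (a
  `correct` flag exists); tables with a zero margin are rejected as
  degenerate rather than returning NaN.
* Significance thresholds are surfaced as configuration, not hard-coded;
  no multiple-testing correction is applied, matching the summary style of
  published screens of this kind.
* Percentages print to one decimal, rounded half away from zero
  (`pct_round1`), which is how count tables are conventionally printed and
  lets every internally consistent published ratio re-derive exactly.

## Synthetic data and what it does (not) emulate

`simulate_alignment` evolves tip sequences from a reference (root)
sequence along a Newick tree under Jukes–Cantor substitution — the
simplest model with a closed form,
\(p = \tfrac{3}{4}(1 - e^{-\tfrac{4}{3} r b})\), used to validate the
generator within 3 standard errors. Planted shared alleles override the
neutral process at their cells (and accidental alternate hits in
non-planted species are reverted), planted deletions insert equal-length
or deliberately unequal gap runs, random geometric gap runs exercise the
gap state, and optional e-lines exercise the two absence states. Gaps are
placed per species independently — no indel phylogeny — which is
sufficient to exercise the state space but does not model shared indel
history. The truth table records the resulting state of every cell,
derived from the simulated arrays independently of the MAF writer/parser,
so recovery checks are end-to-end.

`simulate_ancient` draws reads uniformly over a contig; carriers are
heterozygous (each overlapping read is drawn from the alternate haplotype
with probability 0.5; a homozygous mode is a flag away by assigning
probability 1). Deamination damage is emulated as 5′-terminal C→T flips
at a configurable rate over the first two bases (reverse-strand reads show
G→A in reference orientation). Base qualities come from a configurable
distribution, by default 90% q37, 8% q20, 2% q0 — q0 ("no confidence")
bases are rare in real callers, and 2% keeps the quality-floor path
exercised without dominating the screen. Fragment-length distributions,
library protocols, reference bias and contamination are deliberately not
modelled; passing tests therefore demonstrate correctness of the screening
logic, not robustness to every artefact of real ancient libraries.

`make_panel` draws variants whose categories follow the published type mix
(44.2% frameshift deletion, 22.7% stopgain, …) on a twelve-exon toy
transcript with two domain intervals; the 950-codon CDS is sized so that
even the stopgain category — reachable by only ~0.45 single-base changes
per codon — has enough distinct variants to draw a 1,000-variant panel
without repeats. Every generated variant is verified against the
classifier, so the labels are true by construction.

## Problem sizes and determinism

Validation runs at deliberately desk-sized scales: random alignments of
~60 columns × 3–5 species for oracle equivalence (100+ instances),
Jukes–Cantor checks at 2,000 sites, and carrier recovery over 200 samples
at 8× coverage on a 300-bp locus with 76-bp reads. Under the heterozygous
model the per-carrier miss probability is \(E[(1-q)^N] = (1-pq)^n\) with
\(q = 0.5\,P(\mathrm{bq} \ge 1)\); the chosen geometry puts expected
recovery near 99.7%, so the ≥ 99% recovery check is a property of the
method rather than of a lucky seed. Every generator takes a mandatory
seed; identical configurations give byte-identical outputs, and the
pipeline's reports re-run byte-identically (stable sort orders, fixed
float formatting, no timestamps in provenance).

## Known limitations

* The consequence classifier is a minimal transcript-model annotator, not
  a full annotation engine: one transcript per gene, no HGVS parsing
  beyond pass-through, no start/stop-loss categories.
* Cross-species sharing is read at single-base resolution; a species base
  differing from both alleles counts as `OTHER` even if the codon is
  otherwise conserved.
* The indel rule is purely length-based, as published; no sequence-level
  re-alignment of the gap region is attempted.
* Founder-variant ages are ingested as literature data and never
  recomputed; genotype likelihoods, contamination estimates and damage
  rescaling are out of scope for the ancient screen.
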