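---
title: "Detecting taxonomically restricted genes: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting taxonomically restricted genes: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trgstrat)
```

## The problem

Every sequenced genome contains genes whose homologs are confined to a
narrow taxonomic group — taxonomically restricted genes (TRGs), with
*orphans* (no detectable homolog in any other species examined) as the
extreme case. In social insects these genes are interesting because novel,
lineage-specific behaviour (division of labour, brood care, nest building)
may be built partly from novel genes rather than only from rewired
conserved networks. trgstrat implements the comparative-genomics workflow
that supports this kind of study on a honey-bee-like focal genome:

1. classify every focal gene into a coarse phylostratum by two-tier
   homology search against a panel of comparison species;
2. summarise the structural characteristics of each class;
3. ask which TRGs could have been born by duplication of a conserved
   parent followed by rapid divergence;
4. test whether TRGs are over-represented among caste-biased expression
   sets with contingency-table statistics.

A seeded synthetic generator emulates the full input universe, so every
stage is validated against planted ground truth rather than against
irreproducible downloads.

## Homology model

Homology is operationalised exactly as in classic phylostratigraphy: a
local protein alignment with E-value below a cutoff (default `1e-4`). The
package's own engine is an exact Smith–Waterman aligner (affine gaps, a gap
of length $L$ costing `gap_open + gap_extend * L`, BLOSUM62 by default)
with Karlin–Altschul statistics

$$E = K \, m \, n \, e^{-\lambda S},$$

where $m$ is query length, $n$ total database residues, and $(\lambda, K)$
default to published BLOSUM62 values — the ungapped pair
$(0.3176, 0.134)$ in ungapped mode and the gap-11/1 pair $(0.267, 0.041)$
otherwise. These are configuration, not fitted values; users substituting
real BLAST hit tables bypass them entirely. The engine is exact, not
heuristic: there is no two-hit extension or X-drop, which is feasible at
synthetic scale and makes the oracle test below meaningful. Ambiguous
residues (`X`, and any character outside the matrix alphabet, including
stops in translated frames) score 0 against everything — a neutral
treatment that neither rewards nor punishes ambiguity.

Two operations use BLAST-style exact-word seeding because the procedure
they emulate specifies it: transcript support (ungapped, word size 20, no
low-complexity filtering) and EST-to-gene mapping. Ordinary searches run
the full dynamic program. Low-complexity masking is not implemented at all;
the configuration flag exists and setting it is an error, so a
configuration can never silently claim masking that never happened.

The deterministic tie-break (smallest query start, then subject start, for
equal scores) makes hit tables reproducible and order-independent.

### The exhaustive oracle

`smith_waterman_exhaustive()` computes the same quantity by enumerating
every monotone matching of residue positions — every possible local
alignment — and charging the same affine gap costs on internal unaligned
runs. It shares no code with the dynamic program and is exponential in
sequence length, so it is usable only for short sequences; the test suite
compares the two on >10^4 random pairs of length ≤ 6 over a reduced
alphabet, under several gap-penalty regimes so the gapped recursion is
genuinely exercised.

## Two-tier search and the seven classes

For each focal gene and comparison species, the protein set is searched
first (any splice isoform counts); only genes with no proteome hit are
re-searched against that species' genome in all six translated frames.
This mirrors the practice of rescuing homologs that are present in a
genome but missing from its annotation. The resulting gene × species
matrix stores `absent` / `present_protein` / `present_genome` together
with the best E-values, so presence can be re-derived at other cutoffs.

The seven classes are assigned most-specific-first:

| precedence | class | rule (over comparison species) |
|---|---|---|
| 1 | orphan | absent everywhere |
| 2 | hymenoptera_conserved | present in **all** Hymenoptera, absent outside |
| 3 | social_insect | present in **all** social-insect species, absent elsewhere |
| 4 | hymenoptera | present in ≥ 1 Hymenopteran, absent outside Hymenoptera |
| 5 | insect | present in **all** insects, absent in all non-insects |
| 6 | metazoa | present in **all** metazoans (non-metazoan outgroups ignored) |
| 7 | other | anything else |

The definitions overlap logically (all-Hymenoptera presence also satisfies
"at least one Hymenopteran"), so precedence is what makes the classes a
partition; `social_insect` is tested before the ≥ 1-Hymenopteran rule so
that ant-only genes are not absorbed into `hymenoptera`. The focal species
is trivially present in itself and never consulted. Presence in a
non-metazoan outgroup (yeast) neither helps nor harms the `metazoa` call.
The official-set/ab-initio flag is carried on gene records but never
influences classification — it is descriptive metadata.

`apply_external_recheck()` models the confirmation step in which candidate
TRGs are searched against a comprehensive external database: extra hits
with clade-tagged taxa are folded into the presence vector as
pseudo-species and the gene re-classified. Because hits only ever add
presence, a gene can move only towards a less restricted class — a
property the suite asserts over random cases.

## Gene characteristics

Per gene: protein size (longest isoform — chosen because a per-gene table
needs one number and the longest isoform is the conventional
representative), exon number (maximum over transcripts), gene span on the
1-based inclusive GFF3 convention, GC content of the CDS with ambiguous
bases excluded from numerator and denominator (a missing CDS yields a
missing value, never a silent zero), and transcript support. Class
summaries report mean ± SE with SE = sample sd/√n (0 when n = 1).
`cutoff_ratio_check()` re-derives support at several cutoffs from one pass
of best E-values, to verify that tightening the cutoff changes counts but
not the between-class ratios.

## Duplication origin

A restricted gene may be young because it duplicated from a conserved
parent and then diverged. `find_paralogs()` searches the TRG against the
whole focal gene universe (self and same-gene isoforms excluded by
identity, not score, reusing the homology cutoff), and
`flag_conserved_paralogs()` applies the class-specific escape rule: an
orphan needs a paralog present in any other species; a
Hymenoptera-restricted gene (hymenoptera, hymenoptera_conserved,
social_insect) needs a paralog with a homolog outside the Hymenoptera; an
insect-specific gene, outside the insects. Evidence is read off the
paralog's own presence row rather than re-searched, matching the
matrix-driven workflow; the two are equivalent at a fixed cutoff.

## Enrichment statistics

Expression inputs are EST lists (biased in each direction plus the
complete array list; the no-difference set is the complement). ESTs map to
genes by translated ungapped alignment with a quantified version of the
"large ungapped alignment to a single gene" acceptance rule: ≥ 33 aligned
residues (about 100 nt of a typical ~400 nt EST), E < 1e-4, and a ≥ 5-bit
lead over the runner-up gene — otherwise the EST is ambiguous and mapped
to nothing.

The headline test collapses classes to orphan vs non-orphan and
cross-tabulates against the three expression groups; with three columns
this gives the 2 df Pearson chi-square. The two-column nurse/forager
contrast is a 2×2 table and receives the Yates continuity correction
(`(|O−E|−0.5)²/E`); the correction is *only* defined for 2×2 tables here
and requesting it elsewhere is an error. Direct computation from the
published honey-bee counts confirms that this collapse and correction
policy — and no other grouping — reproduces both printed statistics
(χ² = 17.81, df = 2 and χ² = 0.49, df = 1), which is why it is the
default. Percentage deviations `100(O−E)/E` give effect directions; the
published worker-orphan cell reproduces at 82.7%. Where the running text
and the printed table disagree on a marginal count (537 vs 538
worker-biased genes), the printed table is taken as authoritative because
the statistics reproduce from it.

`cutoff_sensitivity_scan()` re-forms the biased sets at a descending
ladder of differential-expression p-value thresholds and re-runs the test,
reporting "insufficient data" rather than raising when a threshold empties
a set.

## The synthetic generator

`generate_world()` emits a complete, seeded input universe: a manifest
(focal bee; ants as social insects, with genomes, so the translated tier
is exercised; a solitary wasp; flies/other insects; non-insect metazoans;
a yeast-like outgroup), focal gene models (GFF3 + protein + CDS FASTA,
1–6 exons, ~10% of genes with a second truncated isoform), comparison
proteomes with unrelated background proteins, ESTs, and a caste contrast.
Defaults are a scaled-down version of the study conditions: 12 species,
210 genes over all seven classes, per-branch divergence 0.15 expected
substitutions/site (orthologs sit at twice that), class-specific protein
lengths and transcript-support probabilities following the qualitative
pattern that restricted genes are shorter and less supported, expression
group weights mirroring the queen/worker/no-difference proportions of the
brain microarray data, and an orphan odds ratio of 2.5 towards the
worker-like group. These sizes keep a full classification run under a
minute on one CPU while satisfying the ≥ 8 species / ≥ 200 genes scale at
which recovery is assessed.

Sequence divergence is modelled by `mutate_protein()`: Poisson(L·d)
substitution events at uniform positions (so the expected fraction of
sites touched is 1 − e^(−d)), replacements drawn with probability
∝ exp(BLOSUM62/2) against the current residue, which degrades alignment
score gradually. There are no indels and no rate heterogeneity — this is
deliberately *not* a phylogenetic simulator; consequently, passing
recovery tests demonstrates correctness of the classification logic and
E-value machinery, not robustness to the full messiness of real genomes
(fragmented assemblies, contaminated annotations, domain shuffling).

**Duplication-born TRGs** need their planted class and their planted
duplication history to be simultaneously true, which full-length smooth
divergence cannot deliver: a diverged copy of a conserved gene would
remain detectably similar to the parent's orthologs in other species and
therefore would not be an orphan. The generator instead models the
biologically coherent chimeric case: the parent (a conserved metazoan-class
gene) carries a lineage-specific 60-residue extension, present only in the
species of the child's class; the child TRG is a diverged copy of that
extension alone. The parent stays conserved through its core, the child's
cross-species presence comes only from extension carriers, and the
within-genome paralogy signal (child vs parent extension, 0.25 additional
divergence by default) is strong. Genomes are built by back-translating
(uniform synonymous codon choice) the relevant proteins into scaffolds
with random flanks; for two social-insect-class genes the homolog in one
ant is placed *only* in its genome, so the pipeline's translated tier has
planted positives.

Expression bias is planted per gene: assignment probabilities proportional
to group weights, with the worker-like weight multiplied by the odds ratio
for orphans, so the configured odds ratio is recovered exactly in
expectation. Under an odds ratio of 1 this is the null model used to check
type-I calibration of the chi-square at α = 0.05 over 1000 replicates.

## Numerical and design choices

- **Coordinates** are 1-based inclusive everywhere (GFF3/BLAST
  convention); there is no half-open representation anywhere to convert.
- **Database length** for E-values is total residues of the searched
  database (nucleotides for nucleotide databases) — the search-space
  convention of the tools being emulated.
- **Degenerate inputs**: empty EST databases give support `FALSE` (best
  E-value `Inf`), genome sequences shorter than one codon are skipped with
  a warning, an empty gene set classifies to an empty report, zero
  expected counts are an error naming the cell.
- **Determinism**: every stochastic routine takes or derives from an
  explicit seed; the generator restores the caller's RNG state; identical
  seeds give byte-identical fixture directories.
- **Exon counts** use the maximum over a gene's transcripts; whether the
  original tabulations used the longest transcript or an exon union is
  not documented anywhere we know of, and the maximum is the stable
  choice under isoform truncation.

## Problem sizes used by the validation suite

The routine test suite runs small worlds (~30 genes, 12 species); the
acceptance checks run the full default conditions (210 genes, 12 species)
twice — at zero and default divergence — plus a >10^4-pair alignment
oracle sweep, 1000 null calibration replicates and 400 odds-ratio
replicates. A full classification pass on the default world takes roughly
40 s on one CPU; the complete acceptance computation stays within a few
minutes.

## Known limitations

- The engine is exact and therefore quadratic per pair: suitable for
  synthetic validation and small panels, not for 27 real genomes — that is
  what the external hit-table adapter is for.
- Karlin–Altschul parameters for gapped alignment are configured
  constants, not fitted per matrix/gap combination.
- The generator plants neither indels, nor horizontal transfer, nor
  transposable-element exaptation; duplication origin is modelled only via
  the chimeric-extension mechanism described above.
- EST p-values in the generator are drawn from simple uniform/log-uniform
  families — adequate for threshold-scan mechanics, not a model of real
  microarray statistics.
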