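---
title: "Cross-species orthogroup classification of stress-responsive transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species orthogroup classification of stress-responsive transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthostress)
```

## The problem

Comparing stress transcriptomes across distantly related plants (a dicot such
as Arabidopsis and monocots such as rice and barley) cannot be done gene by
gene: gene content has diverged, and one-to-one orthology is the exception.
The unit of comparison in `orthostress` is therefore the *orthogroup* (OG) —
the set of genes across species descended from one ancestral gene, containing
orthologs and within-species paralogs, as produced by tools like OrthoFinder.
Given per-species differential-expression statistics for a panel of
treatments (here, six stress and hormone treatments: 3AT, AA, ABA, MV, SA,
UV), the package asks, per orthogroup and treatment, whether species respond
in the *same* direction (a conserved response), in *opposing* directions (an
opposite response), or in only one species, and then filters orthogroups
whose pattern recurs across treatments.

## Differential-expression calls

A gene is called differentially expressed when its FDR-adjusted p-value is
strictly below 0.05 and |log2 fold-change| >= 1. Both thresholds are
arguments of `call_degs()`. Published descriptions of this kind of filter
differ on whether the fold-change comparison is strict at the boundary; we
use `>=` by default and expose the comparator, since a |log2FC| exactly 1 is
a realistic value in rounded input tables. The package never recomputes
p-values: the statistic tables are the output of an upstream test (e.g. a
sleuth/Wald or DESeq2 analysis) and arrive already FDR-adjusted. Missing
q-values are conservatively treated as 1.

## Direction summaries and the mixed-direction exclusion

`summarize_directions()` reduces each (orthogroup, species, treatment) cell
to one of four states: `up`, `down`, `absent`, or `mixed_excluded`. The last
state implements the exclusion rule for multi-gene orthogroups: when a
species contributes both an up- and a down-regulated paralog to the same
orthogroup under the same treatment, that species' genes are removed from the
classification *for that treatment only*. Without this rule, a tandem array
with divergent members would count simultaneously as conserved and opposite
with every other species, and the tallies would be uninterpretable. The
exclusion is deliberately local: the same species may still classify cleanly
in other treatments, and the other species of the orthogroup are unaffected.

`classify_responses()` then records, for every focal species with a
directional state, which other species share the direction
(`conserved_with`) and which oppose it (`opposite_with`). A species that is
`absent` or `mixed_excluded` appears in neither set. The classification is
tested exhaustively: all 4^3 = 64 state combinations of a three-species
orthogroup are compared against a truth table in the test suite.

Gene-level tallies (`summarize_counts()`) project the orthogroup-level
relation onto each contributing DE gene. A gene conserved with one species
and opposite with the other counts in *both* tallies by default, because the
two relations are logically independent at the gene level; a `strict` mode
assigns such genes to the opposite tally only, so either bookkeeping
convention can be reproduced. Percentages are reported against the species'
DEG total for the treatment, with one decimal in machine outputs and a
round-half-up integer for display; the decimal column is canonical, because
prose summaries of such tables often mix rounding conventions.

## Multi-treatment (k-of-n) filters

`multi_treatment_filter()` selects orthogroups whose response recurs:

* `common_all_species`, k of n treatments in which *all* species share one
  non-excluded direction (optionally pinned to `up` or `down`), and
* `opposite_any_pair`, k treatments containing at least one opposing species
  pair.

For the opposite filter the default does **not** require the same species
pair to recur across treatments — an orthogroup opposite between At/Os under
one stress and At/Hv under another is biologically a recurrently divergent
orthogroup. Requiring pair identity is available as `same_pair = TRUE`. This
was a genuinely open design point; we default to the weaker reading because
the stronger one is recoverable from it but not vice versa.

## Promoter extraction and motif scanning

The mitochondrial dysfunction motif (MDM, `CTTGNNNNNCAMG`) is a degenerate
cis-element bound by NAC transcription factors (ANAC013/ANAC017) that marks
genes of the mitochondrial dysfunction stimulon (MDS). `extract_promoters()`
cuts the 2 kb immediately upstream of the *translation* start (first CDS
base) — not the transcription start — choosing per gene the transcript with
the longest total CDS (ties broken lexicographically). Promoters truncated
by contig ends are flagged; promoters shorter than the pattern are excluded
from scanning. No masking of neighbouring genes is applied.

`scan_motif()` performs exact degenerate matching: a window matches iff every
base lies in the IUPAC code's allowed set; no mismatches are tolerated and
overlapping matches are all counted. A genomic `N` is matched only by pattern
position `N`. Both strands are scanned by default (the reverse strand via the
reverse-complemented pattern, `CKTGNNNNNCAAG`, which is a *different*
pattern, so strandedness is material and exposed as a flag). The scanner is
regex-based with lookahead for overlaps; the test suite verifies exact
hit-count agreement with an independent per-offset scanner on random 2 kb
sequences, and that empirical background match frequency obeys the closed
form 2·(L−12)·2048/4^13 expected matches per promoter (the MDM admits
4^5 × 2 = 2048 concrete words among 4^13 13-mers).

## Enrichment statistics

Three standard tests sit behind the module surface, each driven by the
expressed-gene background (the union of gene ids in the species' statistic
tables — the universe that passed the upstream detection filter):

* **Motif presence, chi-square** (`mdm_enrichment()`): 2×2 chi-square
  (1 df) of motif presence/absence in a DEG set versus the remaining
  background. Presence, not hit count, is tested. No Yates correction by
  default — backgrounds are thousands of genes, where the correction is
  immaterial — with a flag to enable it.
* **TF-family over-representation, hypergeometric**
  (`hypergeom_enrichment()`): one-sided upper tail P[X ≥ k]. One-sided,
  because the question asked of each family is "enriched?"; the lower tail is
  reported alongside. Raw p-values are the primary column (no correction is
  applied by default), with Benjamini–Hochberg columns always emitted.
* **Category over-representation, Fisher** (`fisher_ora()`): exact test on
  the 2×2 table, the statistic used by category-bin ORA tools.

`opposite_family_detection()` flags a family enriched in the up-regulated set
of one species and the down-regulated set of another for the same treatment —
the signature of regulatory divergence at the family level.

The MDS candidate filter (`mds_candidates()`) keeps genes that are (1) in a
supplied regulatory-network list, (2) MDM-positive in the promoter, (3) DE
after both mitochondrial-stress treatments (AA and 3AT by default), and (4)
DE in at least three treatments overall. An or-mode over the two required
treatments is available (`require_all = FALSE`) because figure-legend and
prose descriptions of such filters sometimes differ on and/or; the
conjunctive rule is the default.

## The synthetic-data generator

Real cross-species RNA-seq with matched genomes is far too large to carry in
a package, and reproducing headline counts of any particular study requires
its deposited data. Every pipeline stage is therefore validated against a
generator that plants known structure:

* **Orthogroups** (`generate_orthogroups()`): three species × 500
  orthogroups by default; each species contributes one gene plus a paralog
  with probability 0.3 (giving the closed-form 1 − 0.7³ chance that an
  orthogroup has a multi-gene species). Each OG receives one planted class:
  conserved in all three species (0.15), conserved in one pair (0.15),
  opposite in a pair (0.15), single-species response (0.20), mixed
  up/down paralogs within one species (0.05, to exercise the exclusion
  rule; requires a paralog, so with `paralog_prob = 0` its mass folds into
  the single-species class), or null (0.30). The mixture was chosen once to
  give every downstream branch non-trivial counts; it does not model any
  particular study's class balance.
* **DE statistics** (`generate_deg_tables()`): planted DE genes get
  q ~ U(0, 0.05) and log2FC = ±3 + N(0, 0.2); null genes q ~ U(0.05, 1) and
  a truncated-normal log2FC strictly inside (−1, 1). The q-value model is a
  stylised two-block uniform, not a fitted test statistic — downstream code
  only thresholds at 0.05, so nothing more is needed, and it keeps the
  generator free of any read-count model. Each non-null OG is active in a
  uniform 1–6 of the treatments, which exercises every k-of-n boundary.
* **Promoters** (`generate_promoters()`): iid uniform A/C/G/T sequences of
  2 kb; one exact MDM instance (degenerate positions drawn uniformly) is
  overwritten at a uniform offset with probability 0.15 for target genes
  versus 0.05 for background — a 3× planting contrast on top of the ~0.11
  per-2kb-promoter chance-occurrence rate. At most one instance is planted
  per promoter and instances never span boundaries; random matches may add
  more. With an output directory the generator also writes a one-contig-
  per-gene genome FASTA and GFF3 (half the genes on the minus strand) that
  round-trip exactly through `extract_promoters()`.

What the generator does *not* emulate: read-count noise and its
mean–variance structure, library-size effects, correlated q-values and
fold-changes, promoter base composition and repeat structure, orthology
inference errors, and multi-contig gene models. Passing tests therefore
demonstrate the correctness of thresholding, bookkeeping, scanning and
testing machinery under known truth — not robustness of any upstream
quantification or orthology inference on real data.

## Numerical choices and degenerate inputs

* FDR threshold strict (`<`), fold-change threshold inclusive (`>=`),
  comparator configurable.
* Chi-square without continuity correction (flag available); the 2×2 test is
  refused (an error, not a silent 0) when the DEG set is empty or the
  background carries no motif gene.
* Hypergeometric and one-sided Fisher p-values agree to 1e-12 by
  construction; both are checked against subset enumeration for all tables
  with N ≤ 12.
* Display percentages round half up; machine outputs keep one decimal.
* Orthogroup tables are validated on read: a gene in two orthogroups, a
  duplicated gene in a statistic table, or an unknown species column is an
  error naming the offending token, never a silent coercion.
* Determinism: all generators are seeded per stage from the design seed;
  the same design yields byte-identical FASTA/TSV outputs, and
  `run_pipeline()` on the same inputs writes byte-identical result files.

## Problem sizes used by the test and acceptance runs

The shipped validation runs use 500 orthogroups × 3 species × 6 treatments
(≈ 2,000 genes), 2 kb promoters for the genome round-trip and frequency
checks, and power simulations of 200 replicates with a universe of 1,500
genes, 500 bp promoters and a DEG set of 300 for the motif test (a size at
which the 3× planting contrast has > 99% analytic power at α = 0.01), and a
universe of 2,000 with a family of 20 at 5× enrichment for the
hypergeometric test. These sizes are the package's own validation design:
large enough that every branch and boundary is exercised and binomial checks
are tight, small enough to run routinely.

## Known limitations

* Classification is defined for any number of species ≥ 2, but the shipped
  truth-table test enumerates the three-species case.
* The heatmap export orders rows by orthogroup membership; clustering of
  rows is left to the plotting layer (e.g. `pheatmap`/`ComplexHeatmap`).
* Promoter extraction assumes one representative transcript per gene; genes
  whose isoforms have distinct translation starts are represented by the
  longest-CDS isoform only.
* The unassigned-gene sidecar reports DE genes outside any orthogroup, but
  they enter no orthology-based tally.
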