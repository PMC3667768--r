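---
title: "Assessing RBP-miRNA cooperativity in 3'UTRs with utrcoop"
author: "utrcoop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing RBP-miRNA cooperativity in 3'UTRs with utrcoop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

RNA-binding proteins (RBPs) and microRNAs both regulate transcript decay
through elements in 3'UTRs, and there is case-study evidence that some RBPs
— Pumilio (PUM, consensus `UGUANAUA`) in particular — cooperate with
specific miRNAs: binding of the protein remodels local secondary structure
and exposes a nearby miRNA seed-match site to the RISC complex.  `utrcoop`
implements a transcriptome-scale computational assessment of this
cooperativity hypothesis as a reusable, tested pipeline:

1. **Motif gating by conservation.**  Candidate RBP consensus motifs are
   screened by requiring that their 3'UTR occurrences are evolutionarily
   conserved more often than composition-matched shuffled motifs.
2. **Positional localization** of motif sites along 3'UTRs.
3. **Co-localization calling.**  For each (RBP, miRNA family) pair, the
   number of seed-match sites within 50 nt of an RBP site is compared with
   identity-permutation nulls; families enriched at FDR <= 0.05 under all
   three null schemes and for both seed types are called *interacting*.
4. **Decay and conservation contrasts** across transcript groups defined by
   the presence and proximity of interacting-family sites.
5. **Structure rescue.**  Folding each proximal pair window with and
   without the RBP site masked quantifies how many seed-site nucleotides
   RBP binding would free from intramolecular pairing.
6. **Seed hybridization.**  A local-alignment score measures the ability of
   each family's seed site to base-pair with the reversed RBP motif.

Because the genome-scale inputs (multi-species UTR alignments, half-life
compendia, small-RNA counts) are external downloads, the package ships a
synthetic-data generator that reproduces the statistical structure every
stage assumes, with planted signal and exact ground truth.  All empirical
statements below are computed by the test suite or by
`scripts/acceptance.R`; nothing is asserted that the code does not
recompute.

## Conventions

All site coordinates are **0-based, half-open intervals on the reference
UTR sequence** in 5'-to-3' sense orientation; strand resolution is assumed
to have happened upstream, at annotation time.  Sequences use the RNA
alphabet `A,C,G,U` plus `N`; `T` on input is mapped to `U`.  A masked `N`
in a subject sequence never matches a motif letter — including a pattern
`N` — so masked bases cannot create sites.

## Motif model and conservation gate

Motifs are IUPAC consensus patterns scanned as regular expressions; every
overlapping occurrence is reported.  For each reference hit, a species
counts as *conserved* when its aligned row contains a match whose start
maps within +/-10 nt (reference-anchored) of the hit.  The **branch length
score (BLS)** of the hit is the total branch length of the minimal
phylogenetic subtree connecting the conserved species, as a fraction of
the whole tree.  A hit conserved only in the reference has BLS 0 and still
counts at threshold 0.

Two refinements guard the BLS:

* **Distant-hit pruning.**  A single hit in a distant species can inflate
  the score.  The most distant conserved species is dropped when the
  species between it and the next-nearest conserved species that lack the
  motif number more than one-third of the aligned genomes, *and* its
  distance to the reference is more than twice that of the second-most
  distant conserved species.  We read the two published clauses as a
  conjunction and operationalize "gap" as the count of non-conserved
  species strictly between the two distances; the comparison is against
  the raw fraction n/3 (a ceiling would contradict the rule's own
  motivating example of 2 missing out of 4 aligned genomes).  Species
  distance is tree path length, not rank.

* **Shuffled-motif controls.**  200 random permutations of the motif
  letters are generated; candidates falling in the top 10% of pairwise
  similarity to the canonical motif or an already-retained control are
  discarded as redundant, and up to 10 controls are kept, preferring those
  with a genome hit count within +/-20% of the canonical motif.  Motifs
  with fewer than 3 distinct shuffles (homopolymer-like patterns) are
  flagged ineligible.  Similarity is an ungapped sliding column-overlap
  score on the letter-probability profiles (1 minus half the squared
  Euclidean column distance, averaged over the best overlap of at least 4
  columns) — a self-contained stand-in for an external motif-comparison
  tool that preserves the redundancy-pruning intent.

The **precision** at a BLS threshold t is
`1 - mean(shuffled hits >= t) / (canonical hits >= t)`, evaluated on the
101-point grid t = 0.00, 0.01, ..., 1.00.  An RBP motif passes the gate
when some threshold reaches precision >= 0.6 with more than 10 canonical
hits remaining.

## Seed families

From each mature miRNA, two 7-nt seed-match site types are derived: the
7mer-m8 site (reverse complement of miRNA nucleotides 2-8) and the 7mer-1A
site (reverse complement of nucleotides 2-7 followed by `A` opposite
position 1).  The published description says the site motifs are "the
complements" of the seed; we default to reverse complements (standard
TargetScan site orientation) and keep the literal complement available as
a configuration switch (`orientation = "complement"`).  Families with
identical m8 sites are collapsed, concatenating their names.

## Co-localization statistic

Every (RBP site, miRNA site) pair on a transcript is assigned an
edge-to-edge gap (overlapping sites get gap 0 — adjacent-element semantics
for "within 50 nt") and a signed 50-nt window index, ten windows per side.
Pairs are never deduplicated: one miRNA site next to two RBP sites
contributes two pairs.  The null keeps every site's position fixed and
permutes family identities within strata:

* `plain` — one stratum per chromosome (synthetic transcripts stand in for
  chromosomes; configurable);
* `by_decile` — strata are the 3'UTR decile of the site start, controlling
  positional preference;
* `by_au_category` — strata are the A/U count of the 7-nt seed pattern
  (6-7 / 3-5 / 0-2), controlling AU composition.

The empirical p-value is the raw proportion of permutation replicates with
a count at least as large as observed (an add-one smoothed mode is
available because raw zeros make Benjamini-Hochberg adjustment
degenerate); q-values are BH within each scheme x seed type x window
batch, across families.  A family is **interacting** when, in the first
50-nt window, both seed types pass q <= 0.05 under all three schemes.  The
upstream (-1) and downstream (0) windows are evaluated separately and a
family qualifies if it passes in either; the publication is silent on
pooling, and enrichment appears on both sides of the RBP site, so the
disjunction preserves symmetric signal without mixing the two null
geometries.  Window heatmaps report, per (family, window), the minimum
over schemes of observed/expected.

## Decay and conservation groups

Only *expressed* families — the top 25% by read count, ties included —
enter the grouping.  Each transcript falls into one of `Int-proximal`,
`Int-distant`, `Nonint-proximal`, `Nonint-distant`, or `unclassified`,
with interacting status taking precedence over non-interacting and
proximal over distant (the published prose leaves the overlaps ambiguous;
the precedence rule makes the assignment a function).  Group values
(half-lives, decay rates, site-level BLS) are summarized with median,
quartiles and 1.5xIQR whiskers and compared two-sided with rank-sum tests;
both half-life and decay-rate tables are supported, with direction
recorded (shorter half-life = larger decay rate).  For small groups the
package enumerates the exact mid-rank permutation distribution, which
keeps tied small-sample cases exact; Wilcoxon tests are two-sided by
default since the published captions do not state a direction.

## Structure rescue

For each proximal pair the folding window spans 5 nt upstream of the
5'-most site to 5 nt downstream of the 3'-most site, clamped at UTR
boundaries (the publication does not address boundary pairs).  `C1` is the
number of seed-site positions paired in the folded window, `C2` the same
after the RBP site plus one flanking nucleotide per side is masked to `N`,
and the rescue count is `C = C1 - C2`.  Only the seed-site positions are
counted.

Folding is a pluggable engine boundary:

* **vienna** — RNAfold MFE structures (thermodynamic; required to
  reproduce the published p27^Kip1 worked example once its UTR sequence is
  supplied).  Structures with energy larger than -1 kcal/mol are treated
  as totally open, as published.
* **fallback** — a compiled maximum-base-pairing (Nussinov) engine with
  minimum hairpin loop 3 and G-U wobble, pseudo-energy -1 per pair.  It
  keeps the entire test suite free of thermodynamic parameters and is
  exactly verifiable against exhaustive structure enumeration.  The open
  rule uses `>=` on the integer pseudo-energy so that single-pair
  structures count as open; this is the reading under which designed
  hairpin fixtures satisfy C = C1, since any PUM-site hairpin leaves one
  internal U-A pair in the masked window.

The background model dinucleotide-shuffles each window (exact mono- and
di-nucleotide count preservation via the Eulerian-path construction,
endpoints fixed) while keeping the site intervals in place, and tallies
the rescue histogram over 10 randomizations (mean and SD per bin).

## Seed hybridization score

Each family's 8-mer seed site (7mer-m8 plus the 1A adenosine) is aligned
locally (Smith-Waterman) against the *reversed* RBP motif with match 2 for
any A-U, G-C or G-U pairing (both orientations; wobble symmetry assumed),
mismatch 0 and indel -1, as published.  A degenerate motif letter matches
a seed base if any expansion pairs with it, so the PUM `N` matches
everything.  Because mismatches cost 0, internal gaps flanked by
mismatches never help; ties are broken toward the shortest, then most 5',
alignment, keeping reported alignments deterministic.  Interacting and
non-interacting families' scores are compared by rank-sum test, and
histograms against shuffled-motif controls are reported.

## The synthetic-data generator

`sim_config()` fixes the study conditions; its defaults are the conditions
under which the package's acceptance checks run, and they are not tuned
per run:

* 8 species on a random coalescent tree rescaled to total branch length 4
  substitutions/site (typical of a placental-mammal UTR alignment), with
  the reference as the first leaf;
* 400 UTRs with log-normal lengths (median 1.2 kb, sdlog 0.5, minimum
  80 nt) and a linear AU gradient from 0.45 at the 5' end to 0.65 at the
  3' end, emulating the AU rise toward UTR ends;
* the PUM consensus planted at 1.2 expected sites per UTR (regulatory
  element density of order one per UTR; random 8-mer background occurrence
  alone would be ~0.1);
* 50 miRNA seed families, 200 planted sites per family and seed type.
  Seed-region AU counts are prescribed (planted families 4 of 7, others
  cycling 2-6) so every AU permutation stratum is well-populated — with
  only 50 families, random composition can leave a stratum nearly empty,
  which makes the AU-stratified null degenerate for a family stranded
  alone in its stratum;
* 5 planted "interacting" families whose sites are deliberately placed
  within 50 nt of an RBP site at a rate solving
  `p + c(1-p) = 3c` for the realized chance-proximity `c`, i.e. a 3-fold
  excess proximal fraction; placements retry rather than silently fall
  back, and planted sites never overwrite RBP sites, so truth is exact;
* half-lives log-normal (median 8 h, sdlog 0.5) with a 0.7x multiplier on
  every transcript where a planted-family site lies within 50 nt of an RBP
  site *as re-scanned from the final sequences* — background occurrences
  of the planted patterns are part of the truth bookkeeping, so the
  planted effect coincides with what an analysis of the sequences can see;
* Zipf-skewed read counts (exponent 1.1) with planted families occupying
  the top ranks, so the planted decay effect acts through expressed
  miRNAs, mirroring the expression filter's role in the real analysis.

Non-reference alignment rows are mutated by independent substitutions (no
indels) at a per-branch rate, and each planted site is copied verbatim
into a nested distance-ordered species subset of random depth, giving BLS
variation; explicitly configured plantings (`planted_conservation`) use an
exact species subset for conservation unit tests.  What the generator does
*not* emulate: indel evolution and alignment error, realistic target-site
context beyond AU composition, 3'UTR isoforms, and dependence between
neighboring sites.  Passing tests therefore demonstrate the statistical
machinery, not performance on real alignments.

## Problem sizes and numerical choices

The default acceptance study uses 400 UTRs, 50 families and 1000
permutation replicates; the null-calibration suite uses 50 datasets of 100
UTRs, 12 families and 200 replicates.  These sizes give the permutation
p-values a resolution (1/1000, 1/200) comfortably below the 0.05 FDR
threshold while keeping a full run in minutes on one core.  Empirical
p-values use the raw tail proportion by default (publication-faithful);
BH is applied within each scheme/seed/window batch.  Degenerate cases are
handled explicitly: empty strata permute trivially; a zero control
proportion in the positional binomial test is floored at
1/(total control sites + 1); zero null means in enrichment ratios give 1
for observed 0 and are capped at observed x replicates otherwise; and
group comparisons with fewer than two values are skipped and flagged
rather than reported.

## Known limitations

* The conservation model assumes gapless-enough alignments that a +/-10 nt
  reference-anchored window is meaningful; heavily gapped blocks will
  under-count conservation.
* The fallback folding engine maximizes pair counts, not free energy;
  rescue counts under it are a combinatorial surrogate and are expected to
  differ from RNAfold values on real sequences (the engines agree on the
  designed fixtures by construction).
* Empirical p-values of 0 are reported as 0 in the default mode; use
  `add_one = TRUE` when downstream consumers cannot tolerate zeros.
* The published genome-scale numbers (e.g. the specific human and mouse
  interacting-miRNA lists) require the external UCSC/TargetScan/half-life
  downloads and are out of scope for the shipped tests; the pipeline
  supports such runs through `load_dataset()` once the files are provided.
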