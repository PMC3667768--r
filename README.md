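# utrcoop

Computational assessment of cooperativity between RNA-binding proteins
(RBPs) and microRNAs in 3'UTRs.

Both RBPs and miRNAs promote transcript decay through 3'UTR elements, and
for Pumilio (PUM, consensus `UGUANAUA`) there is experimental evidence
that protein binding remodels local RNA secondary structure and exposes
nearby miRNA seed-match sites to the RISC complex.  `utrcoop` implements
the transcriptome-scale statistical machinery to ask where and how often
this happens:

* **Conservation gating** of IUPAC consensus motifs: per-site branch
  length scores (BLS — total branch length of the minimal phylogenetic
  subtree connecting the species conserving the site, as a fraction of
  the whole tree), shuffled-motif controls, and the precision curve
  `1 - E[shuffled hits]/canonical hits` over BLS thresholds; a motif is
  kept when some threshold reaches precision >= 0.6 with > 10 hits.
* **Positional localization** of sites in UTR deciles and end-anchored
  100-nt windows, with an exact binomial enrichment test against
  composition-matched controls (Bonferroni over 10 bins).
* **Interacting-miRNA calling**: for each (RBP, miRNA family), the number
  of seed-match sites within 50 nt of an RBP site is compared against
  nulls that permute miRNA site identities (positions fixed) — plain,
  within UTR-decile strata, and within seed AU-content strata.  Empirical
  p-values are tail proportions over permutation replicates; families
  with Benjamini-Hochberg q <= 0.05 for both seed types (7mer-m8 and
  7mer-1A) under all three schemes in the first 50-nt window are called
  *interacting*.
* **Decay/conservation contrasts** between transcripts grouped by the
  presence and proximity (<= 50 nt) of interacting-family sites
  (Int-proximal / Int-distant / Nonint-proximal / Nonint-distant),
  restricted to the top-25%-expressed miRNA families, compared with
  rank-sum tests.
* **Structure rescue**: each proximal pair window (sites +/-5 nt flanks)
  is folded, the RBP site masked to `N` (+/-1 nt), and the window folded
  again; the rescue count `C = C1 - C2` is the number of seed-site
  nucleotides freed from intramolecular pairing.  Engines: RNAfold
  (`vienna`) or a compiled maximum-pairing engine (`fallback`), with a
  dinucleotide-preserving shuffle background.
* **Seed hybridization**: Smith-Waterman local alignment of each family's
  8-mer seed site against the reversed RBP motif (pair match 2, mismatch
  0, indel -1), comparing interacting vs non-interacting families.

A synthetic-data generator (`sim_config()` / `simulate_dataset()`)
produces download-free datasets with planted signal and exact ground
truth, in the same standard formats the genome-scale path reads (newick,
MAF, BED6, TSV), so the whole pipeline is testable end to end.

## Worked example

Simulate the default study (400 UTRs, 8 species, 50 seed families, 5 of
them planted with 3-fold excess proximal co-occurrence and a 0.7x
half-life multiplier), call interacting families, and test the decay
contrast:

```r
library(utrcoop)

sim  <- simulate_dataset(sim_config())
seqs <- utr_ref_seqs(sim$utrs)
rbp  <- scan_utr_sites(seqs, sim$rbp_motif)      # PUM consensus sites
fam  <- scan_family_sites(seqs, sim$families)    # m8 + 1A seed-match sites

it    <- colocalization_test(rbp, fam, nchar(seqs),
                             n_perm = 1000, seed = 42)
calls <- call_interacting_mirnas(it, fdr = 0.05)
calls
#> [1] "fam001" "fam002" "fam003" "fam004" "fam005" "fam030"
sim$truth$planted_families
#> [1] "fam001" "fam002" "fam003" "fam004" "fam005"
```

All five planted families are recovered, with one false call (`fam030`)
— FDR control bounds, but does not eliminate, false discoveries.
(`run_pipeline()` chains this with the gating, localization, decay,
rescue and hybridization stages, writing one report TSV per stage.)  The
decay contrast on the same dataset:

```r
expressed <- filter_expressed_mirnas(sim$expression)
assign <- classify_transcripts_by_pairing(rbp, fam, calls,
                                          expressed, names(sim$utrs))
hl  <- setNames(sim$halflife$halflife_h, sim$halflife$transcript_id)
cmp <- compare_group_values(split(hl[assign$transcript_id], assign$group))
subset(cmp$tests, group2 == "Int-distant")$p
#> [1] 0.01264495
```

Transcripts with a proximal interacting-family site decay significantly
faster than those whose interacting sites are distant — the planted 0.7x
half-life effect is recovered.  A single rescue computation looks like:

```r
rescue_count("CUGUAGAUACCCCAUCUACAC", c(1, 9), c(13, 20))
#> <rescue_result> C1 = 7, C2 = 0, C = 7
```

Here all 7 seed-site bases are paired to the PUM site in a hairpin (C1 =
7) and masking the PUM site frees all of them (C2 = 0): rescue count 7.

## Command line

```sh
exec/utrcoop simulate --out-dir data --seed 7
exec/utrcoop run-all  --out-dir results --seed 7 --n-perm 1000
```

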