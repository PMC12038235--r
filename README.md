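# bclhap

Structural haplotype analysis of the grapevine **berry color locus (BCL)**
— the cluster of *VvMybA* transcription-factor genes on chromosome 2 that
controls anthocyanin accumulation in berry skin, and with it whether a
cultivar bears black or white grapes.

The package is written for grape geneticists and, more broadly, for anyone
working on structural variation in tandem gene clusters. It implements, as
tested and reusable functions, the computational workflow for
characterising the divergent **haplotype F** of the BCL and its deleted
derivative **HapF^DEL^**:

* a **seeded synthetic-locus generator** for the five haplotype
  architectures (HapA, HapC-N, HapF1, HapF2, HapF^DEL^) with their
  diagnostic features — the Gret1 retrotransposon silencing the *VvMybA1*
  promoter in HapA; the 44/111/33-bp insertions defining *VvMybA1_SUB*;
  the 209-bp exon-3 deletion inactivating *VvMybA3* outside haplotype F;
  the 6.1-kb *VvMybA4* tandem duplication of HapF2 (90% copy identity, one
  copy with a 213-bp exon-3 insertion, the other with an RLG element in
  exon 1); and the ~76-kb deletion that leaves HapF^DEL^ with only
  *VvMybA1*, *VvMybA9* and *VvMybA13* — plus DNA/RNA read simulators, so
  the whole pipeline runs without any external data;
* **subhaplotype diagnosis from reads**: junction, insertion-span,
  private-SNP and absence-region markers scanned on alignments, with the
  decision rule that calls HapF1 / HapF2 / HapF^DEL^ / no-HapF /
  ambiguous;
* **in-silico PCR** emulating the INDEL assay that detects
  *VvMybA3_HapF*;
* **allele-specific expression**: private SNPs from a multi-allele cDNA
  alignment, per-allele proportions from RNA pileups, and per-allele TPM
  (`tpm_i = (c_i/l_i) / Σ_j (c_j/l_j) × 10⁶`);
* **locus structure**: R2R3-probe gene discovery, exact-word dotplots,
  structural diffs between haplotypes, CDS translation, and **LTR
  insertion dating** `T = K/(2µ)` with Jukes-Cantor-corrected LTR
  divergence `K` (default µ = 1.3×10⁻⁸ substitutions/site/year);
* **phylogenetics**: Tamura-Nei (TN93) distances, UPGMA, bootstrap
  consensus with branches under 90% support collapsed, outgroup rooting,
  Newick IO;
* **single-locus genetics**: 3:1 segregation chi-square, allele
  frequencies, genotype×phenotype contingency with Fisher's exact test,
  haplotype-dosage comparison of anthocyanin content (Welch), and survey
  aggregation.

## Worked example

Build the locus, simulate a diploid HapF2/HapA accession at 20× depth,
and call its subhaplotype from the reads:

```r
library(bclhap)

cfg   <- default_locus_config(seed = 1)
f2    <- build_haplotype("HapF2", cfg)
hapA  <- build_haplotype("HapA", cfg)
panel <- hapf_marker_panel(cfg)

reads <- simulate_dna_reads(list(f2, hapA), depth = 20, read_len = 150,
                            error_rate = 0.005, seed = 42)
diagnose_reads(reads, panel, accession = "synthetic_F2xA")
```

```
<haplotype_call> synthetic_F2xA: HapF2
  hapF_ins33         insertion_span sup   10  opp    0  (HapF)
  snp_intron2_99     private_snp    sup   15  opp    3  (HapF)
  tandem_junction    junction       sup    6  opp    0  (HapF2)
  ins213_A4a         insertion_span sup   12  opp    0  (HapF2)
  rlg_A4b_junction   junction       sup    8  opp    0  (HapF2)
  absence_left       absence_region sup   30  opp   68  (HapF_DEL)
  absence_right      absence_region sup   35  opp   73  (HapF_DEL)
  del_junction       junction       sup    0  opp    0  (HapF_DEL)
```

Ten reads span the 33-bp intron-2 insertion of *VvMybA1_SUB* (haplotype F
is present), six span the tandem-copy junction (corroborated by the
213-bp span and the RLG junction), and the deleted interval's interior is
covered (`opp` 68/73 on the absence markers), so the call is HapF2 — not
HapF^DEL^.

Comparing the intact and deleted haplotypes localises the deletion:

```r
detect_structural_diff(f2, build_haplotype("HapF_DEL", cfg))
```

```
<structural_diff> HapF2 vs HapF_DEL
  deletion 58920..134526 (75.6 kb): 6 genes
  [VvMybA3,VvMybA11,VvMybA10,VvMybA2,VvMybA4a,VvMybA4b];
  1401 bp upstream of VvMybA3, 10799 bp downstream of VvMybA4b
```

Dating a retrotransposon from its LTR pair, and the single-locus
statistics:

```r
ltr_age(f2$te_features$RLG_1, mu = 1.3e-8, sequence = f2$sequence)
#> <te_age_estimate> RLG_1: p = 0.0175, K(JC69) = 0.0177, age = 0.68 Myr

segregation_test(151, 36)
#> <segregation_result> 151:36 vs 3:1 -> chi-square = 3.30, p = 0.0695 (df = 1)

allele_frequency(71, 528)$percent_reported
#> [1] 7
```

The 151:36 black:white cross fits 3:1 single-locus segregation
(chi-square 3.30, not significant at 5%), and 71 carriers among 528
diploid accessions give a 7% allele frequency.

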