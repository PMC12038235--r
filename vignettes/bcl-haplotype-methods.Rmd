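---
title: "Methods: synthetic berry-color-locus haplotypes and their analysis"
author: "bclhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic berry-color-locus haplotypes and their analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bclhap)
```

# The locus and the questions

The berry color locus (BCL) on grapevine chromosome 2 is a tandem cluster
of *VvMybA* MYB transcription-factor genes. Functional *VvMybA* alleles
activate *UFGT* and anthocyanin synthesis in berry skin; cultivars whose
BCL haplotypes are all non-functional bear white berries. The classical
white haplotype, HapA, is silenced by the Gret1 retrotransposon in the
*VvMybA1* promoter and by point mutations in *VvMybA2* and a 209-bp
deletion in *VvMybA3*. Haplotype F is a structurally divergent alternative:
its *VvMybA1* allele (*VvMybA1_SUB*) carries three small intronic
insertions (44, 111 and 33 bp), its *VvMybA3* lacks the 209-bp deletion,
and the cluster carries extra members, including the divergent *VvMybA13*.
Three subforms matter: HapF1 (single *VvMybA4*), HapF2 (a tandem
duplication producing *VvMybA4a*/*VvMybA4b*), and HapF^DEL^, in which a
roughly 76-kb deletion has removed six of the nine MybA genes — a second,
independent route to white berries.

This package implements the analyses that characterise these haplotypes —
read-based subhaplotype diagnosis, allele-specific expression,
retrotransposon dating, gene-family phylogenetics, and the single-locus
genetics — driven by a synthetic-locus generator, so every computation is
reproducible at the desk from a seed.

# The synthetic locus

## What the generator emulates

`default_locus_config(seed)` derives everything from one seed:

* **Gene templates.** Nine MybA paralogs share one architecture: 300-bp
  promoter, three exons (240 + 130 + 383 bp; 753-bp CDS; 250-aa protein,
  matching the functional allele's length), introns of 200 and 300 bp, a
  100-bp 3'UTR. Template sequences are pseudo-random at GC 0.45, not real
  *Vitis* sequence; real sequences can be substituted via templates in the
  config. Paralogs descend from a common ancestor through two group
  ancestors (the *VvMybA1/2/3/9* group and the *VvMybA4/10/11* group, each
  ~10% from the ancestor, members ~3–4% within groups), with *VvMybA13*
  placed at 16% CDS divergence so its identity to the rest falls in the
  observed 60–78% band, and an *AtMyb75*-like outgroup at 35%. Coding
  mutations avoid stop codons so every template stays translatable.
* **Alleles** are edit lists on templates: Gret1 (450-bp LTRs) in the
  *VvMybA1a* promoter; the 44/111/33-bp insertions, an intron-2
  position-99 SNP and private exonic SNPs for *VvMybA1_SUB*; the 282-bp
  in-frame C-terminal duplication shared by the *VvMybA2* templates, with
  the CA dinucleotide deletion and R44L substitution added for *VvMybA2w*;
  the 209-bp exon-3 deletion for non-F *VvMybA3*; the 213-bp exon-3
  insertion (*VvMybA4a*) and an RLG element in exon 1 (*VvMybA4b*).
* **Allele-private SNPs** for expression analysis are planted at third
  codon positions where the three quantified genes share a base, six per
  allele, spread evenly along the eligible CDS (codons 10–129 and
  215–232). The spreading matters: clustered SNPs would sample one read
  window and defeat the averaging across SNPs. Excluded regions: the
  209-bp/CA-deletion territory (privacy requires ungapped columns), codon
  44, and the INDEL-assay reverse-primer footprint. Substitutions flip the
  third position to C (or T when already C), which can never create a stop.
* **Haplotype assembly.** HapF1/F2/F^DEL^ share one seeded intergenic
  backbone, HapA/HapC-N another, so F-family intergenic sequence is
  private to F — mirroring the real situation in which the haplotypes'
  intergenic space has diverged, and giving the absence markers something
  to measure. Spacer lengths are calibrated (weights 1.34 outside, 0.773
  inside the deleted interval; ±8% per-gap jitter normalised to a fixed
  total) so HapF2 spans 138 ± 2 kb while the HapF^DEL^ deletion is ~76 kb.
  Gene order and orientation at this locus are only schematically known;
  the defaults (all genes forward; F order A13, A9, A1, A3, A11, A10, A2,
  A4-region) are declared approximations. HapF^DEL^ is produced by exact
  substring deletion from HapF2 — from 1.4 kb upstream of *VvMybA3* to
  10.8 kb downstream of *VvMybA4b* — because only HapF2 holds the six
  deleted genes as one contiguous block. Intact retrotransposons are
  placed with identical LTR pairs aged by a Poisson clock (below); ages
  0.15 (Gret1), 0.19, 0.5, 0.69 (the RLG in *VvMybA4b*) and 1.19 Myr.

One wrinkle the generator does **not** model: somatic chimerism (distinct
L1/L2 cell layers, as in bronze-berried mutants) and ONT-style indel
errors. The read simulators are substitution-only; the diagnostics depend
on spanning and matching, and indel errors would add nothing at desk
scale. Coordinates are 1-based closed throughout (the Bioconductor
convention, shared by the GFF3 output); this keeps every IRanges/GRanges
interaction conversion-free.

## Read simulation

`simulate_dna_reads()` draws uniform start positions, assigns each read of
a diploid pair to either haplotype with probability 1/2, flips half the
reads to the minus strand, applies i.i.d. substitution errors, and keeps
truth labels; it is bit-reproducible from its seed. For a diploid the
`depth` argument is the total depth relative to the mean haplotype length,
so each haplotype contributes about `depth/2`. `simulate_rna_reads()`
draws allele read counts multinomially with probabilities proportional to
`tpm × length` (TPM is a per-molecule measure; fragment counts scale with
length), then uniform positions within each cDNA.

# Subhaplotype diagnosis

Real alignments enter as SAM (`read_sam()`, via Rsamtools); simulated
reads are aligned by an internal exact-seed mapper (24-bp seeds at two
offsets, both strands, full-length ungapped verification with at most 6%
mismatches). The strictness is the point: a read crossing a structural
breakpoint that the reference lacks *fails* verification, which is
precisely the evidence model the markers need. The mapper is not a
general-purpose aligner and is documented as simulation plumbing.

`hapf_marker_panel()` extracts small reference windows from the built
HapF2 and defines eight markers; `scan_marker()` counts evidence:

* *junction* / *insertion-span*: a read supports the feature iff it aligns
  contiguously with ≥ `min_overhang` (default 20 bp) matched bases on both
  sides of the breakpoint (for insertions, of either insertion boundary —
  a 150-bp read cannot span a 213-bp insert in full);
* *private SNP*: supporting reads carry the expected base, opposing reads
  any other;
* *absence region*: opposing reads overlap the interior of the deleted
  interval by ≥ `min_overhang`; supporting reads cover the retained flank.
  Requiring covered flanks distinguishes a deletion from missing data —
  the explicit form of what visual alignment inspection does implicitly.

`classify_subhaplotype()` then applies the decision rule: no HapF without
≥ `min_reads` (default 3) reads spanning the 33-bp intron-2 insertion;
HapF^DEL^ when both absence windows are confirmed and no tandem/213-bp/RLG
junction support exists; HapF2 on tandem-junction support with the two
corroborating markers; HapF1 otherwise, but only when the interval
interior is demonstrably covered. Any conflicting combination returns
`ambiguous` — a miss is allowed to be ambiguous, never a wrong positive.
Thresholds were fixed a priori at `min_overhang = 20`, `min_reads = 3`
(the reference protocol inspected alignments visually; these make that
judgement explicit and configurable). Which subhaplotype the intron-2
position-99 SNP distinguishes is not settled, so the marker is carried as
configurable corroboration and takes no part in the decision rule.

The in-silico PCR (`insilico_pcr()`) uses exact primer matching in both
orientations, so product lengths are invariant under reverse-complementing
the template; the *VvMybA3_HapF* assay scores the presence of the
209-bp-longer product.

# Allele-specific expression

`find_private_snps()` takes a **pre-aligned** set of allele cDNAs (the
built-in six-allele set reconstructs its alignment exactly from the known
indel structure) and reports columns where exactly one sequence differs,
ungapped, from an otherwise identical background; with only two sequences
no state can be called the background, so at least three are required.

Quantification assigns each RNA read to its best-matching allele cDNA and
pools placements per gene (quantify per gene, then split). A single
consensus per gene is attractive but breaks with an ungapped mapper when
alleles differ by indels — reads spanning the 209-bp or CA deletion
junctions become unmappable and bias the pileup — whereas per-allele
competitive mapping measures the same private-SNP frequencies without the
artifact. Per-allele frequency is the unweighted mean over that allele's
private SNPs (a depth-weighted mean is available behind a flag, off by
default, since plain averaging is the reference behaviour). Before
renormalising within the gene, frequencies are corrected by the
coverage-per-transcript factor `(L − r + 1)/L`: with read length `r`, a
transcript of length `L` yields per-column depth proportional to
`tpm·L/(L−r+1)`, so without the correction the shorter allele of a gene
(e.g. the 544-bp deleted *VvMybA3* vs its 753-bp full-length counterpart)
is systematically over-weighted. Proportions below the detection floor
(default 0.01) are reported not-detected — the "n. d." convention.
`min_depth` per SNP column defaults to 10. Gene-level TPM uses the exact
closed form over the quantified genes only; the package does not quantify
a transcriptome.

What the passing tests do and do not show: proportion recovery within
three binomial standard errors is demonstrated on substitution-only reads
with evenly spread private SNPs; real RNA-seq adds mappability and
sequencing-error structure (errors slightly inflate rare-allele
frequencies) that the bound does not model.

# Locus structure and dating

Gene discovery scans both strands with windowed local alignment
(Biostrings) of the R2R3 probe — exon 1 + intron 1 + exon 2 of *VvMybA1*,
the conserved family core — keeping hits at ≥ 60% identity (low enough for
*VvMybA13*) and ≥ 60% probe coverage, merging across windows. The
structural diff anchors a single deletion by common prefix/suffix of the
two sequences (exact for a substring deletion; the anchor can slide by a
few bases where flank and deleted sequence coincide) and falls back to
annotation anchors otherwise; it reports contained genes and the
upstream/downstream offsets to the first and last of them, and its two
directions are mirror images.

LTR dating: the element's two LTRs are globally aligned; the raw mismatch
fraction `p` (gap columns excluded) is corrected for multiple hits with
Jukes-Cantor, `K = −(3/4)·ln(1 − 4p/3)` (Kimura two-parameter behind a
flag; the appropriate correction at these divergences differs negligibly),
and `T = K/(2µ)`. µ defaults to 1.3×10⁻⁸ substitutions/site/year and is a
stated assumption, configurable. Pairs under 60% identity are rejected as
unreliable rather than dated. The generator ages LTRs by drawing
`Poisson(µ·T·L)` substitutions per LTR at distinct positions; at small
`µ·T·L` (young elements, short LTRs) single estimates are dominated by
Poisson noise — the package's recovery property therefore averages 20
replicates per age, and single-element dates, like the default config's
Gret1 (the expected 0.15-Myr divergence of a 450-bp LTR pair is under two
substitutions), should be read with that variance in mind.

# Phylogenetics

Distances are Tamura-Nei (TN93) via `ape::dist.dna` with per-pair complete
deletion of gapped sites by default (global complete-deletion is a flag;
the reference protocol does not state its gap handling). Saturated pairs
return `+Inf` with a warning rather than a clipped value. Trees are UPGMA
(`phangorn::upgma`: average linkage, heights half the merge distance,
ultrametric; ties resolved by matrix order). `bootstrap_consensus()`
resamples columns, scores the point-estimate tree's bipartitions
(`ape::boot.phylo`), collapses branches under the support threshold
(default 90%) by merging each weak node into its parent with the collapsed
length pushed onto the children — preserving ultrametricity — and roots on
the outgroup. Supports are computed once, on the point-estimate topology,
not recomputed after collapsing. Within a bootstrap replicate a saturated
distance is replaced by twice the largest finite distance so the replicate
still yields a tree; the point estimate itself never silently clips.

# Genetics statistics

The segregation test is the uncorrected Pearson goodness-of-fit (the
continuity-corrected statistic would not reproduce the 151:36 result);
its chi-square equals the squared z of the binomial proportion test, which
the suite checks numerically. Allele frequency assumes one allele copy per
carrier unless told otherwise, and reports integer percent rounded
half-up, like the survey aggregation. The genotype×phenotype table is
tested by Fisher's exact test on the black/non-black collapse with an
explicit perfect-separation flag. The dosage comparison is Welch's
two-sample test (the underlying test in the reference analysis is
unstated; a mean comparison of this kind is the natural reading) with the
effect expressed as percent difference of means; two constant identical
groups short-circuit to p = 1.

# Problem sizes and determinism

Everything is seeded: one seed generates the configuration, and every
simulator takes its own. Test problem sizes are chosen for desk-scale
statistical resolution: 138-kb haplotypes; diploid read sets at 20× (about
17,000 150-bp reads) across ten seeds per haplotype pair for the
diagnosis round-trip; 30,000–50,000 RNA reads for expression recovery;
1000 bootstrap replicates for the consensus tree; 20 replicates per age
for dating recovery.

# Known limitations

* Templates are random sequences with a shared exon architecture; intron
  divergence between paralogs is uniform rather than structured, and there
  is no repeat landscape beyond the planted TEs.
* The internal mapper is ungapped and substitution-only; real aligner
  artifacts (soft-clips, multi-mapping in the duplication) are not
  emulated. Real alignments should be produced externally and imported as
  SAM.
* Gene order/orientation and intergenic distances are schematic defaults.
* The ASE estimator measures within-gene allele proportions; cDNAs more
  similar across genes than the synthetic ~6% paralog divergence would
  raise cross-assignment.
* Phylogeny assumes a clock (UPGMA); rate heterogeneity among paralogs
  would distort depths, though the bootstrap supports would reveal the
  fragility.
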