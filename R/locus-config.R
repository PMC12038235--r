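## Gene architecture shared by all synthetic MybA templates (bp).
## Three exons (R2R3 MYB layout: R2R3 DNA-binding domain on exons 1-2,
## C-terminal domain on exon 3); CDS = 753 bp = 251 codons = 250 aa + stop.
GENE_GEOM <- list(prom = 300L, e1 = 240L, i1 = 200L, e2 = 130L,
                  i2 = 300L, e3 = 383L, utr3 = 100L)

gene_part_starts <- function() {
  g <- GENE_GEOM
  e1s <- g$prom + 1L
  i1s <- e1s + g$e1
  e2s <- i1s + g$i1
  i2s <- e2s + g$e2
  e3s <- i2s + g$i2
  utrs <- e3s + g$e3
  list(e1 = e1s, i1 = i1s, e2 = e2s, i2 = i2s, e3 = e3s, utr = utrs,
       len = utrs + g$utr3 - 1L)
}

# map a coordinate on the 753-bp spliced CDS to the genomic template
cds_to_genomic <- function(pos) {
  g <- GENE_GEOM
  p <- gene_part_starts()
  ifelse(pos <= g$e1, p$e1 - 1L + pos,
         ifelse(pos <= g$e1 + g$e2, p$e2 - 1L + (pos - g$e1),
                p$e3 - 1L + (pos - g$e1 - g$e2)))
}

assemble_template <- function(name, prom, cds, i1, i2, utr3) {
  g <- GENE_GEOM
  e1 <- substr(cds, 1L, g$e1)
  e2 <- substr(cds, g$e1 + 1L, g$e1 + g$e2)
  e3 <- substr(cds, g$e1 + g$e2 + 1L, nchar(cds))
  p <- gene_part_starts()
  gene_template(
    name,
    paste0(prom, e1, i1, e2, i2, e3, utr3),
    exons = rbind(c(p$e1, p$e1 + g$e1 - 1L),
                  c(p$e2, p$e2 + g$e2 - 1L),
                  c(p$e3, p$e3 + g$e3 - 1L)),
    promoter = c(1L, g$prom))
}

# derive a paralog's parts from ancestral parts at given divergences
derive_parts <- function(parts, cds_div, nc_div) {
  list(prom = mutate_dna(parts$prom, nc_div),
       cds  = mutate_cds(parts$cds, cds_div),
       i1   = mutate_dna(parts$i1, nc_div),
       i2   = mutate_dna(parts$i2, nc_div),
       utr3 = mutate_dna(parts$utr3, nc_div))
}

make_template <- function(name, parts) {
  assemble_template(name, parts$prom, parts$cds, parts$i1, parts$i2,
                    parts$utr3)
}

# third-codon-position substitution that can never create a stop codon
flip_third <- function(base) if (base == "C") "T" else "C"

#' Default synthetic berry-color-locus configuration
#'
#' Builds, from a single seed, everything the synthetic locus needs: the nine
#' MybA gene templates (three paralog groups -- the VvMybA1/2/3/9 group, the
#' VvMybA4/10/11 group, and the divergent VvMybA13, plus the HapA-private
#' VvMybA5 and an AtMyb75-like outgroup), the allele variant catalogue
#' (Gret1 promoter insertion for VvMybA1a; the 44/111/33-bp insertions and
#' intron-2 SNP of VvMybA1_SUB; the 209-bp exon-3 deletion of non-F VvMybA3;
#' the CA dinucleotide deletion and R44L substitution of VvMybA2w; planted
#' allele-private exonic SNPs for allele-specific expression), the LTR
#' retrotransposons with their insertion ages, and the locus geometry
#' (gene orders, intergenic spacers scaled so HapF2 spans about 138 kb, the
#' 6.1-kb tandem-duplication block at 90% copy identity, and the HapF^DEL
#' deletion offsets: 1.4 kb upstream of VvMybA3 to 10.8 kb downstream of
#' VvMybA4b).
#'
#' @param seed Integer seed; the whole configuration is a deterministic
#'   function of it.
#' @param spacer_mean Mean intergenic spacer length in bp. The default is
#'   calibrated so the HapF2 locus spans 138 +/- 2 kb.
#' @param mu LTR molecular-clock substitution rate, per site per year.
#' @return An object of class `locus_config`.
#' @export
default_locus_config <- function(seed = 1L, spacer_mean = 12460L,
                                 mu = 1.3e-8) {
  set.seed(as.integer(seed))
  g <- GENE_GEOM

  anc <- list(prom = random_dna(g$prom), cds = random_cds(251L),
              i1 = random_dna(g$i1), i2 = random_dna(g$i2),
              utr3 = random_dna(g$utr3))
  grp1 <- derive_parts(anc, 0.10, 0.14)   # VvMybA1/2/3/9 group
  grp2 <- derive_parts(anc, 0.10, 0.14)   # VvMybA4/10/11 group
  parts <- list(
    VvMybA1  = derive_parts(grp1, 0.03, 0.05),
    VvMybA2  = derive_parts(grp1, 0.03, 0.05),
    VvMybA3  = derive_parts(grp1, 0.03, 0.05),
    VvMybA9  = derive_parts(grp1, 0.04, 0.06),
    VvMybA4  = derive_parts(grp2, 0.03, 0.05),
    VvMybA10 = derive_parts(grp2, 0.04, 0.06),
    VvMybA11 = derive_parts(grp2, 0.03, 0.05),
    VvMybA13 = derive_parts(anc, 0.16, 0.22), # 60-78% identity to the rest
    VvMybA5  = derive_parts(grp2, 0.05, 0.07))
  templates <- Map(make_template, names(parts), parts)
  outgroup <- make_template("AtMyb75", derive_parts(anc, 0.35, 0.45))

  ## VvMybA2 carries a 282-bp in-frame duplication of the C-terminal domain
  ## (present in both its functional alleles); duplicate the last 282 coding
  ## bases before the stop, i.e. CDS 469..750.
  dup_start <- cds_to_genomic(469L)
  templates$VvMybA2 <- build_allele(
    templates$VvMybA2,
    list(variant_spec("duplication", dup_start, 282L,
                      label = "CR_282bp_duplication", identity = 1)))

  ## Allele-private exonic SNPs: third codon positions where the three ASE
  ## genes (VvMybA1/2/3) share a base, so the edited allele is the only
  ## divergent sequence at that alignment column. Codons 130..214 are
  ## excluded (209-bp deletion / CA-deletion territory), 233..242 sit under
  ## the INDEL-assay reverse primer, and codon 44 carries the R44L change.
  ## The 36 picks are spread evenly along the CDS so each allele's SNPs
  ## sample decorrelated read windows.
  third_base <- function(tpl, codon) {
    substr(tpl$sequence, cds_to_genomic(3L * codon), cds_to_genomic(3L * codon))
  }
  pool <- Filter(function(co) {
    b <- vapply(templates[c("VvMybA1", "VvMybA2", "VvMybA3")], third_base,
                character(1L), codon = co)
    length(unique(b)) == 1L
  }, setdiff(c(10:129, 215:232), 44L))
  stopifnot(length(pool) >= 36L)
  picks <- pool[unique(round(seq(1L, length(pool), length.out = 36L)))]
  stopifnot(length(picks) == 36L)
  snp_codons <- split(picks, rep(1:6, times = 6L))
  names(snp_codons) <- c("VvMybA1_SUB", "VvMybA1a", "VvMybA2_HapF",
                         "VvMybA2w", "VvMybA3_HapF", "VvMybA3del")
  planted <- function(allele, gene) {
    lapply(snp_codons[[allele]], function(co) {
      pos <- cds_to_genomic(3L * co)
      variant_spec("substitution", pos,
                   flip_third(substr(templates[[gene]]$sequence, pos, pos)),
                   label = paste0(allele, "_snp_c", co))
    })
  }

  ## Retrotransposons (ages from the insertion-dating analyses: Gret1
  ## 0.15 Myr; HapF elements 0.19-1.19 Myr; the RLG in VvMybA4b 0.69 Myr).
  tes <- list(
    Gret1 = make_te("Gret1", ltr_len = 450L, internal_len = 4100L,
                    age = 0.15e6, mu = mu),
    RLG_1 = make_te("RLG_1", ltr_len = 400L, internal_len = 2000L,
                    age = 0.69e6, mu = mu),
    RLC_1 = make_te("RLC_1", ltr_len = 350L, internal_len = 1800L,
                    age = 0.19e6, mu = mu),
    RLG_2 = make_te("RLG_2", ltr_len = 400L, internal_len = 2200L,
                    age = 0.50e6, mu = mu),
    RLC_2 = make_te("RLC_2", ltr_len = 350L, internal_len = 2300L,
                    age = 1.19e6, mu = mu))

  p <- gene_part_starts()
  i2_99 <- p$i2 + 98L   # position 99 of intron 2
  snp99_state <- flip_third(substr(templates$VvMybA1$sequence, i2_99, i2_99))

  alleles <- list(
    VvMybA1c = list(gene = "VvMybA1", variants = list()),
    VvMybA1a = list(gene = "VvMybA1", variants = c(
      list(variant_spec("te_insertion", 150L, tes$Gret1,
                        label = "Gret1_promoter")),
      planted("VvMybA1a", "VvMybA1"))),
    VvMybA1_SUB = list(gene = "VvMybA1", variants = c(
      list(variant_spec("insertion", p$i1 + 59L, random_dna(44L),
                        label = "ins44_intron1"),
           variant_spec("insertion", p$i2 + 119L, random_dna(111L),
                        label = "ins111_intron2"),
           variant_spec("insertion", p$i2 + 199L, random_dna(33L),
                        label = "ins33_intron2"),
           variant_spec("substitution", i2_99, snp99_state,
                        label = "snp_intron2_pos99")),
      planted("VvMybA1_SUB", "VvMybA1"))),
    VvMybA2r = list(gene = "VvMybA2", variants = list()),
    VvMybA2w = list(gene = "VvMybA2", variants = c(
      list(variant_spec("deletion", cds_to_genomic(400L), 2L,
                        label = "CA_deletion"),
           variant_spec("substitution", cds_to_genomic(130L), "CTG",
                        label = "R44L")),
      planted("VvMybA2w", "VvMybA2"))),
    VvMybA2_HapF = list(gene = "VvMybA2",
                        variants = planted("VvMybA2_HapF", "VvMybA2")),
    VvMybA3del = list(gene = "VvMybA3", variants = c(
      list(variant_spec("deletion", cds_to_genomic(400L), 209L,
                        label = "del209_exon3")),
      planted("VvMybA3del", "VvMybA3"))),
    VvMybA3_HapF = list(gene = "VvMybA3",
                        variants = planted("VvMybA3_HapF", "VvMybA3")),
    VvMybA4a = list(gene = "VvMybA4", variants = list(
      variant_spec("insertion", cds_to_genomic(430L), random_dna(213L),
                   label = "ins213_exon3"))),
    VvMybA4b = list(gene = "VvMybA4", variants = list(
      variant_spec("te_insertion", p$e1 + 99L, tes$RLG_1,
                   label = "RLG_exon1"))))

  structure(list(
    seed = as.integer(seed),
    mu = mu,
    spacer_mean = as.integer(spacer_mean),
    spacer_jitter = 0.08,
    flank_left = 3000L,
    flank_right = 12000L,
    dup_pad_up = 2200L,
    dup_pad_down = 2247L,
    dup_identity = 0.90,
    del_upstream = 1400L,     # deletion starts this far upstream of VvMybA3
    del_downstream = 10800L,  # and ends this far downstream of VvMybA4b
    templates = templates,
    outgroup = outgroup,
    alleles = alleles,
    tes = tes,
    snp99 = list(position_template = i2_99, state = snp99_state),
    gene_order = list(
      F = c("VvMybA13", "VvMybA9", "VvMybA1", "VvMybA3", "VvMybA11",
            "VvMybA10", "VvMybA2", "VvMybA4"),
      A = c("VvMybA5", "VvMybA9", "VvMybA1", "VvMybA10", "VvMybA2",
            "VvMybA11", "VvMybA3", "VvMybA4")),
    ## relative spacer weights per gap; the F backbone is denser inside the
    ## deleted interval (gaps 4-7) so that the HapF2 span is ~138 kb while
    ## the HapF^DEL deletion is ~76 kb, as observed
    spacer_weights = list(F = c(1.34, 1.34, 1.34, 0.773, 0.773, 0.773,
                                0.773),
                          A = rep(1, 7L)),
    hap_alleles = list(
      F = c(VvMybA13 = NA, VvMybA9 = NA, VvMybA1 = "VvMybA1_SUB",
            VvMybA3 = "VvMybA3_HapF", VvMybA11 = NA, VvMybA10 = NA,
            VvMybA2 = "VvMybA2_HapF", VvMybA4 = NA),
      A = c(VvMybA5 = NA, VvMybA9 = NA, VvMybA1 = "VvMybA1a",
            VvMybA10 = NA, VvMybA2 = "VvMybA2w", VvMybA11 = NA,
            VvMybA3 = "VvMybA3del", VvMybA4 = NA),
      `C-N` = c(VvMybA5 = NA, VvMybA9 = NA, VvMybA1 = "VvMybA1c",
                VvMybA10 = NA, VvMybA2 = "VvMybA2r", VvMybA11 = NA,
                VvMybA3 = "VvMybA3del", VvMybA4 = NA)),
    intergenic_tes = list(
      list(te = "RLC_1", after = "VvMybA13"),
      list(te = "RLG_2", after = "VvMybA11"),
      list(te = "RLC_2", after = "VvMybA10"))),
    class = "locus_config")
}

#' @export
print.locus_config <- function(x, ...) {
  cat(sprintf(paste0("<locus_config> seed %d: %d gene templates, ",
                     "%d alleles, %d TEs, spacer %d bp\n"),
              x$seed, length(x$templates), length(x$alleles),
              length(x$tes), x$spacer_mean))
  invisible(x)
}

#' Write / read the scalar locus parameters as YAML
#'
#' Only the reproducible inputs are serialized (seed, rates, geometry); the
#' sequences themselves are regenerated from the seed on read, so a config
#' round-trips exactly.
#'
#' @param config A [default_locus_config()] object.
#' @param path YAML file path.
#' @return `write_locus_config` returns `path` invisibly;
#'   `read_locus_config` returns the reconstructed `locus_config`.
#' @export
write_locus_config <- function(config, path) {
  yaml::write_yaml(list(seed = config$seed, spacer_mean = config$spacer_mean,
                        mu = config$mu), path)
  invisible(path)
}

#' @rdname write_locus_config
#' @export
read_locus_config <- function(path) {
  p <- yaml::read_yaml(path)
  default_locus_config(seed = p$seed, spacer_mean = p$spacer_mean, mu = p$mu)
}

# final (post-edit) coordinate of an original-template position, given the
# allele's variant list (variants are specified on original coordinates)
edited_position <- function(variants, pos) {
  shift <- 0L
  for (v in variants) {
    if (v$position <= pos) {
      if (v$kind %in% c("insertion", "te_insertion")) {
        shift <- shift + variant_length(v)
      } else if (v$kind == "deletion") {
        shift <- shift - variant_length(v)
      }
    }
  }
  pos + shift
}
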