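#' Build a synthetic berry-color-locus haplotype
#'
#' Assembles the full locus sequence and annotations for one of the five
#' structural haplotypes: `HapA` and `HapC-N` (eight MybA genes, shared gene
#' order and intergenic backbone, differing in alleles: HapA carries
#' Gret1-silenced VvMybA1a, the doubly mutated VvMybA2w and the 209-bp
#' deleted VvMybA3), `HapF1` (eight genes incl. the divergent VvMybA13, a
#' single VvMybA4), `HapF2` (nine genes: the VvMybA4 region tandemly
#' duplicated at 90% copy identity, one copy carrying a 213-bp exon-3
#' insertion, the other an RLG retrotransposon in exon 1) and `HapF_DEL`
#' (HapF2 with the interval from 1.4 kb upstream of VvMybA3 to 10.8 kb
#' downstream of VvMybA4b removed, leaving VvMybA1, VvMybA9 and VvMybA13).
#'
#' HapF1, HapF2 and HapF_DEL share one seeded intergenic backbone; HapA and
#' HapC-N share another, so F-haplotype spacers are private to the F family
#' (as the real haplotypes' intergenic space is), which the diagnostic
#' markers exploit.
#'
#' @param name One of `"HapA"`, `"HapC-N"`, `"HapF1"`, `"HapF2"`,
#'   `"HapF_DEL"`.
#' @param config A [default_locus_config()].
#' @return An object of class `haplotype_model`: list with `name`,
#'   `sequence`, `genes` (per-gene edited templates with offsets),
#'   `te_features`, `annotations` (data.frame of gene/exon/TE/LTR
#'   intervals, 1-based closed), plus haplotype-specific fields
#'   (`tandem_junction` for HapF2; `deletion`, `del_junction` and `parent`
#'   for HapF_DEL).
#' @export
build_haplotype <- function(name, config = default_locus_config()) {
  name <- match.arg(name, c("HapA", "HapC-N", "HapF1", "HapF2", "HapF_DEL"))
  stopifnot(inherits(config, "locus_config"))
  if (name == "HapF_DEL") return(build_hapf_del(config))
  family <- if (name %in% c("HapA", "HapC-N")) "A" else "F"
  allele_key <- switch(name, HapA = "A", `HapC-N` = "C-N", "F")
  assemble_haplotype(name, family, allele_key,
                     tandem_dup = (name == "HapF2"), config)
}

assemble_haplotype <- function(name, family, allele_key, tandem_dup,
                               config) {
  order <- config$gene_order[[family]]
  alleles <- config$hap_alleles[[allele_key]]
  n_spacer <- length(order) - 1L

  ## scaffold randomness is drawn up-front in a fixed order so that all
  ## haplotypes of a family share spacers/flanks exactly
  set.seed(config$seed + if (family == "F") 101L else 202L)
  jit <- stats::runif(n_spacer, 1 - config$spacer_jitter,
                      1 + config$spacer_jitter)
  jit <- jit * config$spacer_weights[[family]]
  spacer_len <- as.integer(round(jit / sum(jit) * n_spacer *
                                   config$spacer_mean))
  spacer_seq <- vapply(spacer_len, random_dna, character(1L))
  flank_left <- random_dna(config$flank_left)
  flank_right <- random_dna(config$flank_right)
  pad_u <- random_dna(config$dup_pad_up)
  pad_d <- random_dna(config$dup_pad_down)

  a4_base <- config$templates$VvMybA4
  base_block <- paste0(pad_u, a4_base$sequence, pad_d)
  copy2_mut <- mutate_dna(base_block, 1 - config$dup_identity)

  st <- locus_state()
  st <- push_seq(st, flank_left)
  for (i in seq_along(order)) {
    gene <- order[i]
    if (gene == "VvMybA4" && family == "F") {
      if (!tandem_dup) {
        st <- push_seq(st, pad_u)
        st <- push_gene(st, "VvMybA4", "VvMybA4", NA_character_, a4_base)
        st <- push_seq(st, pad_d)
      } else {
        ## copy 1: VvMybA4a (213-bp insertion in exon 3)
        st <- push_seq(st, pad_u)
        tpl_a <- build_allele(a4_base, config$alleles$VvMybA4a$variants)
        st <- push_gene(st, "VvMybA4a", "VvMybA4", "VvMybA4a", tpl_a)
        st <- push_seq(st, pad_d)
        st$tandem_junction <- st$cursor
        ## copy 2: whole block at 90% identity, RLG TE in VvMybA4b exon 1
        tpl_b <- build_allele(a4_base, config$alleles$VvMybA4b$variants)
        te_at <- config$dup_pad_up +
          config$alleles$VvMybA4b$variants[[1L]]$position - 1L
        copy2 <- paste0(substr(copy2_mut, 1L, te_at),
                        config$tes$RLG_1$sequence,
                        substr(copy2_mut, te_at + 1L, nchar(copy2_mut)))
        gene_off <- st$cursor + config$dup_pad_up
        st <- push_seq(st, copy2)
        st <- register_gene(st, "VvMybA4b", "VvMybA4", "VvMybA4b", tpl_b,
                            gene_off)
      }
    } else {
      allele <- alleles[[gene]]
      tpl <- if (is.na(allele)) config$templates[[gene]] else
        build_allele(config$templates[[gene]],
                     config$alleles[[allele]]$variants)
      st <- push_gene(st, gene, gene, allele, tpl)
    }
    if (i <= n_spacer) {
      te_here <- if (family == "F") {
        Filter(function(x) x$after == gene, config$intergenic_tes)
      } else list()
      if (length(te_here)) {
        te <- config$tes[[te_here[[1L]]$te]]
        half <- spacer_len[i] %/% 2L
        st <- push_seq(st, substr(spacer_seq[i], 1L, half))
        st <- push_te(st, te)
        st <- push_seq(st, substr(spacer_seq[i], half + 1L, spacer_len[i]))
      } else {
        st <- push_seq(st, spacer_seq[i])
      }
    }
  }
  st <- push_seq(st, flank_right)
  finish_haplotype(st, name)
}

## --- incremental locus assembly state ---------------------------------

locus_state <- function() {
  list(pieces = list(), cursor = 0L, genes = list(), te_features = list(),
       ann = list(), tandem_junction = NULL)
}

push_seq <- function(st, seq) {
  st$pieces[[length(st$pieces) + 1L]] <- seq
  st$cursor <- st$cursor + nchar(seq)
  st
}

push_gene <- function(st, label, gene, allele, tpl) {
  off <- st$cursor
  st <- push_seq(st, tpl$sequence)
  register_gene(st, label, gene, allele, tpl, off)
}

# register annotations for a gene whose sequence sits at `offset`
register_gene <- function(st, label, gene, allele, tpl, offset) {
  len <- nchar(tpl$sequence)
  st$genes[[label]] <- list(label = label, gene = gene, allele = allele,
                            template = tpl, offset = offset, strand = "+")
  st$ann[[length(st$ann) + 1L]] <- data.frame(
    feature = "gene", name = label, start = offset + 1L,
    end = offset + len, strand = "+", parent = NA_character_)
  ex <- tpl$exons
  st$ann[[length(st$ann) + 1L]] <- data.frame(
    feature = "exon",
    name = paste0(label, "_exon", seq_len(nrow(ex))),
    start = offset + ex[, 1L], end = offset + ex[, 2L],
    strand = "+", parent = label)
  if (!is.null(tpl$te)) {
    st <- register_te(st, tpl$te, offset)
  }
  st
}

push_te <- function(st, te) {
  off <- st$cursor
  st <- push_seq(st, te$sequence)
  register_te(st, list(name = te$name, start = 1L,
                       end = nchar(te$sequence), ltr5 = te$ltr5,
                       ltr3 = te$ltr3, age = te$age), off)
}

register_te <- function(st, te, offset) {
  nm <- te$name
  if (nm %in% names(st$te_features)) nm <- paste0(nm, "_", offset)
  feat <- list(name = nm, start = offset + te$start, end = offset + te$end,
               ltr5 = offset + te$ltr5, ltr3 = offset + te$ltr3,
               age = te$age)
  st$te_features[[nm]] <- feat
  st$ann[[length(st$ann) + 1L]] <- data.frame(
    feature = c("TE", "LTR5", "LTR3"),
    name = c(nm, paste0(nm, "_LTR5"), paste0(nm, "_LTR3")),
    start = c(feat$start, feat$ltr5[1L], feat$ltr3[1L]),
    end = c(feat$end, feat$ltr5[2L], feat$ltr3[2L]),
    strand = "+", parent = c(NA_character_, nm, nm))
  st
}

finish_haplotype <- function(st, name) {
  ann <- do.call(rbind, st$ann)
  ann <- ann[order(ann$start, ann$end), , drop = FALSE]
  rownames(ann) <- NULL
  structure(list(name = name,
                 sequence = paste(unlist(st$pieces), collapse = ""),
                 genes = st$genes,
                 te_features = st$te_features,
                 annotations = ann,
                 tandem_junction = st$tandem_junction),
            class = "haplotype_model")
}

## --- HapF^DEL: exact substring deletion of the HapF2 sequence -----------

build_hapf_del <- function(config) {
  f2 <- build_haplotype("HapF2", config)
  a3 <- f2$genes$VvMybA3
  a4b <- f2$genes$VvMybA4b
  del_start <- a3$offset + 1L - config$del_upstream
  del_end <- a4b$offset + nchar(a4b$template$sequence) +
    config$del_downstream
  del_len <- del_end - del_start + 1L
  stopifnot(del_start > 1L, del_end < nchar(f2$sequence))

  seq <- paste0(substr(f2$sequence, 1L, del_start - 1L),
                substr(f2$sequence, del_end + 1L, nchar(f2$sequence)))
  ann <- f2$annotations
  inside <- ann$start >= del_start & ann$end <= del_end
  straddle <- !inside & ann$start <= del_end & ann$end >= del_start
  stopifnot(!any(straddle))   # breakpoints fall in intergenic sequence
  ann <- ann[!inside, , drop = FALSE]
  after <- ann$start > del_end
  ann$start[after] <- ann$start[after] - del_len
  ann$end[ann$end > del_end] <- ann$end[ann$end > del_end] - del_len
  rownames(ann) <- NULL

  shift_feat <- function(x) {
    if (x$start >= del_start && x$end <= del_end) return(NULL)
    if (x$start > del_end) {
      x$start <- x$start - del_len; x$end <- x$end - del_len
      x$ltr5 <- x$ltr5 - del_len; x$ltr3 <- x$ltr3 - del_len
    }
    x
  }
  tes <- Filter(Negate(is.null), lapply(f2$te_features, shift_feat))
  genes <- Filter(Negate(is.null), lapply(f2$genes, function(g) {
    ge <- g$offset + nchar(g$template$sequence)
    if (g$offset + 1L >= del_start && ge <= del_end) return(NULL)
    if (g$offset >= del_end) g$offset <- g$offset - del_len
    g
  }))

  structure(list(name = "HapF_DEL", sequence = seq, genes = genes,
                 te_features = tes, annotations = ann,
                 tandem_junction = NULL, parent = "HapF2",
                 deletion = c(start = del_start, end = del_end),
                 del_junction = del_start - 1L),
            class = "haplotype_model")
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat(sprintf("<haplotype_model> %s: %d bp, %d genes, %d TEs\n",
              x$name, nchar(x$sequence), length(x$genes),
              length(x$te_features)))
  cat("  genes:", paste(names(x$genes), collapse = ", "), "\n")
  invisible(x)
}

#' Gene spans of a haplotype model
#'
#' @param hap A [build_haplotype()] model.
#' @return data.frame with `name`, `start`, `end` (1-based closed) of the
#'   gene features only, in locus order.
#' @export
gene_spans <- function(hap) {
  ann <- hap$annotations
  out <- ann[ann$feature == "gene", c("name", "start", "end")]
  rownames(out) <- NULL
  out
}

#' Write a haplotype model to FASTA + GFF3
#'
#' @param hap A `haplotype_model`.
#' @param fasta,gff3 Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_haplotype <- function(hap, fasta, gff3) {
  dss <- Biostrings::DNAStringSet(hap$sequence)
  names(dss) <- hap$name
  Biostrings::writeXStringSet(dss, fasta)
  ann <- hap$annotations
  gr <- GenomicRanges::GRanges(
    seqnames = hap$name,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand)
  gr$type <- ann$feature
  gr$ID <- paste0(ann$feature, ":", ann$name)
  gr$Name <- ann$name
  gr$Parent <- ifelse(is.na(ann$parent), NA_character_,
                      paste0("gene_or_te:", ann$parent))
  rtracklayer::export(gr, gff3, format = "gff3")
  invisible(list(fasta = fasta, gff3 = gff3))
}

#' Read a haplotype model back from FASTA + GFF3
#'
#' Reconstructs the sequence and annotation table (gene templates and edit
#' logs are not serialized; the returned model carries `genes` spans only).
#'
#' @param fasta,gff3 Paths written by [write_haplotype()].
#' @return A `haplotype_model` with `name`, `sequence`, `annotations`.
#' @export
read_haplotype <- function(fasta, gff3) {
  dss <- Biostrings::readDNAStringSet(fasta)
  gr <- rtracklayer::import(gff3)
  ann <- data.frame(
    feature = as.character(gr$type),
    name = gr$Name,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    parent = vapply(as.list(gr$Parent), function(p) {
      if (length(p)) sub("^gene_or_te:", "", p[1L]) else NA_character_
    }, character(1L)))
  ann <- ann[order(ann$start, ann$end), , drop = FALSE]
  rownames(ann) <- NULL
  structure(list(name = names(dss)[1L],
                 sequence = as.character(dss[[1L]]),
                 genes = NULL, te_features = NULL, annotations = ann),
            class = "haplotype_model")
}

#' Spliced cDNA of a configured allele
#'
#' @param config A [default_locus_config()].
#' @param allele Allele name from `config$alleles` (e.g. `"VvMybA1_SUB"`).
#' @return Character scalar: the allele's spliced coding sequence.
#' @export
allele_cdna <- function(config, allele) {
  a <- config$alleles[[allele]]
  if (is.null(a)) stop("unknown allele: ", allele)
  spliced_cds(build_allele(config$templates[[a$gene]], a$variants))
}
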