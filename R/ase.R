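#' Find allele-private SNPs in a multiple alignment of allele cDNAs
#'
#' A private SNP is an alignment column at which exactly one sequence holds
#' a distinct base while all the others share a single state, with no gap in
#' the column -- the columns that let RNA reads be assigned to a single
#' allele. At least three sequences are required (with two, neither state
#' can be called the background).
#'
#' @param alignment Named character vector of aligned sequences (equal
#'   length, gaps as `-`).
#' @param genes Optional named character vector mapping each allele name to
#'   its gene; carried into the output.
#' @return An object of class `private_snp_table`: data.frame with `gene`,
#'   `allele`, `column`, `allele_state`, `background_state`.
#' @export
find_private_snps <- function(alignment, genes = NULL) {
  stopifnot(length(alignment) >= 3L, !is.null(names(alignment)))
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequences have unequal aligned lengths")
  }
  m <- matrix(unlist(strsplit(toupper(alignment), "", fixed = TRUE),
                     use.names = FALSE),
              nrow = length(alignment), byrow = TRUE,
              dimnames = list(names(alignment), NULL))
  rows <- list()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(col == "-")) next
    tab <- table(col)
    if (length(tab) != 2L || min(tab) != 1L) next
    minor <- names(tab)[which.min(tab)]
    allele <- rownames(m)[col == minor]
    rows[[length(rows) + 1L]] <- data.frame(
      gene = if (is.null(genes)) NA_character_ else
        unname(genes[allele]),
      allele = allele, column = j, allele_state = minor,
      background_state = names(tab)[which.max(tab)],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), allele = character(),
               column = integer(), allele_state = character(),
               background_state = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("private_snp_table", class(out))
  out
}

#' Per-SNP allele frequencies from a pileup
#'
#' @param pileup 4 x n-columns base-count matrix in alignment-column space
#'   (rows `A`,`C`,`G`,`T`), e.g. from [pileup_counts()] reprojected with
#'   the gap structure, or assembled by [run_ase()].
#' @param table A [find_private_snps()] table (typically one allele's rows).
#' @param min_depth Minimum read depth for a column to be used; shallower
#'   columns are skipped and reported in `attr(, "skipped")`.
#' @return data.frame with `allele`, `column`, `frequency`, `depth`; warns
#'   (and returns zero rows) when no SNP reaches `min_depth`.
#' @export
allele_frequencies_at_snps <- function(pileup, table, min_depth = 10L) {
  stopifnot(min_depth >= 1L, nrow(pileup) == 4L)
  depth <- colSums(pileup)[table$column]
  cnt <- pileup[cbind(match(table$allele_state, rownames(pileup)),
                      table$column)]
  keep <- depth >= min_depth
  out <- data.frame(allele = table$allele[keep],
                    column = table$column[keep],
                    frequency = cnt[keep] / depth[keep],
                    depth = as.integer(depth[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- table$column[!keep]
  if (!nrow(out)) warning("no private SNP reaches min_depth = ", min_depth)
  out
}

#' Average per-SNP frequencies into one allele proportion
#'
#' The unweighted arithmetic mean of the per-SNP allele frequencies (the
#' averaging used when combining private-SNP evidence); per-gene proportions
#' are renormalized to sum to one downstream. A depth-weighted mean is
#' available as an extension.
#'
#' @param frequencies Numeric vector of per-SNP frequencies (non-empty).
#' @param weights Optional depths for a weighted mean (off by default).
#' @return Proportion in \[0, 1\].
#' @export
estimate_allele_proportion <- function(frequencies, weights = NULL) {
  if (!length(frequencies)) stop("empty frequency list")
  if (is.null(weights)) mean(frequencies)
  else stats::weighted.mean(frequencies, weights)
}

#' Transcripts per million
#'
#' `tpm_i = (c_i / l_i) / sum_j(c_j / l_j) * 1e6`.
#'
#' @param counts Per-transcript read counts.
#' @param lengths Effective transcript lengths in bp (> 0).
#' @return Numeric TPM vector summing to 1e6 (all-zero counts give all-zero
#'   TPM with a warning).
#' @export
compute_tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), all(lengths > 0),
            all(counts >= 0))
  rate <- counts / lengths
  if (sum(rate) == 0) {
    warning("all counts are zero; returning all-zero TPM")
    return(rate)
  }
  rate / sum(rate) * 1e6
}

#' Split a gene's TPM across its alleles
#'
#' @param gene_tpm Gene-level TPM (>= 0).
#' @param proportions Named allele proportions summing to 1.
#' @param floor Detection floor: alleles below it are reported as not
#'   detected (the "n. d." convention), default 0.01.
#' @return data.frame with `allele`, `proportion`, `tpm`, `detected`.
#' @export
partition_tpm <- function(gene_tpm, proportions, floor = 0.01) {
  stopifnot(gene_tpm >= 0, all(proportions >= 0),
            abs(sum(proportions) - 1) < 1e-6)
  data.frame(allele = names(proportions),
             proportion = unname(proportions),
             tpm = unname(gene_tpm * proportions),
             detected = unname(proportions >= floor),
             stringsAsFactors = FALSE)
}

#' Full allele-specific-expression pipeline
#'
#' Given the aligned allele cDNAs and an RNA read set: competitively
#' assigns each read to its best-matching allele cDNA (the per-gene
#' quantify-then-split scheme: allele placements of one gene are pooled
#' into the gene's pileup and count), computes gene-level TPM over the
#' quantified genes, identifies private SNPs, measures each allele's
#' frequency at its private SNPs in the gene's pooled pileup (projected
#' into alignment-column space through each allele's gap structure),
#' averages and renormalizes per gene, and splits the gene TPM into
#' per-allele TPM.
#'
#' @param alignment Named character vector: aligned allele cDNAs.
#' @param genes Named character vector: allele name -> gene name.
#' @param reads A `read_set` (e.g. from [simulate_rna_reads()]).
#' @param min_depth Minimum depth per SNP column.
#' @param floor Detection floor for [partition_tpm()].
#' @return data.frame with `gene`, `allele`, `n_snps`, `proportion`, `tpm`,
#'   `detected`; attribute `gene_tpm` holds the gene-level table.
#' @export
run_ase <- function(alignment, genes, reads, min_depth = 10L,
                    floor = 0.01) {
  stopifnot(setequal(names(alignment), names(genes)))
  snps <- find_private_snps(alignment, genes = genes)
  gene_names <- unique(unname(genes))
  n_col <- nchar(alignment[[1L]])

  ## ungapped per-allele references + allele coordinate -> alignment column
  refs <- vapply(alignment, function(s) gsub("-", "", s, fixed = TRUE),
                 character(1L))
  colmap <- lapply(alignment, function(s) {
    which(strsplit(s, "", fixed = TRUE)[[1L]] != "-")
  })

  aln_reads <- map_reads(reads, refs, mode = "best",
                         max_mismatch = max(2L, round(0.04 *
                                                        nchar(reads$seq[1L]))))
  allele_counts <- table(factor(aln_reads$rname, levels = names(genes)))
  gene_counts <- tapply(as.numeric(allele_counts), unname(genes)[
    match(names(allele_counts), names(genes))], sum)[gene_names]
  gene_len <- tapply(nchar(refs), unname(genes), mean)[gene_names]
  gene_tpm <- compute_tpm(as.numeric(gene_counts), as.numeric(gene_len))
  names(gene_tpm) <- gene_names

  out <- list()
  for (g in gene_names) {
    alleles <- names(genes)[genes == g]
    ## pooled pileup of the gene's reads in alignment-column space
    pile <- matrix(0L, nrow = 4L, ncol = n_col,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
    for (a in alleles) {
      pit <- pileup_counts(aln_reads[aln_reads$rname == a, , drop = FALSE],
                           nchar(refs[[a]]))
      pile[, colmap[[a]]] <- pile[, colmap[[a]]] + pit
    }
    props <- numeric(0)
    nsnp <- integer(0)
    for (a in alleles) {
      tab_a <- snps[snps$allele == a, , drop = FALSE]
      fr <- if (nrow(tab_a)) {
        suppressWarnings(allele_frequencies_at_snps(pile, tab_a,
                                                    min_depth = min_depth))
      } else data.frame(frequency = numeric(0))
      props[a] <- if (nrow(fr)) estimate_allele_proportion(fr$frequency)
        else 0
      nsnp[a] <- nrow(fr)
    }
    ## correct for coverage-per-transcript differing between alleles of
    ## unequal length (column depth scales with L/(L - read_len + 1)), then
    ## renormalize within the gene
    width <- if (nrow(aln_reads)) aln_reads$width[1L] else
      nchar(reads$seq[1L])
    k <- vapply(alleles, function(a) {
      L <- nchar(refs[[a]])
      max(L - width + 1L, 1L) / L
    }, numeric(1L))
    props <- props * k
    if (sum(props) > 0) props <- props / sum(props)
    else props[] <- 1 / length(props)
    part <- partition_tpm(gene_tpm[[g]], props, floor = floor)
    part$gene <- g
    part$n_snps <- unname(nsnp)
    out[[g]] <- part[, c("gene", "allele", "n_snps", "proportion", "tpm",
                         "detected")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "gene_tpm") <- gene_tpm
  attr(res, "snps") <- snps
  res
}

#' Export a private-SNP table as VCF
#'
#' Minimal VCFv4.2 records on the alignment-column coordinate system; the
#' background state is written as REF and the allele-private state as ALT,
#' with the owning allele in the INFO field.
#'
#' @param table A [find_private_snps()] table.
#' @param path Output path.
#' @param contig Name to use as the VCF CHROM.
#' @return `path`, invisibly.
#' @export
write_private_snps_vcf <- function(table, path, contig = "cdna_alignment") {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", contig),
              paste0("##INFO=<ID=ALLELE,Number=1,Type=String,",
                     "Description=\"Allele carrying the private state\">"),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tALLELE=%s", contig,
                 table$column, paste0("psnp_", seq_len(nrow(table))),
                 table$background_state, table$allele_state, table$allele)
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Aligned allele cDNAs of the synthetic locus
#'
#' Returns the six-allele cDNA alignment used for allele-specific
#' expression (VvMybA1/2/3, one F and one A allele each), built exactly from
#' the known indel structure: the 282-bp VvMybA2 duplication block is gapped
#' in non-A2 rows, the 209-bp VvMybA3 deletion and the CA dinucleotide
#' deletion of VvMybA2w appear as gaps in their rows.
#'
#' @param config A [default_locus_config()].
#' @return List with `alignment` (named character vector, equal widths),
#'   `cdnas` (ungapped), and `genes` (allele -> gene map).
#' @export
ase_reference_set <- function(config) {
  sel <- c(VvMybA1_HapF = "VvMybA1_SUB", VvMybA1_HapA = "VvMybA1a",
           VvMybA2_HapF = "VvMybA2_HapF", VvMybA2_HapA = "VvMybA2w",
           VvMybA3_HapF = "VvMybA3_HapF", VvMybA3_HapA = "VvMybA3del")
  cdnas <- vapply(sel, function(a) allele_cdna(config, a), character(1L))
  gap <- function(n) strrep("-", n)
  row_of <- function(nm) {
    cd <- cdnas[[nm]]
    if (startsWith(nm, "VvMybA2")) {
      if (nm == "VvMybA2_HapA") {   # CA deletion at CDS 400
        paste0(substr(cd, 1L, 399L), gap(2L), substr(cd, 400L, nchar(cd)))
      } else cd
    } else if (nm == "VvMybA3_HapA") {  # 209-bp deletion at CDS 400..608
      paste0(substr(cd, 1L, 399L), gap(209L), substr(cd, 400L, 541L),
             gap(282L), substr(cd, 542L, 544L))
    } else {
      paste0(substr(cd, 1L, 750L), gap(282L), substr(cd, 751L, 753L))
    }
  }
  alignment <- vapply(names(sel), row_of, character(1L))
  genes <- stats::setNames(sub("_Hap[AF]$", "", names(sel)), names(sel))
  list(alignment = alignment, cdnas = cdnas, genes = genes)
}
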