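#' Discover MybA gene models on a contig with an R2R3 probe
#'
#' Scans both strands with windowed local alignment of the conserved R2R3
#' probe (exon 1 + intron 1 + exon 2 of VvMybA1, the most conserved part of
#' the family), keeps hits above identity and probe-coverage thresholds,
#' and merges overlapping window hits. The default identity threshold (0.6)
#' is low enough to recover the divergent VvMybA13 (60-78% identity to the
#' rest of the cluster).
#'
#' @param contig DNA character scalar.
#' @param probe R2R3 probe sequence (>= 100 bp); see [r2r3_probe()].
#' @param min_identity Minimum alignment identity in \[0,1\].
#' @param min_coverage Minimum fraction of the probe aligned.
#' @return data.frame (`start`, `end`, `strand`, `identity`, `coverage`),
#'   sorted by position; zero rows for an empty or non-homologous contig.
#' @export
find_myba_genes <- function(contig, probe, min_identity = 0.6,
                            min_coverage = 0.6) {
  stopifnot(nchar(probe) >= 100L)
  if (!nchar(contig)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), identity = numeric(),
                      coverage = numeric()))
  }
  hits_fwd <- scan_probe_one_strand(contig, probe, min_identity,
                                    min_coverage)
  hits_rev <- scan_probe_one_strand(revcomp(contig), probe, min_identity,
                                    min_coverage)
  if (nrow(hits_rev)) {
    L <- nchar(contig)
    tmp <- L - hits_rev$end + 1L
    hits_rev$end <- L - hits_rev$start + 1L
    hits_rev$start <- tmp
    hits_rev$strand <- "-"
  }
  out <- rbind(hits_fwd, hits_rev)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

scan_probe_one_strand <- function(contig, probe, min_identity,
                                  min_coverage) {
  plen <- nchar(probe)
  L <- nchar(contig)
  step <- plen
  win <- 3L * plen
  starts <- seq.int(1L, max(1L, L - plen + 1L), by = step)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = TRUE)
  p_dna <- Biostrings::DNAString(probe)
  raw <- list()
  for (ws in starts) {
    we <- min(L, ws + win - 1L)
    pa <- Biostrings::pairwiseAlignment(
      p_dna, Biostrings::DNAString(substr(contig, ws, we)),
      type = "local", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 4)
    alen <- Biostrings::nchar(pa)          # alignment length incl. gaps
    if (!alen) next
    identity <- Biostrings::nmatch(pa) / alen
    coverage <- IRanges::width(pa@pattern@range) / plen
    if (identity >= min_identity && coverage >= min_coverage) {
      sp <- pa@subject@range
      raw[[length(raw) + 1L]] <- data.frame(
        start = ws + IRanges::start(sp) - 1L,
        end = ws + IRanges::end(sp) - 1L,
        strand = "+", identity = identity, coverage = coverage)
    }
  }
  if (!length(raw)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), identity = numeric(),
                      coverage = numeric()))
  }
  hits <- do.call(rbind, raw)
  ## merge hits of the same gene found in overlapping windows
  ir <- IRanges::IRanges(hits$start, hits$end)
  red <- IRanges::reduce(ir, min.gapwidth = 50L)
  ov <- IRanges::findOverlaps(ir, red)
  grp <- S4Vectors::subjectHits(ov)
  data.frame(start = IRanges::start(red),
             end = IRanges::end(red),
             strand = "+",
             identity = as.numeric(tapply(hits$identity, grp, max)),
             coverage = as.numeric(tapply(hits$coverage, grp, max)))
}

#' The conserved R2R3 probe of the synthetic locus
#'
#' @param config A [default_locus_config()].
#' @return Character scalar: exon 1 + intron 1 + exon 2 of the VvMybA1
#'   template.
#' @export
r2r3_probe <- function(config) {
  p <- gene_part_starts()
  substr(config$templates$VvMybA1$sequence, p$e1, p$i2 - 1L)
}

#' Exact-word dotplot of two sequences
#'
#' All shared words of length `word_size`, both strands, as match
#' coordinates -- the text form of the dotplots used to compare haplotype
#' structures.
#'
#' @param seqA,seqB DNA character scalars.
#' @param word_size Word length (>= 8).
#' @return data.frame with `posA`, `posB` (1-based word start positions)
#'   and `strand` (`+` shared word, `-` word shared with the reverse
#'   complement of `seqB`).
#' @export
dotplot <- function(seqA, seqB, word_size = 12L) {
  stopifnot(word_size >= 8L)
  w <- as.integer(word_size)
  words_of <- function(s) {
    n <- nchar(s)
    if (n < w) return(character(0))
    substring(s, 1:(n - w + 1L), w:n)
  }
  wa <- words_of(seqA)
  idx <- split(seq_along(wa), wa)
  match_one <- function(sB, strand) {
    wb <- words_of(sB)
    grp <- idx[wb]
    lens <- lengths(grp)
    if (!sum(lens)) return(NULL)
    posB <- rep.int(seq_along(wb), lens)
    posA <- unlist(grp, use.names = FALSE)
    if (strand == "-") posB <- nchar(sB) - posB - w + 2L
    data.frame(posA = posA, posB = posB, strand = strand)
  }
  out <- rbind(match_one(seqB, "+"), match_one(revcomp(seqB), "-"))
  if (is.null(out)) {
    return(data.frame(posA = integer(), posB = integer(),
                      strand = character()))
  }
  out <- out[order(out$posA, out$posB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Structural differences between two haplotype models
#'
#' Reports the maximal intervals present in one haplotype and absent in the
#' other, with the gene models each interval contains and its offsets to
#' the first/last contained gene (the "x kb upstream of gene / y kb
#' downstream of gene" description of a deletion), plus gene-order changes
#' among shared genes. Interval bounds are anchored on the sequences (an
#' exact substring deletion is recovered by common prefix/suffix); with
#' more than one event, bounds fall back to the annotation anchors.
#'
#' @param hapA,hapB `haplotype_model` objects sharing a gene label space.
#' @return An object of class `structural_diff`: list with `deletions`
#'   (in `hapA` absent from `hapB`), `insertions` (the mirror), and
#'   `order_changes`.
#' @export
detect_structural_diff <- function(hapA, hapB) {
  del <- missing_intervals(hapA, hapB)
  ins <- missing_intervals(hapB, hapA)
  shared <- intersect(names(hapA$genes), names(hapB$genes))
  oa <- shared[order(vapply(hapA$genes[shared], `[[`, 0L, "offset"))]
  ob <- shared[order(vapply(hapB$genes[shared], `[[`, 0L, "offset"))]
  order_changes <- if (identical(oa, ob)) character(0) else
    setdiff(oa, lcs_labels(oa, ob))
  structure(list(deletions = del, insertions = ins,
                 order_changes = order_changes,
                 hapA = hapA$name, hapB = hapB$name),
            class = "structural_diff")
}

# longest common subsequence of two label vectors (small n)
lcs_labels <- function(a, b) {
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1L, j + 1L] <- if (a[i] == b[j]) d[i, j] + 1L else
      max(d[i, j + 1L], d[i + 1L, j])
  }
  out <- character(0)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (a[i] == b[j]) { out <- c(a[i], out); i <- i - 1L; j <- j - 1L }
    else if (d[i, j + 1L] >= d[i + 1L, j]) i <- i - 1L
    else j <- j - 1L
  }
  out
}

# intervals of `ref` whose genes are absent from `other`
missing_intervals <- function(ref, other) {
  gs <- gene_spans(ref)
  miss <- !(gs$name %in% names(other$genes))
  if (!any(miss)) return(list())
  runs <- rle(miss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  events <- which(runs$values)
  one_event <- length(events) == 1L
  lenR <- nchar(ref$sequence); lenO <- nchar(other$sequence)
  lapply(events, function(k) {
    rows <- gs[starts[k]:ends[k], , drop = FALSE]
    iv <- NULL
    if (one_event && !is.null(ref$sequence) && !is.null(other$sequence) &&
        lenR > lenO) {
      iv <- anchor_deletion(ref$sequence, other$sequence)
    }
    if (is.null(iv)) {
      up_gene <- gs$name[gs$end < rows$start[1L]]
      dn_gene <- gs$name[gs$start > rows$end[nrow(rows)]]
      iv <- c(if (length(up_gene))
                gs$end[gs$name == up_gene[length(up_gene)]] + 1L else 1L,
              if (length(dn_gene))
                gs$start[gs$name == dn_gene[1L]] - 1L else lenR)
    }
    list(start = iv[1L], end = iv[2L], length = iv[2L] - iv[1L] + 1L,
         genes_contained = rows$name[rows$start >= iv[1L] &
                                       rows$end <= iv[2L]],
         upstream_offset = rows$start[1L] - iv[1L],
         downstream_offset = iv[2L] - rows$end[nrow(rows)],
         first_gene = rows$name[1L], last_gene = rows$name[nrow(rows)])
  })
}

# locate a single exact substring deletion by common prefix/suffix
anchor_deletion <- function(long, short) {
  nl <- nchar(long); ns <- nchar(short)
  a <- Biostrings::lcprefix(Biostrings::DNAString(long),
                            Biostrings::DNAString(short))
  b <- Biostrings::lcsuffix(Biostrings::DNAString(long),
                            Biostrings::DNAString(short))
  if (a + b < ns) return(NULL)     # not a clean single deletion
  p <- min(a, ns - b)              # keep the suffix anchor intact
  c(p + 1L, p + nl - ns)
}

#' @export
print.structural_diff <- function(x, ...) {
  cat(sprintf("<structural_diff> %s vs %s\n", x$hapA, x$hapB))
  for (d in x$deletions) {
    cat(sprintf(paste0("  deletion %d..%d (%.1f kb): %d genes [%s]; ",
                       "%d bp upstream of %s, %d bp downstream of %s\n"),
                d$start, d$end, d$length / 1e3, length(d$genes_contained),
                paste(d$genes_contained, collapse = ","),
                d$upstream_offset, d$first_gene, d$downstream_offset,
                d$last_gene))
  }
  for (d in x$insertions) {
    cat(sprintf("  insertion (in %s) %d..%d: genes [%s]\n", x$hapB,
                d$start, d$end, paste(d$genes_contained, collapse = ",")))
  }
  if (length(x$order_changes)) {
    cat("  order changes:", paste(x$order_changes, collapse = ","), "\n")
  }
  invisible(x)
}

#' Translate a gene model's spliced CDS
#'
#' @param template A [gene_template()] (variants already applied).
#' @return List with `protein` (up to the first stop), `length` (aa),
#'   `premature_stop` (stop before the final codon, or a frameshifted CDS),
#'   `frameshift` (spliced length not divisible by 3).
#' @export
translate_gene <- function(template) {
  cds <- spliced_cds(template)
  if (substr(cds, 1L, 3L) != "ATG") stop("CDS does not start with ATG")
  if (grepl("N", cds, fixed = TRUE)) stop("CDS contains N")
  frameshift <- nchar(cds) %% 3L != 0L
  usable <- 3L * (nchar(cds) %/% 3L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, usable)),
    if.fuzzy.codon = "X"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  n_codon <- nchar(aa)
  if (stop_at > 0L) {
    protein <- substr(aa, 1L, stop_at - 1L)
    premature <- stop_at < n_codon || frameshift
  } else {
    protein <- aa
    premature <- frameshift
  }
  list(protein = protein, length = nchar(protein),
       premature_stop = premature, frameshift = frameshift)
}

#' Date an LTR retrotransposon insertion from its LTR divergence
#'
#' The two LTRs are identical at insertion and diverge at twice the
#' molecular-clock rate afterwards; they are globally aligned, the raw
#' mismatch fraction `p` is corrected for multiple hits (Jukes-Cantor
#' `K = -3/4 ln(1 - 4p/3)` by default, Kimura two-parameter behind the
#' `model` flag), and the age is `K / (2 mu)`.
#'
#' @param te TE feature: list with `sequence` plus `ltr5`/`ltr3` spans (a
#'   [make_te()] element, or an entry of a haplotype's `te_features` paired
#'   with the haplotype sequence via `sequence`).
#' @param mu Substitution rate per site per year.
#' @param model `"JC69"` (default) or `"K80"`.
#' @param sequence Optional: the sequence the LTR spans refer to, when `te`
#'   itself carries none.
#' @return An object of class `te_age_estimate`: `te_name`, `p_raw`, `K`,
#'   `mu`, `age_years`, `model`.
#' @export
ltr_age <- function(te, mu = 1.3e-8, model = c("JC69", "K80"),
                    sequence = NULL) {
  model <- match.arg(model)
  stopifnot(mu > 0)
  src <- if (!is.null(sequence)) sequence else te$sequence
  l5 <- substr(src, te$ltr5[1L], te$ltr5[2L])
  l3 <- substr(src, te$ltr3[1L], te$ltr3[2L])
  stopifnot(nchar(l5) >= 100L, nchar(l3) >= 100L)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(l5),
                                      Biostrings::DNAString(l3),
                                      type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  keep <- ap != "-" & as_ != "-"
  p_raw <- mean(ap[keep] != as_[keep])
  if (1 - p_raw < 0.60) stop("unreliable LTR pair: identity below 60%")
  K <- if (model == "JC69") {
    -0.75 * log(1 - 4 * p_raw / 3)
  } else {
    dn <- ape::dist.dna(ape::as.DNAbin(rbind(ltr5 = tolower(ap),
                                             ltr3 = tolower(as_))),
                        model = "K80", pairwise.deletion = TRUE)
    as.numeric(dn)
  }
  structure(list(te_name = te$name, p_raw = p_raw, K = K, mu = mu,
                 age_years = K / (2 * mu), model = model),
            class = "te_age_estimate")
}

#' @export
print.te_age_estimate <- function(x, ...) {
  cat(sprintf("<te_age_estimate> %s: p = %.4f, K(%s) = %.4f, age = %.2f Myr\n",
              x$te_name, x$p_raw, x$model, x$K, x$age_years / 1e6))
  invisible(x)
}

#' Pairwise nucleotide identity after global alignment
#'
#' Matches over aligned columns, terminal gap columns excluded (internal
#' gaps count as mismatch columns).
#'
#' @param seqA,seqB DNA character scalars.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(seqA, seqB) {
  stopifnot(nchar(seqA) > 0L, nchar(seqB) > 0L)
  if (identical(seqA, seqB)) return(1)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(seqA),
                                      Biostrings::DNAString(seqB),
                                      type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  inner <- which(ap != "-" & as_ != "-")
  cols <- seq.int(min(inner), max(inner))
  mean(ap[cols] == as_[cols])
}

#' Indel events between two allele sequences
#'
#' Globally aligns two alleles of a gene and reports each insertion /
#' deletion event with its length -- e.g. VvMybA1_SUB vs VvMybA1c yields
#' the three insertions of 44, 111 and 33 bp.
#'
#' @param seqA,seqB DNA character scalars (A is compared *to* B: an
#'   insertion is sequence present in A, absent in B).
#' @return data.frame with `kind` (`insertion`/`deletion`), `start`
#'   (position on `seqA`), `width`.
#' @export
compare_alleles <- function(seqA, seqB) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seqA), Biostrings::DNAString(seqB),
    type = "global", gapOpening = 12, gapExtension = 0.5)
  ins <- Biostrings::indel(pa)@insertion[[1L]]   # gaps in subject = in A
  del <- Biostrings::indel(pa)@deletion[[1L]]    # gaps in pattern = in B
  out <- rbind(
    if (length(ins)) data.frame(kind = "insertion",
                                start = IRanges::start(ins),
                                width = IRanges::width(ins)),
    if (length(del)) data.frame(kind = "deletion",
                                start = IRanges::start(del),
                                width = IRanges::width(del)))
  if (is.null(out)) {
    return(data.frame(kind = character(), start = integer(),
                      width = integer()))
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
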