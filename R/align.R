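#' Map substitution-only short reads to small reference sequences
#'
#' Exact-seed, full-length verification mapper for the package's simulated
#' reads: a read maps to a reference if a 24-bp seed (tried at two offsets,
#' both strands) matches exactly and the full read then aligns ungapped with
#' at most `max_mismatch` mismatches. This is deliberately strict -- a read
#' crossing a structural breakpoint that the reference does not carry fails
#' verification, which is exactly the behaviour the diagnostic markers rely
#' on. Real alignments (any mapper) enter the package as SAM via
#' [read_sam()]; this function exists to close the loop on simulated data.
#'
#' @param reads A `read_set` data.frame (or character vector of equal-length
#'   read sequences).
#' @param refs Named character vector of reference sequences.
#' @param max_mismatch Maximum mismatches over the full read (default 6% of
#'   the read length, which admits ~1%-error reads and rejects
#'   breakpoint-crossing or paralog-crossing placements).
#' @param mode `"all"` keeps every verified placement (marker scanning);
#'   `"best"` keeps one placement with the fewest mismatches per read
#'   (competitive assignment, used for allele-expression pileups).
#' @param seed_len Seed length in bp.
#' @param seed_offsets Read offsets at which seeds are tried.
#' @return data.frame with columns `qname`, `rname`, `pos` (1-based start on
#'   the reference), `strand`, `seq` (reference-oriented read sequence),
#'   `nm` (mismatch count), `width`.
#' @export
map_reads <- function(reads, refs, max_mismatch = NULL,
                      mode = c("all", "best"), seed_len = 24L,
                      seed_offsets = c(1L, 74L)) {
  mode <- match.arg(mode)
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  ids <- if (is.data.frame(reads) && !is.null(reads$id)) reads$id else
    sprintf("read_%06d", seq_along(seqs))
  stopifnot(length(seqs) > 0, !is.null(names(refs)))
  width <- nchar(seqs[1L])
  stopifnot(all(nchar(seqs) == width))
  seed_offsets <- seed_offsets[seed_offsets + seed_len - 1L <= width]
  stopifnot(length(seed_offsets) >= 1L)
  if (is.null(max_mismatch)) max_mismatch <- max(2L, round(0.06 * width))

  oriented <- list(
    "+" = seqs,
    "-" = as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs))))

  ## index every seed_len-mer of the (small) references once, then join the
  ## read seeds against it -- O(ref bp + reads) instead of per-read scans
  ref_words <- lapply(names(refs), function(r) {
    L <- nchar(refs[[r]])
    if (L < seed_len) return(NULL)
    pos <- seq_len(L - seed_len + 1L)
    data.frame(word = substring(refs[[r]], pos, pos + seed_len - 1L),
               rname = r, wpos = pos, stringsAsFactors = FALSE)
  })
  ref_words <- do.call(rbind, ref_words)
  word_index <- split(seq_len(nrow(ref_words)), ref_words$word)

  hits <- list()
  for (strand in names(oriented)) {
    os <- oriented[[strand]]
    for (o in seed_offsets) {
      grp <- word_index[substring(os, o, o + seed_len - 1L)]
      lens <- lengths(grp)
      if (!sum(lens)) next
      ridx <- rep.int(seq_along(os), lens)
      widx <- unlist(grp, use.names = FALSE)
      starts <- ref_words$wpos[widx] - o + 1L
      rn <- ref_words$rname[widx]
      ok <- starts >= 1L & starts + width - 1L <= nchar(refs[rn])
      if (!any(ok)) next
      hits[[length(hits) + 1L]] <- data.frame(
        read = ridx[ok], rname = rn[ok], pos = starts[ok], strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty_alignments(names(refs)))
  cand <- unique(do.call(rbind, hits))
  cand$seq <- oriented[["+"]][cand$read]
  minus <- cand$strand == "-"
  cand$seq[minus] <- oriented[["-"]][cand$read[minus]]
  ref_sub <- substring(refs[cand$rname], cand$pos, cand$pos + width - 1L)
  cand$nm <- hamming(cand$seq, ref_sub)
  cand <- cand[cand$nm <= max_mismatch, , drop = FALSE]
  if (mode == "best" && nrow(cand)) {
    cand <- cand[order(cand$read, cand$nm, match(cand$rname, names(refs)),
                       cand$pos), , drop = FALSE]
    cand <- cand[!duplicated(cand$read), , drop = FALSE]
  }
  out <- data.frame(qname = ids[cand$read], rname = cand$rname,
                    pos = cand$pos, strand = cand$strand, seq = cand$seq,
                    nm = cand$nm, width = width, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "refs") <- names(refs)
  out
}

empty_alignments <- function(ref_names = character()) {
  out <- data.frame(qname = character(), rname = character(),
                    pos = integer(), strand = character(),
                    seq = character(), nm = integer(), width = integer(),
                    stringsAsFactors = FALSE)
  attr(out, "refs") <- ref_names
  out
}

#' Write an alignment table as SAM
#'
#' Emits minimal ungapped records (full-length match CIGAR) with proper
#' `@SQ` headers, readable by samtools and [read_sam()].
#'
#' @param aln Alignment data.frame from [map_reads()] or [read_sam()].
#' @param refs Named character vector of the reference sequences aligned to.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, refs, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)))
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                 aln$qname, flag, aln$rname, aln$pos, aln$width, aln$seq)
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Read a SAM file into the package's alignment table
#'
#' SAM is the only alignment dialect accepted; the file is converted with
#' Rsamtools and unmapped/secondary records are dropped. Gapped alignments
#' are kept with their reference span computed from the CIGAR.
#'
#' @param path SAM file path.
#' @return Alignment data.frame (`qname`, `rname`, `pos`, `strand`, `seq`,
#'   `width`), with the header's reference names in `attr(, "refs")`.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  refs <- names(Rsamtools::scanBamHeader(bam)[[1L]]$targets)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !bitwAnd(b$flag, 4L) & !bitwAnd(b$flag, 256L) & !is.na(b$pos)
  out <- data.frame(
    qname = b$qname[keep],
    rname = as.character(b$rname[keep]),
    pos = b$pos[keep],
    strand = as.character(b$strand[keep]),
    seq = as.character(b$seq[keep]),
    width = cigar_ref_width(b$cigar[keep]),
    stringsAsFactors = FALSE)
  attr(out, "refs") <- refs
  out
}

# reference-space width of a CIGAR string (M/=/X/D/N consume reference)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(NA_integer_)
    len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    op <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1L]]
    sum(len[op %in% c("M", "=", "X", "D", "N")])
  }, integer(1L), USE.NAMES = FALSE)
}

#' Per-position base counts from an alignment table
#'
#' @param aln Alignment data.frame restricted to one reference.
#' @param ref_len Reference length in bp.
#' @return 4 x `ref_len` integer matrix with rows `A`, `C`, `G`, `T`.
#' @export
pileup_counts <- function(aln, ref_len) {
  counts <- matrix(0L, nrow = 4L, ncol = ref_len,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  if (!nrow(aln)) return(counts)
  stopifnot(length(unique(aln$rname)) == 1L)
  bases <- unlist(strsplit(aln$seq, "", fixed = TRUE), use.names = FALSE)
  posn <- unlist(lapply(seq_len(nrow(aln)), function(i) {
    seq.int(aln$pos[i], length.out = nchar(aln$seq[i]))
  }), use.names = FALSE)
  keep <- posn >= 1L & posn <= ref_len & bases %in% rownames(counts)
  bi <- match(bases[keep], rownames(counts))
  idx <- (posn[keep] - 1L) * 4L + bi
  tab <- tabulate(idx, nbins = 4L * ref_len)
  matrix(tab, nrow = 4L, dimnames = list(rownames(counts), NULL))
}
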