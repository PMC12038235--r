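#' Define a diagnostic marker
#'
#' A marker ties a structural feature of the locus to a small reference
#' sequence on which read evidence is counted:
#' \describe{
#'   \item{junction}{a breakpoint (tandem-copy junction, TE/gene junction,
#'     deletion junction); a read supports it by aligning contiguously with
#'     at least `min_overhang` matched bases on each side.}
#'   \item{insertion_span}{an inserted block (the 33-bp intron-2 insertion
#'     of VvMybA1_SUB, the 213-bp insertion of VvMybA4a); a read supports it
#'     by spanning either insertion boundary with `min_overhang` on both
#'     sides.}
#'   \item{private_snp}{a diagnostic base (the intron-2 position-99 SNP);
#'     supporting reads carry `expected_state`, opposing reads any other
#'     base.}
#'   \item{absence_region}{an interval whose *lack* of coverage is the
#'     signal (the deleted VvMybA3..VvMybA4b interior); opposing reads
#'     overlap the interval, supporting reads cover the retained flank.}
#' }
#'
#' @param id Marker identifier.
#' @param kind One of `"junction"`, `"insertion_span"`, `"private_snp"`,
#'   `"absence_region"`.
#' @param reference Name of the marker reference sequence.
#' @param position Breakpoint / SNP position (junction, private_snp): the
#'   junction lies between `position` and `position + 1`.
#' @param interval Length-2 vector (insertion_span, absence_region).
#' @param expected_state Expected base (private_snp).
#' @param supports Subhaplotype label this marker is evidence for
#'   (`"HapF"`, `"HapF1"`, `"HapF2"`, `"HapF_DEL"`).
#' @return An object of class `diagnostic_marker`.
#' @export
diagnostic_marker <- function(id, kind, reference, position = NA_integer_,
                              interval = c(NA_integer_, NA_integer_),
                              expected_state = NA_character_,
                              supports = NA_character_) {
  kind <- match.arg(kind, c("junction", "insertion_span", "private_snp",
                            "absence_region"))
  if (kind %in% c("junction", "private_snp")) stopifnot(!is.na(position))
  if (kind %in% c("insertion_span", "absence_region")) {
    stopifnot(!anyNA(interval), interval[1L] <= interval[2L])
  }
  structure(list(id = id, kind = kind, reference = reference,
                 position = as.integer(position),
                 interval = as.integer(interval),
                 expected_state = expected_state, supports = supports),
            class = "diagnostic_marker")
}

#' Build the HapF diagnostic marker panel from a synthetic locus
#'
#' Extracts the marker reference windows and marker definitions that emulate
#' the visual WGS-alignment inspection used to type F subhaplotypes:
#' the 33-bp intron-2 insertion of VvMybA1_SUB (HapF presence), the intron-2
#' position-99 SNP, the tandem-copy junction, the 213-bp VvMybA4a insertion
#' and the RLG/VvMybA4b junction (HapF2), and absence windows over the two
#' deletion breakpoints plus the deletion junction itself (HapF^DEL). The
#' absence windows sit in F-family intergenic sequence, so HapA reads do not
#' align there and a covered interior can only come from an intact F
#' haplotype.
#'
#' @param config A [default_locus_config()].
#' @param halfwin Flank length around each feature, bp.
#' @return An object of class `marker_panel`: list with `refs` (named
#'   character vector) and `markers` (named list of [diagnostic_marker()]s).
#' @export
hapf_marker_panel <- function(config, halfwin = 450L) {
  f2 <- build_haplotype("HapF2", config)
  s <- f2$sequence
  W <- as.integer(halfwin)

  ## 33-bp insertion + position-99 SNP in VvMybA1_SUB intron 2
  a1 <- f2$genes$VvMybA1
  vs <- config$alleles$VvMybA1_SUB$variants
  ins33 <- payload_span(vs, "ins33_intron2")
  snp99 <- edited_position(drop_variant(vs, "snp_intron2_pos99"),
                           config$snp99$position_template)
  r1_start <- a1$offset + ins33[1L] - W
  r1 <- substr(s, r1_start, a1$offset + ins33[2L] + W)

  ## tandem-copy junction
  j <- f2$tandem_junction
  r2 <- substr(s, j - W + 1L, j + W)

  ## 213-bp insertion in VvMybA4a exon 3
  a4a <- f2$genes$VvMybA4a
  i213 <- payload_span(config$alleles$VvMybA4a$variants, "ins213_exon3")
  r3_start <- a4a$offset + i213[1L] - W
  r3 <- substr(s, r3_start, a4a$offset + i213[2L] + W)

  ## RLG / VvMybA4b exon-1 junction (5' side of the TE insertion)
  a4b <- f2$genes$VvMybA4b
  rlg_at <- config$alleles$VvMybA4b$variants[[1L]]$position   # insert before
  bp_rlg <- a4b$offset + rlg_at - 1L
  r4 <- substr(s, bp_rlg - W + 1L, bp_rlg + W)

  ## deletion breakpoints (HapF^DEL)
  ds <- f2$genes$VvMybA3$offset + 1L - config$del_upstream
  de <- a4b$offset + nchar(a4b$template$sequence) + config$del_downstream
  int_w <- 1150L
  r5 <- substr(s, ds - 650L, ds + int_w - 1L)
  r6 <- substr(s, de - int_w + 1L, de + 650L)
  r7 <- paste0(substr(s, ds - W, ds - 1L), substr(s, de + 1L, de + W))

  refs <- c(hapF_A1_intron2 = r1, tandem_junction = r2, A4a_ins213 = r3,
            rlg_A4b = r4, del_left = r5, del_right = r6, del_junction = r7)
  markers <- list(
    hapF_ins33 = diagnostic_marker(
      "hapF_ins33", "insertion_span", "hapF_A1_intron2",
      interval = c(W + 1L, W + 33L), supports = "HapF"),
    snp_intron2_99 = diagnostic_marker(
      "snp_intron2_99", "private_snp", "hapF_A1_intron2",
      position = a1$offset + snp99 - r1_start + 1L,
      expected_state = config$snp99$state, supports = "HapF"),
    tandem_junction = diagnostic_marker(
      "tandem_junction", "junction", "tandem_junction", position = W,
      supports = "HapF2"),
    ins213_A4a = diagnostic_marker(
      "ins213_A4a", "insertion_span", "A4a_ins213",
      interval = c(W + 1L, W + 213L), supports = "HapF2"),
    rlg_A4b_junction = diagnostic_marker(
      "rlg_A4b_junction", "junction", "rlg_A4b", position = W,
      supports = "HapF2"),
    absence_left = diagnostic_marker(
      "absence_left", "absence_region", "del_left",
      interval = c(651L, 650L + int_w), supports = "HapF_DEL"),
    absence_right = diagnostic_marker(
      "absence_right", "absence_region", "del_right",
      interval = c(1L, int_w), supports = "HapF_DEL"),
    del_junction = diagnostic_marker(
      "del_junction", "junction", "del_junction", position = W,
      supports = "HapF_DEL"))
  structure(list(refs = refs, markers = markers, seed = config$seed),
            class = "marker_panel")
}

drop_variant <- function(variants, label) {
  Filter(function(v) v$label != label, variants)
}

# final span of an insertion variant's payload after all of the allele's
# edits are applied
payload_span <- function(variants, label) {
  v <- Filter(function(x) x$label == label, variants)[[1L]]
  shift <- 0L
  for (w in variants) {
    if (w$position < v$position) {
      if (w$kind %in% c("insertion", "te_insertion")) {
        shift <- shift + variant_length(w)
      } else if (w$kind == "deletion") {
        shift <- shift - variant_length(w)
      }
    }
  }
  start <- v$position + shift
  c(start, start + variant_length(v) - 1L)
}

#' Count read evidence for one diagnostic marker
#'
#' @param alignments Alignment data.frame ([map_reads()] or [read_sam()]).
#' @param marker A [diagnostic_marker()].
#' @param min_overhang Minimum matched bases required on each side of a
#'   breakpoint (and minimum overlap for an opposing read of an absence
#'   marker), bp.
#' @return An object of class `read_evidence`: `marker_id`, `kind`,
#'   `supports`, `supporting`, `opposing`, `mean_overhang`.
#' @export
scan_marker <- function(alignments, marker, min_overhang = 20L) {
  stopifnot(inherits(marker, "diagnostic_marker"), min_overhang >= 1L)
  hdr <- attr(alignments, "refs")
  if (!is.null(hdr) && !(marker$reference %in% hdr)) {
    stop("marker reference '", marker$reference,
         "' absent from alignment header")
  }
  aln <- alignments[alignments$rname == marker$reference, , drop = FALSE]
  starts <- aln$pos
  ends <- aln$pos + aln$width - 1L
  ov <- as.integer(min_overhang)

  spans_bp <- function(bp) starts <= bp - ov + 1L & ends >= bp + ov
  supporting <- opposing <- 0L
  mean_overhang <- NA_real_
  if (marker$kind == "junction") {
    sup <- spans_bp(marker$position)
    supporting <- sum(sup)
    if (supporting) {
      mean_overhang <- mean(pmin(marker$position - starts[sup] + 1L,
                                 ends[sup] - marker$position))
    }
  } else if (marker$kind == "insertion_span") {
    sup <- spans_bp(marker$interval[1L] - 1L) | spans_bp(marker$interval[2L])
    supporting <- sum(sup)
    if (supporting) {
      bp1 <- marker$interval[1L] - 1L
      mean_overhang <- mean(pmin(bp1 - starts[sup] + 1L,
                                 ends[sup] - bp1))
    }
  } else if (marker$kind == "private_snp") {
    covers <- starts <= marker$position & ends >= marker$position
    base <- substr(aln$seq[covers],
                   marker$position - starts[covers] + 1L,
                   marker$position - starts[covers] + 1L)
    supporting <- sum(base == marker$expected_state)
    opposing <- sum(covers) - supporting
  } else {   # absence_region
    s <- marker$interval[1L]; e <- marker$interval[2L]
    overlap <- pmin(ends, e) - pmax(starts, s) + 1L
    opposing <- sum(overlap >= ov)
    supporting <- sum(ends < s | starts > e)
  }
  structure(list(marker_id = marker$id, kind = marker$kind,
                 supports = marker$supports,
                 supporting = as.integer(supporting),
                 opposing = as.integer(opposing),
                 mean_overhang = mean_overhang),
            class = "read_evidence")
}

#' Decide HapF presence from the 33-bp intron-2 insertion evidence
#'
#' @param evidence `read_evidence` for the `hapF_ins33` marker.
#' @param min_reads Minimum supporting junction-spanning reads (default 3).
#' @return Logical; attribute `low_evidence` is set when 0 < support <
#'   `min_reads`.
#' @export
detect_hapF <- function(evidence, min_reads = 3L) {
  stopifnot(inherits(evidence, "read_evidence"))
  out <- evidence$supporting >= min_reads
  attr(out, "low_evidence") <- evidence$supporting > 0L && !out
  out
}

#' Classify the F subhaplotype from a full evidence set
#'
#' Implements the decision rule used on WGS alignments: no F haplotype
#' unless the 33-bp intron-2 insertion is supported; HapF^DEL when the
#' absence windows over the VvMybA3..VvMybA4b interval are confirmed
#' (covered flanks, empty interior) and no tandem/213-bp/RLG junction
#' support exists; HapF2 when the tandem-copy junction is supported
#' (corroborated by the 213-bp span and RLG junction); otherwise HapF1,
#' which additionally requires the interval interior to be covered.
#' Conflicting evidence yields `ambiguous`, never a forced call.
#'
#' @param evidence_set List of `read_evidence` objects covering the marker
#'   ids of [hapf_marker_panel()].
#' @param min_reads Evidence threshold (reads) for each criterion.
#' @param accession Sample identifier carried into the call.
#' @return An object of class `haplotype_call`: `accession`, `call` (one of
#'   `HapF1`, `HapF2`, `HapF_DEL`, `no_HapF`, `ambiguous`), `evidence`,
#'   `thresholds`.
#' @export
classify_subhaplotype <- function(evidence_set, min_reads = 3L,
                                  accession = "sample") {
  ev <- stats::setNames(evidence_set,
                        vapply(evidence_set, `[[`, "", "marker_id"))
  required <- c("hapF_ins33", "tandem_junction", "ins213_A4a",
                "rlg_A4b_junction", "absence_left", "absence_right")
  missing <- setdiff(required, names(ev))
  if (length(missing)) {
    stop("incomplete evidence: missing marker(s) ",
         paste(missing, collapse = ", "))
  }
  sup <- function(id) ev[[id]]$supporting
  opp <- function(id) ev[[id]]$opposing

  absence_ok <- opp("absence_left") == 0L && opp("absence_right") == 0L &&
    sup("absence_left") >= min_reads && sup("absence_right") >= min_reads
  intact <- opp("absence_left") >= min_reads &&
    opp("absence_right") >= min_reads
  f2_signal <- sup("tandem_junction") >= min_reads ||
    sup("ins213_A4a") >= min_reads || sup("rlg_A4b_junction") >= min_reads

  call <- if (!detect_hapF(ev$hapF_ins33, min_reads)) {
    "no_HapF"
  } else if (absence_ok && !f2_signal) {
    "HapF_DEL"
  } else if (absence_ok && f2_signal) {
    "ambiguous"
  } else if (intact && sup("tandem_junction") >= min_reads) {
    "HapF2"
  } else if (intact && sup("tandem_junction") < min_reads &&
             !f2_signal) {
    "HapF1"
  } else {
    "ambiguous"
  }
  structure(list(accession = accession, call = call, evidence = ev,
                 thresholds = list(min_reads = as.integer(min_reads))),
            class = "haplotype_call")
}

#' @export
print.haplotype_call <- function(x, ...) {
  cat(sprintf("<haplotype_call> %s: %s\n", x$accession, x$call))
  for (e in x$evidence) {
    cat(sprintf("  %-18s %-14s sup %4d  opp %4d  (%s)\n", e$marker_id,
                e$kind, e$supporting, e$opposing, e$supports))
  }
  invisible(x)
}

#' End-to-end subhaplotype diagnosis of a read set
#'
#' Maps reads to the panel references, scans every marker, and classifies.
#'
#' @param reads A `read_set` data.frame (simulated or parsed from FASTQ).
#' @param panel A [hapf_marker_panel()].
#' @param min_overhang,min_reads Evidence thresholds.
#' @param accession Sample identifier.
#' @return A `haplotype_call`.
#' @export
diagnose_reads <- function(reads, panel, min_overhang = 20L, min_reads = 3L,
                           accession = "sample") {
  stopifnot(inherits(panel, "marker_panel"))
  aln <- map_reads(reads, panel$refs, mode = "all")
  evidence <- lapply(panel$markers, scan_marker, alignments = aln,
                     min_overhang = min_overhang)
  classify_subhaplotype(unname(evidence), min_reads = min_reads,
                        accession = accession)
}

#' Write / read a marker panel as FASTA + TSV
#'
#' The TSV columns are `id`, `kind`, `reference`, `position`,
#' `interval_start`, `interval_end`, `expected_state`, `supports`; marker
#' reference sequences go to a FASTA alongside.
#'
#' @param panel A `marker_panel`.
#' @param fasta,tsv Paths for references and marker definitions.
#' @return `write_marker_panel`: the paths, invisibly; `read_marker_panel`:
#'   the reconstructed `marker_panel`.
#' @export
write_marker_panel <- function(panel, fasta, tsv) {
  dss <- Biostrings::DNAStringSet(panel$refs)
  Biostrings::writeXStringSet(dss, fasta)
  rows <- do.call(rbind, lapply(panel$markers, function(m) {
    data.frame(id = m$id, kind = m$kind, reference = m$reference,
               position = m$position, interval_start = m$interval[1L],
               interval_end = m$interval[2L],
               expected_state = m$expected_state, supports = m$supports,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta, tsv = tsv))
}

#' @rdname write_marker_panel
#' @export
read_marker_panel <- function(fasta, tsv) {
  dss <- Biostrings::readDNAStringSet(fasta)
  refs <- stats::setNames(as.character(dss), names(dss))
  rows <- utils::read.table(tsv, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  markers <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    diagnostic_marker(r$id, r$kind, r$reference, position = r$position,
                      interval = c(r$interval_start, r$interval_end),
                      expected_state = r$expected_state,
                      supports = r$supports)
  })
  names(markers) <- rows$id
  structure(list(refs = refs, markers = markers, seed = NA_integer_),
            class = "marker_panel")
}
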