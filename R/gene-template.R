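#' Construct a gene template
#'
#' A gene template is the unit the synthetic-locus builder works with: a
#' genomic DNA string, its exon intervals, and the promoter span upstream of
#' exon 1. Alleles are derived from a template by applying [variant_spec()]
#' edits with [build_allele()]. Coordinates are 1-based closed throughout
#' (the IRanges convention); GFF3 output keeps the same convention.
#'
#' @param name Gene name, e.g. `"VvMybA1"`.
#' @param sequence Genomic DNA character scalar.
#' @param exons Integer matrix with columns `start`, `end` (1-based closed),
#'   rows sorted and non-overlapping.
#' @param promoter Length-2 integer vector, promoter interval upstream of
#'   exon 1.
#' @return An object of class `gene_template`.
#' @export
gene_template <- function(name, sequence, exons, promoter) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  stopifnot(all(exons[, 1L] <= exons[, 2L]),
            all(exons >= 1L), all(exons <= nchar(sequence)))
  if (nrow(exons) > 1L) {
    stopifnot(!is.unsorted(exons[, 1L]),
              all(exons[-1L, 1L] > exons[-nrow(exons), 2L]))
  }
  structure(
    list(name = name, sequence = sequence, exons = exons,
         promoter = as.integer(promoter), edits = list()),
    class = "gene_template")
}

#' @export
print.gene_template <- function(x, ...) {
  cat(sprintf("<gene_template> %s: %d bp, %d exons, CDS %d bp, %d edits\n",
              x$name, nchar(x$sequence), nrow(x$exons),
              sum(x$exons[, 2L] - x$exons[, 1L] + 1L), length(x$edits)))
  invisible(x)
}

#' Describe a single edit to apply to a gene template
#'
#' Variant kinds mirror the structural features reported at the berry color
#' locus: small insertions (such as the 44/111/33-bp insertions that define
#' the VvMybA1_SUB allele), deletions (the 209-bp exon-3 deletion that
#' inactivates VvMybA3 outside haplotype F), substitutions, in-place
#' duplications (the 282-bp C-terminal repeat of VvMybA2), and
#' LTR-retrotransposon insertions (Gret1 in the VvMybA1 promoter of
#' haplotype A).
#'
#' @param kind One of `"insertion"`, `"deletion"`, `"substitution"`,
#'   `"duplication"`, `"te_insertion"`.
#' @param position 1-based template coordinate. Insertions are placed
#'   immediately *before* this position; deletions/substitutions/duplications
#'   start at it.
#' @param payload Kind-specific: DNA string (insertion, substitution), length
#'   in bp (deletion, duplication), or a TE object from [make_te()]
#'   (te_insertion).
#' @param label Free-text label carried into the edit log and annotations.
#' @param identity For duplications only: nucleotide identity of the new copy
#'   to the original, in \[0, 1\] (1 = exact copy).
#' @return An object of class `variant_spec`.
#' @export
variant_spec <- function(kind, position, payload, label = kind,
                         identity = 1) {
  kind <- match.arg(kind, c("insertion", "deletion", "substitution",
                            "duplication", "te_insertion"))
  stopifnot(position >= 1, identity >= 0, identity <= 1)
  structure(list(kind = kind, position = as.integer(position),
                 payload = payload, label = label, identity = identity),
            class = "variant_spec")
}

variant_length <- function(v) {
  switch(v$kind,
    insertion = , substitution = nchar(v$payload),
    deletion = , duplication = as.integer(v$payload),
    te_insertion = nchar(v$payload$sequence))
}

#' Apply variants to a gene template
#'
#' Variants are applied right-to-left (sorted by decreasing position) so that
#' coordinates never shift under earlier edits. Exon and promoter intervals
#' are remapped across indels; an indel that only partially overlaps an exon
#' is rejected as a coordinate conflict. The edit log of the returned
#' template records every applied variant.
#'
#' @param template A [gene_template()].
#' @param variants List of [variant_spec()] objects (may be empty).
#' @return The edited `gene_template`, with `edits` extended and, for
#'   TE insertions, a `te` field holding the feature span.
#' @export
build_allele <- function(template, variants = list()) {
  stopifnot(inherits(template, "gene_template"))
  if (inherits(variants, "variant_spec")) variants <- list(variants)
  if (!length(variants)) return(template)
  pos <- vapply(variants, function(v) v$position, integer(1L))
  stopifnot(all(pos >= 1L), all(pos <= nchar(template$sequence) + 1L))
  out <- template
  for (v in variants[order(pos, decreasing = TRUE)]) {
    out <- apply_variant(out, v)
  }
  out
}

apply_variant <- function(tpl, v) {
  n <- nchar(tpl$sequence)
  s <- tpl$sequence
  p <- v$position
  if (v$kind == "substitution") {
    len <- nchar(v$payload)
    stopifnot(p + len - 1L <= n)
    substr(s, p, p + len - 1L) <- v$payload
    tpl$sequence <- s
  } else if (v$kind %in% c("insertion", "te_insertion")) {
    ins <- if (v$kind == "te_insertion") v$payload$sequence else v$payload
    len <- nchar(ins)
    tpl$sequence <- paste0(substr(s, 1L, p - 1L), ins, substr(s, p, n))
    tpl$exons <- shift_intervals_insert(tpl$exons, p, len, v$label)
    tpl$promoter <- drop_shift_insert(tpl$promoter, p, len)
    if (v$kind == "te_insertion") {
      te <- v$payload
      tpl$te <- list(name = te$name, start = p, end = p + len - 1L,
                     ltr5 = te$ltr5 + p - 1L, ltr3 = te$ltr3 + p - 1L,
                     age = te$age)
    }
  } else if (v$kind == "deletion") {
    len <- as.integer(v$payload)
    q <- p + len - 1L
    stopifnot(q <= n)
    check_indel_consistent(tpl$exons, p, q, v$label)
    tpl$sequence <- paste0(substr(s, 1L, p - 1L), substr(s, q + 1L, n))
    tpl$exons <- shift_intervals_delete(tpl$exons, p, q)
    tpl$promoter <- drop_shift_delete(tpl$promoter, p, q)
  } else if (v$kind == "duplication") {
    len <- as.integer(v$payload)
    q <- p + len - 1L
    stopifnot(q <= n)
    copy <- substr(s, p, q)
    if (v$identity < 1) copy <- mutate_dna(copy, 1 - v$identity)
    ins <- variant_spec("insertion", q + 1L, copy, label = v$label)
    tpl <- apply_variant(tpl, ins)
    tpl$edits <- tpl$edits[-length(tpl$edits)]
  }
  tpl$edits <- c(tpl$edits, list(v))
  tpl
}

# insertion of `len` bases immediately before position `p`
shift_intervals_insert <- function(iv, p, len, label) {
  if (is.null(iv) || !nrow(iv)) return(iv)
  for (i in seq_len(nrow(iv))) {
    s <- iv[i, 1L]; e <- iv[i, 2L]
    if (p <= s) {
      iv[i, ] <- c(s + len, e + len)
    } else if (p <= e) {          # inserted inside the exon: exon grows
      iv[i, 2L] <- e + len
    }
  }
  iv
}

shift_intervals_delete <- function(iv, p, q) {
  if (is.null(iv) || !nrow(iv)) return(iv)
  len <- q - p + 1L
  for (i in seq_len(nrow(iv))) {
    s <- iv[i, 1L]; e <- iv[i, 2L]
    if (q < s) {
      iv[i, ] <- c(s - len, e - len)
    } else if (p >= s && q <= e) { # fully inside exon: exon shrinks
      iv[i, 2L] <- e - len
    }
  }
  iv
}

# an indel must fall fully inside an exon or fully outside all exons
check_indel_consistent <- function(iv, p, q, label) {
  if (is.null(iv) || !nrow(iv)) return(invisible())
  for (i in seq_len(nrow(iv))) {
    s <- iv[i, 1L]; e <- iv[i, 2L]
    overlaps <- p <= e && q >= s
    inside <- p >= s && q <= e
    if (overlaps && !inside) {
      stop("coordinate conflict: variant '", label,
           "' [", p, ",", q, "] straddles an exon boundary [",
           s, ",", e, "]", call. = FALSE)
    }
  }
  invisible()
}

drop_shift_insert <- function(interval, p, len) {
  if (is.null(interval)) return(interval)
  ifelse(interval >= p, interval + len, interval)
}

drop_shift_delete <- function(interval, p, q) {
  if (is.null(interval)) return(interval)
  len <- q - p + 1L
  ifelse(interval > q, interval - len, interval)
}

#' Spliced coding sequence of a template
#'
#' @param template A [gene_template()].
#' @return Character scalar: exon sequences concatenated 5' to 3'.
#' @export
spliced_cds <- function(template) {
  paste(substring(template$sequence, template$exons[, 1L],
                  template$exons[, 2L]), collapse = "")
}
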