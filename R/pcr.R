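#' In-silico PCR on a DNA sequence
#'
#' Finds exact primer binding sites (forward primer on either strand, with
#' the reverse primer's reverse complement downstream within `max_product`)
#' and returns every amplifiable product. Both primer orientations are
#' scanned, so product lengths are invariant under reverse-complementing the
#' input sequence.
#'
#' @param sequence Template DNA character scalar.
#' @param forward_primer,reverse_primer Primer sequences, 5'->3', each at
#'   least 15 bp.
#' @param max_product Maximum product length in bp.
#' @return data.frame with `product_length`, `start`, `end` (inclusive span
#'   on the input sequence), sorted; zero rows when no site pair amplifies.
#' @export
insilico_pcr <- function(sequence, forward_primer, reverse_primer,
                         max_product = 5000L) {
  stopifnot(nchar(forward_primer) >= 15L, nchar(reverse_primer) >= 15L)
  subject <- Biostrings::DNAString(sequence)
  site_starts <- function(p) {
    Biostrings::start(Biostrings::matchPattern(Biostrings::DNAString(p),
                                               subject))
  }
  products <- list()
  for (pair in list(c(forward_primer, reverse_primer),
                    c(reverse_primer, forward_primer))) {
    fs <- site_starts(pair[1L])
    rs <- site_starts(revcomp(pair[2L]))
    if (!length(fs) || !length(rs)) next
    re <- rs + nchar(pair[2L]) - 1L
    for (f in fs) {
      hit <- re[re >= f + nchar(pair[1L]) & re - f + 1L <= max_product]
      if (length(hit)) {
        products[[length(products) + 1L]] <- data.frame(
          product_length = hit - f + 1L, start = f, end = hit)
      }
    }
  }
  if (!length(products)) {
    return(data.frame(product_length = integer(), start = integer(),
                      end = integer()))
  }
  out <- unique(do.call(rbind, products))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The VvMybA3_HapF INDEL assay definition
#'
#' Primers flank the 209-bp region of VvMybA3 exon 3 that is deleted in all
#' non-F haplotypes, so the HapF allele yields a product 209 bp longer than
#' the HapA/HapC-N allele; the diagnostic (HapF-length) product is the
#' assay's positive signal. Primer sites sit in sequence shared by all
#' VvMybA3 alleles.
#'
#' @param config A [default_locus_config()].
#' @return List with `forward`, `reverse`, `diagnostic_length`,
#'   `nonf_length`, `max_product`.
#' @export
vvmyba3_assay <- function(config) {
  tpl <- config$templates$VvMybA3$sequence
  f_start <- 1100L; f_end <- 1124L
  r_start <- 1500L; r_end <- 1524L
  forward <- substr(tpl, f_start, f_end)
  reverse <- revcomp(substr(tpl, r_start, r_end))
  list(forward = forward, reverse = reverse,
       diagnostic_length = r_end - f_start + 1L,
       nonf_length = r_end - f_start + 1L - 209L,
       max_product = 2000L)
}

#' Run the VvMybA3_HapF assay on a diploid haplotype pair
#'
#' @param hap_pair List of two [build_haplotype()] models (or one model for
#'   a haploid test).
#' @param assay Assay definition from [vvmyba3_assay()].
#' @return Logical: `TRUE` iff either haplotype yields the HapF-diagnostic
#'   product; attribute `products` holds the per-haplotype product tables.
#' @export
assay_vvmyba3_hapF <- function(hap_pair, assay) {
  if (inherits(hap_pair, "haplotype_model")) hap_pair <- list(hap_pair)
  prods <- lapply(hap_pair, function(h) {
    insilico_pcr(h$sequence, assay$forward, assay$reverse,
                 max_product = assay$max_product)
  })
  names(prods) <- vapply(hap_pair, `[[`, "", "name")
  positive <- any(vapply(prods, function(p) {
    any(p$product_length == assay$diagnostic_length)
  }, logical(1L)))
  structure(positive, products = prods)
}
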