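#' Generate a random DNA sequence
#'
#' Draws an i.i.d. nucleotide string at a given GC content. Uses the current
#' R random-number stream; callers that need reproducibility should
#' `set.seed()` first (all simulators in this package do so via their `seed`
#' argument).
#'
#' @param n Sequence length in bp.
#' @param gc Target GC fraction (default 0.45, typical for plant genic
#'   regions).
#' @return A character scalar of length-`n` DNA.
#' @export
random_dna <- function(n, gc = 0.45) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a random coding sequence
#'
#' Builds `n_codons` codons: an ATG start, random internal codons with stop
#' codons excluded, and a terminal TAA. Translation therefore yields
#' `n_codons - 1` amino acids.
#'
#' @param n_codons Total codon count including start and stop.
#' @return Character scalar of DNA, length `3 * n_codons`.
#' @export
random_cds <- function(n_codons) {
  stopifnot(n_codons >= 2)
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1L, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  body <- sample(codons, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

#' Apply random point substitutions at a fixed per-site divergence
#'
#' Each position is substituted with probability `divergence`, always to a
#' different base. Used to derive paralog and duplicated-copy sequences at a
#' controlled nucleotide identity.
#'
#' @param seq DNA character scalar.
#' @param divergence Per-site substitution probability in \[0, 1\].
#' @return Mutated character scalar of the same length.
#' @export
mutate_dna <- function(seq, divergence) {
  stopifnot(divergence >= 0, divergence <= 1)
  if (divergence == 0 || nchar(seq) == 0L) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(x)) < divergence)
  if (length(hit)) x[hit] <- vapply(x[hit], other_base, character(1L))
  paste(x, collapse = "")
}

# substitute one base for a uniformly chosen different base
other_base <- function(b) {
  sample(setdiff(c("A", "C", "G", "T"), b), 1L)
}

#' Mutate a coding sequence without breaking the reading frame
#'
#' Like [mutate_dna()] but keeps the ATG start and terminal stop intact and
#' repairs any internal stop codon created by mutation (third codon position
#' set to C), so the result remains a translatable CDS of the same length.
#'
#' @inheritParams mutate_dna
#' @return Mutated CDS, same length, still `ATG ... TAA/TAG/TGA`-free
#'   internally.
#' @export
mutate_cds <- function(seq, divergence) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0, n >= 6)
  mid <- mutate_dna(substr(seq, 4L, n - 3L), divergence)
  out <- paste0(substr(seq, 1L, 3L), mid, substr(seq, n - 2L, n))
  x <- strsplit(out, "", fixed = TRUE)[[1L]]
  starts <- seq(4L, n - 5L, by = 3L)
  cod <- paste0(x[starts], x[starts + 1L], x[starts + 2L])
  bad <- which(cod %in% c("TAA", "TAG", "TGA"))
  for (i in bad) x[starts[i] + 2L] <- "C"
  paste(x, collapse = "")
}

#' Reverse-complement a DNA string
#'
#' @param seq DNA character scalar.
#' @return Reverse complement as a character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# fast substring extraction of many windows from one sequence
substr_many <- function(seq, start, end) {
  substring(seq, start, end)
}

# count mismatching positions between equal-length DNA strings (vectorised
# over pairs); returns integer vector
hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!length(a)) return(integer(0))
  n <- nchar(a)
  stopifnot(all(nchar(b) == n))
  am <- matrix(unlist(strsplit(a, "", fixed = TRUE), use.names = FALSE),
               nrow = length(a), byrow = TRUE)
  bm <- matrix(unlist(strsplit(b, "", fixed = TRUE), use.names = FALSE),
               nrow = length(b), byrow = TRUE)
  as.integer(rowSums(am != bm))
}
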