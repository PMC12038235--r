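#' Build a synthetic LTR retrotransposon
#'
#' An LTR retrotransposon carries two identical long terminal repeats at the
#' moment of insertion; substitutions accumulate independently in each LTR
#' afterwards, so their divergence dates the insertion (see [ltr_age()]).
#' This constructor makes `LTR + internal + LTR` with both LTRs identical,
#' then ages the element with [mutate_ltr_pair()].
#'
#' @param name TE name (e.g. `"Gret1"`, `"RLG_1"`).
#' @param ltr_len LTR length in bp.
#' @param internal_len Internal-domain length in bp.
#' @param age Insertion age in years (0 = brand-new element, LTRs identical).
#' @param mu Substitution rate per site per year (default `1.3e-8`).
#' @param seed Optional integer seed for the aging substitutions.
#' @return A list with `name`, `sequence`, `ltr5`, `ltr3` (1-based closed
#'   spans within the element), and `age`.
#' @export
make_te <- function(name, ltr_len = 400L, internal_len = 2200L, age = 0,
                    mu = 1.3e-8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ltr <- random_dna(ltr_len)
  internal <- random_dna(internal_len)
  te <- list(name = name,
             sequence = paste0(ltr, internal, ltr),
             ltr5 = c(1L, ltr_len),
             ltr3 = c(ltr_len + internal_len + 1L,
                      2L * ltr_len + internal_len),
             age = age)
  if (age > 0) te$sequence <- mutate_ltr_pair(te$sequence, te$ltr5, te$ltr3,
                                              age = age, mu = mu)
  te
}

#' Age an LTR pair by the molecular clock
#'
#' Each LTR independently accumulates `Poisson(mu * age * L)` substitutions
#' at uniformly chosen positions (substitution always to a different base),
#' so the expected pairwise divergence of the two LTRs is `2 * mu * age`.
#'
#' @param sequence Element (or haplotype) DNA as a character scalar.
#' @param ltr5,ltr3 Length-2 integer vectors: 1-based closed spans of the 5'
#'   and 3' LTR within `sequence`.
#' @param age Age in years (>= 0).
#' @param mu Substitution rate per site per year (> 0 unless `age == 0`).
#' @param seed Optional integer seed.
#' @return The mutated sequence (same length).
#' @export
mutate_ltr_pair <- function(sequence, ltr5, ltr3, age, mu = 1.3e-8,
                            seed = NULL) {
  stopifnot(age >= 0, mu >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (age == 0) return(sequence)
  for (span in list(ltr5, ltr3)) {
    L <- span[2L] - span[1L] + 1L
    stopifnot(L >= 1L)
    k <- stats::rpois(1L, mu * age * L)
    if (k == 0L) next
    at <- span[1L] - 1L + sample.int(L, min(k, L))
    x <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    x[at] <- vapply(x[at], other_base, character(1L))
    sequence <- paste(x, collapse = "")
  }
  sequence
}

#' Simulate whole-genome shotgun reads from one or two haplotypes
#'
#' Substitution-only short-read simulator. Read start positions are uniform;
#' for a diploid input each read is drawn from either haplotype with
#' probability 1/2. The origin haplotype and interval of every read are
#' retained as truth labels, and the simulation is bit-reproducible under a
#' fixed seed.
#'
#' @param haps A single [build_haplotype()] model or a list of two (a diploid
#'   pair).
#' @param depth Target fold-coverage per haplotype copy contributed
#'   (total over the pair for a diploid).
#' @param read_len Read length in bp (must be shorter than every haplotype).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `id`, `seq`, `hap`, `start`, `end`
#'   (truth interval on the haplotype of origin), of class `read_set`.
#' @export
simulate_dna_reads <- function(haps, depth, read_len = 150L,
                               error_rate = 0, seed = 1L) {
  if (inherits(haps, "haplotype_model")) haps <- list(haps)
  stopifnot(length(haps) %in% c(1L, 2L), depth > 0,
            error_rate >= 0, error_rate < 1)
  lens <- vapply(haps, function(h) nchar(h$sequence), integer(1L))
  if (any(read_len >= lens)) {
    stop("read_len must be shorter than every haplotype sequence")
  }
  set.seed(seed)
  total_reads <- as.integer(round(depth * sum(lens) / read_len /
                                    length(haps)))
  src <- if (length(haps) == 2L) {
    sample.int(2L, total_reads, replace = TRUE)
  } else rep(1L, total_reads)
  start <- integer(total_reads)
  for (i in seq_along(haps)) {
    idx <- which(src == i)
    start[idx] <- sample.int(lens[i] - read_len + 1L, length(idx),
                             replace = TRUE)
  }
  seqs <- character(total_reads)
  for (i in seq_along(haps)) {
    idx <- which(src == i)
    seqs[idx] <- substring(haps[[i]]$sequence, start[idx],
                           start[idx] + read_len - 1L)
  }
  ## half the reads come from the minus strand, as in real libraries
  minus <- stats::runif(total_reads) < 0.5
  if (any(minus)) {
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  }
  seqs <- add_read_errors(seqs, error_rate)
  hap_names <- vapply(haps, function(h) h$name, character(1L))
  out <- data.frame(
    id = sprintf("read_%06d", seq_len(total_reads)),
    seq = seqs,
    hap = hap_names[src],
    strand = ifelse(minus, "-", "+"),
    start = start,
    end = start + read_len - 1L,
    stringsAsFactors = FALSE)
  class(out) <- c("read_set", class(out))
  attr(out, "read_len") <- as.integer(read_len)
  attr(out, "error_rate") <- error_rate
  attr(out, "seed") <- as.integer(seed)
  out
}

# substitution-only sequencing errors, vectorised over all read bases
add_read_errors <- function(seqs, error_rate) {
  if (error_rate == 0 || !length(seqs)) return(seqs)
  n <- nchar(seqs[1L])
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
  hit <- which(matrix(stats::runif(length(chars)) < error_rate,
                      nrow = nrow(chars)))
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], other_base, character(1L))
  }
  apply(chars, 1L, paste, collapse = "")
}

#' Configuration for the allele-tagged RNA read simulator
#'
#' @param allele_cdnas Named character vector (or list) of spliced allele
#'   cDNA sequences.
#' @param allele_tpm Named numeric vector of true expression levels
#'   (transcripts per million scale); non-negative, not all zero.
#' @param read_len RNA read length in bp.
#' @param n_reads Total read count to simulate.
#' @param seed Integer seed.
#' @param error_rate Per-base substitution error probability.
#' @return An object of class `rna_sim_config`.
#' @export
rna_sim_config <- function(allele_cdnas, allele_tpm, read_len = 100L,
                           n_reads = 10000L, seed = 1L, error_rate = 0) {
  allele_cdnas <- unlist(allele_cdnas)
  stopifnot(!is.null(names(allele_cdnas)), !anyDuplicated(names(allele_cdnas)),
            setequal(names(allele_cdnas), names(allele_tpm)),
            all(allele_tpm >= 0))
  if (all(allele_tpm == 0)) stop("all-zero expression: no reads to simulate")
  allele_tpm <- allele_tpm[names(allele_cdnas)]
  structure(list(allele_cdnas = allele_cdnas, allele_tpm = allele_tpm,
                 read_len = as.integer(read_len),
                 n_reads = as.integer(n_reads), seed = as.integer(seed),
                 error_rate = error_rate),
            class = "rna_sim_config")
}

#' Simulate RNA reads from allele cDNAs
#'
#' Reads are assigned to alleles multinomially with probabilities
#' proportional to `tpm * length` (TPM is a per-transcript measure, so the
#' read count scales with transcript length), then start positions are drawn
#' uniformly along each cDNA. Truth allele labels are retained.
#'
#' @param cfg An [rna_sim_config()].
#' @return A `read_set` data.frame as in [simulate_dna_reads()], with `hap`
#'   holding the allele of origin.
#' @export
simulate_rna_reads <- function(cfg) {
  stopifnot(inherits(cfg, "rna_sim_config"))
  set.seed(cfg$seed)
  lens <- nchar(cfg$allele_cdnas)
  stopifnot(all(cfg$read_len <= lens))
  w <- cfg$allele_tpm * lens
  counts <- as.vector(stats::rmultinom(1L, cfg$n_reads, prob = w / sum(w)))
  allele <- rep(names(cfg$allele_cdnas), counts)
  start <- integer(cfg$n_reads)
  seqs <- character(cfg$n_reads)
  for (i in seq_along(cfg$allele_cdnas)) {
    idx <- which(allele == names(cfg$allele_cdnas)[i])
    if (!length(idx)) next
    start[idx] <- sample.int(lens[i] - cfg$read_len + 1L, length(idx),
                             replace = TRUE)
    seqs[idx] <- substring(cfg$allele_cdnas[i], start[idx],
                           start[idx] + cfg$read_len - 1L)
  }
  seqs <- add_read_errors(seqs, cfg$error_rate)
  out <- data.frame(
    id = sprintf("rna_%06d", seq_len(cfg$n_reads)),
    seq = seqs, hap = allele, start = start,
    end = start + cfg$read_len - 1L, stringsAsFactors = FALSE)
  class(out) <- c("read_set", class(out))
  attr(out, "read_len") <- cfg$read_len
  attr(out, "seed") <- cfg$seed
  out
}

#' Write simulated reads to FASTQ
#'
#' Qualities are uniform `I` (Q40): the simulator models substitution errors
#' only, so per-base qualities carry no extra information.
#'
#' @param reads A `read_set` data.frame.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(reads$seq)
  names(dss) <- reads$id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  invisible(path)
}
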