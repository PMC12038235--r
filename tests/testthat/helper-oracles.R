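# Independent oracle implementations used to cross-check the package's
# computations. These deliberately share no code with the implementation.

# Closed-form TN93 distance from the raw pair of (ungapped, equal-length)
# sequences, with base frequencies pooled over the pair.
tn93_oracle <- function(s1, s2) {
  a <- strsplit(s1, "", fixed = TRUE)[[1L]]
  b <- strsplit(s2, "", fixed = TRUE)[[1L]]
  g <- table(factor(c(a, b), levels = c("A", "C", "G", "T"))) /
    (2 * length(a))
  gA <- g[["A"]]; gC <- g[["C"]]; gG <- g[["G"]]; gT <- g[["T"]]
  gR <- gA + gG; gY <- gC + gT
  P1 <- mean((a == "A" & b == "G") | (a == "G" & b == "A"))
  P2 <- mean((a == "C" & b == "T") | (a == "T" & b == "C"))
  Q <- mean(a != b) - P1 - P2
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  -k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
    k2 * log(1 - P2 / k2 - Q / (2 * gY)) -
    2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY) *
      log(1 - Q / (2 * gR * gY))
}

# Brute-force breakpoint-spanning check for one read
spans_oracle <- function(start, end, bp, ov) {
  (bp - start + 1L) >= ov && (end - bp) >= ov
}

# Minimal alignment table for marker-scanning tests
toy_alignments <- function(pos, width, ref = "ref", seqs = NULL,
                           refs = "ref") {
  df <- data.frame(
    qname = sprintf("r%03d", seq_along(pos)),
    rname = rep(ref, length(pos)), pos = as.integer(pos),
    strand = rep("+", length(pos)),
    seq = if (is.null(seqs)) rep(strrep("A", width), length(pos)) else seqs,
    nm = rep(0L, length(pos)),
    width = rep(as.integer(width), length(pos)), stringsAsFactors = FALSE)
  attr(df, "refs") <- refs
  df
}
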