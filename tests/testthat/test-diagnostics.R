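test_that("scan_marker agrees with a brute-force per-read oracle", {
  set.seed(42)
  width <- 100L
  bp <- 200L
  pos <- sample.int(300L, 60L, replace = TRUE)
  aln <- toy_alignments(pos, width)

  jm <- diagnostic_marker("j", "junction", "ref", position = bp)
  ev <- scan_marker(aln, jm, min_overhang = 20L)
  oracle <- sum(vapply(pos, function(s) {
    spans_oracle(s, s + width - 1L, bp, 20L)
  }, logical(1L)))
  expect_equal(ev$supporting, oracle)

  # insertion-span: support = spanning either boundary of the insert
  im <- diagnostic_marker("i", "insertion_span", "ref",
                          interval = c(180L, 212L))
  evi <- scan_marker(aln, im, min_overhang = 20L)
  oracle_i <- sum(vapply(pos, function(s) {
    spans_oracle(s, s + width - 1L, 179L, 20L) ||
      spans_oracle(s, s + width - 1L, 212L, 20L)
  }, logical(1L)))
  expect_equal(evi$supporting, oracle_i)

  # reads ending exactly at the breakpoint do not support it
  edge <- toy_alignments(c(bp - width + 1L, bp + 1L), width)
  expect_equal(scan_marker(edge, jm, min_overhang = 20L)$supporting, 0L)

  # empty alignment set
  expect_equal(scan_marker(toy_alignments(integer(), width), jm)$supporting,
               0L)
  expect_equal(scan_marker(toy_alignments(integer(), width), jm)$opposing,
               0L)

  # marker reference absent from the header errors
  expect_error(
    scan_marker(aln, diagnostic_marker("x", "junction", "other",
                                       position = 5L)),
    "absent from alignment header")
})

test_that("private-SNP and absence-region evidence count reads correctly", {
  width <- 50L
  seqs <- c(strrep("A", 50L), strrep("A", 50L),
            paste0(strrep("A", 24L), "G", strrep("A", 25L)))
  aln <- toy_alignments(c(1L, 10L, 1L), width, seqs = seqs)
  sm <- diagnostic_marker("s", "private_snp", "ref", position = 25L,
                          expected_state = "G")
  ev <- scan_marker(aln, sm)
  expect_equal(ev$supporting, 1L)   # read 3 carries G at position 25
  expect_equal(ev$opposing, 2L)     # reads 1-2 carry A there

  am <- diagnostic_marker("a", "absence_region", "ref",
                          interval = c(100L, 200L))
  flank_only <- toy_alignments(c(1L, 10L, 30L, 220L), width)
  eva <- scan_marker(flank_only, am, min_overhang = 20L)
  expect_equal(eva$opposing, 0L)
  expect_equal(eva$supporting, 4L)
  covered <- toy_alignments(c(1L, 90L, 120L), width)
  evc <- scan_marker(covered, am, min_overhang = 20L)
  expect_equal(evc$opposing, 2L)    # reads overlapping >= 20 bp
})

test_that("HapF detection applies the evidence threshold", {
  ev <- function(n) structure(list(marker_id = "hapF_ins33",
                                   kind = "insertion_span",
                                   supports = "HapF", supporting = n,
                                   opposing = 0L, mean_overhang = NA_real_),
                              class = "read_evidence")
  expect_true(detect_hapF(ev(12L)))
  expect_false(detect_hapF(ev(0L)))
  low <- detect_hapF(ev(2L), min_reads = 3L)
  expect_false(low)
  expect_true(attr(low, "low_evidence"))
})

test_that("classification is a pure function of evidence and thresholds", {
  mk <- function(id, sup, opp = 0L) {
    structure(list(marker_id = id, kind = "junction", supports = NA,
                   supporting = as.integer(sup), opposing = as.integer(opp),
                   mean_overhang = NA_real_), class = "read_evidence")
  }
  base <- function(ins33, tj, i213, rlg, al_s, al_o, ar_s, ar_o) {
    list(mk("hapF_ins33", ins33), mk("tandem_junction", tj),
         mk("ins213_A4a", i213), mk("rlg_A4b_junction", rlg),
         mk("absence_left", al_s, al_o), mk("absence_right", ar_s, ar_o))
  }
  expect_equal(classify_subhaplotype(base(0, 0, 0, 0, 0, 0, 0, 0))$call,
               "no_HapF")
  expect_equal(classify_subhaplotype(base(10, 0, 0, 0, 30, 0, 28, 0))$call,
               "HapF_DEL")
  expect_equal(classify_subhaplotype(base(10, 8, 6, 7, 20, 40, 22, 38))$call,
               "HapF2")
  expect_equal(classify_subhaplotype(base(10, 0, 0, 0, 20, 40, 22, 38))$call,
               "HapF1")
  # conflict: deletion confirmed AND tandem junction present
  expect_equal(classify_subhaplotype(base(10, 8, 0, 0, 30, 0, 28, 0))$call,
               "ambiguous")
  # determinism: identical evidence gives the identical call
  e <- base(10, 8, 6, 7, 20, 40, 22, 38)
  expect_identical(classify_subhaplotype(e)$call,
                   classify_subhaplotype(e)$call)
  # incomplete evidence names the missing marker
  expect_error(classify_subhaplotype(e[-2L]), "tandem_junction")
})

test_that("simulated diploid read sets are diagnosed correctly", {
  panel <- fx_panel()
  ha <- fx_hap("HapA")
  for (truth in c("HapF1", "HapF2", "HapF_DEL")) {
    for (seed in c(101L, 202L, 303L)) {
      reads <- simulate_dna_reads(list(fx_hap(truth), ha), depth = 20,
                                  read_len = 150L, error_rate = 0.005,
                                  seed = seed)
      call <- diagnose_reads(reads, panel, accession = truth)
      expect_equal(call$call, truth)
    }
  }
  reads <- simulate_dna_reads(list(ha, ha), depth = 20, read_len = 150L,
                              error_rate = 0.005, seed = 404L)
  expect_equal(diagnose_reads(reads, panel)$call, "no_HapF")
})

test_that("marker panels round-trip through FASTA + TSV", {
  panel <- fx_panel()
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_marker_panel(panel, fa, tsv)
  back <- read_marker_panel(fa, tsv)
  expect_identical(unname(back$refs), unname(panel$refs))
  expect_identical(names(back$markers), names(panel$markers))
  expect_equal(back$markers$tandem_junction$position,
               panel$markers$tandem_junction$position)
})

test_that("in-silico PCR finds products and is strand-invariant", {
  cfg <- fx_config()
  assay <- vvmyba3_assay(cfg)
  f1 <- fx_hap("HapF1")
  ha <- fx_hap("HapA")

  p_f <- insilico_pcr(f1$sequence, assay$forward, assay$reverse,
                      assay$max_product)
  p_a <- insilico_pcr(ha$sequence, assay$forward, assay$reverse,
                      assay$max_product)
  # the HapF product is exactly 209 bp longer than the non-F product
  expect_equal(p_f$product_length, p_a$product_length + 209L)

  # product lengths invariant under reverse-complementing the template
  p_rc <- insilico_pcr(revcomp(f1$sequence), assay$forward, assay$reverse,
                       assay$max_product)
  expect_equal(sort(p_rc$product_length), sort(p_f$product_length))

  # absent primer site gives no product
  expect_equal(nrow(insilico_pcr(f1$sequence, strrep("ACGT", 5L),
                                 assay$reverse)), 0L)
  expect_error(insilico_pcr(f1$sequence, "ACGTACGT", assay$reverse))
})

test_that("the VvMybA3_HapF INDEL assay separates genotypes", {
  cfg <- fx_config()
  assay <- vvmyba3_assay(cfg)
  ha <- fx_hap("HapA")
  expect_true(as.logical(assay_vvmyba3_hapF(list(fx_hap("HapF1"), ha),
                                            assay)))
  expect_true(as.logical(assay_vvmyba3_hapF(list(fx_hap("HapF2"), ha),
                                            assay)))
  expect_false(as.logical(assay_vvmyba3_hapF(list(fx_hap("HapF_DEL"), ha),
                                             assay)))
  expect_false(as.logical(assay_vvmyba3_hapF(list(ha, ha), assay)))
})

test_that("alignment tables round-trip through SAM", {
  f2 <- fx_hap("HapF2")
  reads <- simulate_dna_reads(f2, depth = 2, read_len = 100L,
                              error_rate = 0, seed = 3L)
  refs <- c(w1 = substr(f2$sequence, 30001L, 32000L))
  aln <- map_reads(reads, refs)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, refs, sam)
  back <- read_sam(sam)
  expect_equal(nrow(back), nrow(aln))
  expect_setequal(attr(back, "refs"), names(refs))
  key <- function(x) paste(x$qname, x$rname, x$pos, x$strand, x$seq)
  expect_setequal(key(back), key(aln))
})
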