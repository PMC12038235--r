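test_that("build_allele applies variants and round-trips indels", {
  cfg <- fx_config()
  tpl <- cfg$templates$VvMybA1

  expect_identical(build_allele(tpl, list())$sequence, tpl$sequence)

  sub <- build_allele(tpl, cfg$alleles$VvMybA1_SUB$variants)
  expect_equal(nchar(sub$sequence), nchar(tpl$sequence) + 188L)
  expect_equal(nchar(spliced_cds(sub)), nchar(spliced_cds(tpl)))

  # delete 209 bp inside exon 3, re-insert the same payload at the same
  # spot: the original template must be restored exactly
  a3 <- cfg$templates$VvMybA3
  payload <- substr(a3$sequence, 1200L, 1408L)
  del <- build_allele(a3, list(variant_spec("deletion", 1200L, 209L)))
  back <- build_allele(del, list(variant_spec("insertion", 1200L, payload)))
  expect_identical(back$sequence, a3$sequence)
  expect_identical(back$exons, a3$exons)

  # an indel straddling an exon boundary is a coordinate conflict
  e3_start <- a3$exons[3L, 1L]
  expect_error(
    build_allele(a3, list(variant_spec("deletion", e3_start - 10L, 50L))),
    "coordinate conflict")
})

test_that("haplotype builders reproduce the locus architecture", {
  counts <- c(HapA = 8L, `HapC-N` = 8L, HapF1 = 8L, HapF2 = 9L,
              HapF_DEL = 3L)
  for (h in names(counts)) {
    expect_length(fx_hap(h)$genes, counts[[h]])
  }
  f2 <- fx_hap("HapF2")
  expect_true(abs(nchar(f2$sequence) - 138000L) <= 2000L)
  expect_true(all(c("VvMybA4a", "VvMybA4b") %in% names(f2$genes)))
  expect_true("VvMybA4" %in% names(fx_hap("HapF1")$genes))
  # Gret1 annotated within the VvMybA1 promoter region of HapA
  ha <- fx_hap("HapA")
  gret <- ha$te_features$Gret1
  a1 <- ha$genes$VvMybA1
  expect_true(gret$start > a1$offset &&
                gret$end <= a1$offset + nchar(a1$template$sequence))
  expect_error(build_haplotype("HapX", fx_config()))
})

test_that("HapF_DEL is an exact substring deletion removing six genes", {
  f2 <- fx_hap("HapF2")
  fd <- fx_hap("HapF_DEL")
  d <- fd$deletion
  recon <- paste0(substr(f2$sequence, 1L, d[["start"]] - 1L),
                  substr(f2$sequence, d[["end"]] + 1L,
                         nchar(f2$sequence)))
  expect_identical(recon, fd$sequence)
  expect_setequal(names(fd$genes), c("VvMybA1", "VvMybA9", "VvMybA13"))
  expect_setequal(setdiff(names(f2$genes), names(fd$genes)),
                  c("VvMybA3", "VvMybA11", "VvMybA10", "VvMybA2",
                    "VvMybA4a", "VvMybA4b"))
})

test_that("a haplotype round-trips through FASTA + GFF3", {
  fd <- fx_hap("HapF_DEL")
  fa <- withr::local_tempfile(fileext = ".fa")
  gf <- withr::local_tempfile(fileext = ".gff3")
  write_haplotype(fd, fa, gf)
  back <- read_haplotype(fa, gf)
  expect_identical(back$sequence, fd$sequence)
  cols <- c("feature", "name", "start", "end", "strand", "parent")
  orig <- fd$annotations[order(fd$annotations$start, fd$annotations$name),
                         cols]
  got <- back$annotations[order(back$annotations$start,
                                back$annotations$name), cols]
  rownames(orig) <- rownames(got) <- NULL
  expect_equal(got, orig)
})

test_that("DNA read simulation is reproducible and exact at zero error", {
  fd <- fx_hap("HapF_DEL")
  r1 <- simulate_dna_reads(fd, depth = 30, read_len = 100L,
                           error_rate = 0, seed = 7L)
  r2 <- simulate_dna_reads(fd, depth = 30, read_len = 100L,
                           error_rate = 0, seed = 7L)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), round(30 * nchar(fd$sequence) / 100))

  # every read is an exact (strand-aware) substring of its source
  idx <- seq(1L, nrow(r1), by = 17L)
  truth <- substring(fd$sequence, r1$start[idx], r1$end[idx])
  minus <- r1$strand[idx] == "-"
  truth[minus] <- vapply(truth[minus], revcomp, character(1L))
  expect_identical(r1$seq[idx], truth)

  # mean coverage approximately equals the requested depth
  cov <- nrow(r1) * 100 / nchar(fd$sequence)
  expect_lt(abs(cov - 30), 0.5)

  expect_error(simulate_dna_reads(fd, depth = 1,
                                  read_len = nchar(fd$sequence) + 1L),
               "read_len")
})

test_that("RNA read simulation follows the multinomial expectation", {
  cd <- fx_ase()$cdnas[c("VvMybA1_HapF", "VvMybA1_HapA")]
  cfg50 <- rna_sim_config(cd, c(VvMybA1_HapF = 50, VvMybA1_HapA = 50),
                          read_len = 80L, n_reads = 8000L, seed = 5L)
  reads <- simulate_rna_reads(cfg50)
  n1 <- sum(reads$hap == "VvMybA1_HapF")
  # both cDNAs are 753 bp, so expected split is 1:1
  expect_lt(abs(n1 - 4000), 3 * sqrt(8000 * 0.25))
  expect_identical(simulate_rna_reads(cfg50), reads)

  only1 <- simulate_rna_reads(
    rna_sim_config(cd, c(VvMybA1_HapF = 100, VvMybA1_HapA = 0),
                   read_len = 80L, n_reads = 500L, seed = 2L))
  expect_true(all(only1$hap == "VvMybA1_HapF"))
  expect_error(rna_sim_config(cd, c(VvMybA1_HapF = 0, VvMybA1_HapA = 0)),
               "all-zero")
})

test_that("LTR aging produces the expected divergence", {
  te0 <- make_te("fresh", ltr_len = 500L, internal_len = 300L, age = 0,
                 seed = 11L)
  l5 <- substr(te0$sequence, te0$ltr5[1L], te0$ltr5[2L])
  l3 <- substr(te0$sequence, te0$ltr3[1L], te0$ltr3[2L])
  expect_identical(l5, l3)

  # expected pairwise LTR divergence 2*mu*age = 0.01
  mu <- 1.3e-8
  age <- 0.01 / (2 * mu)
  aged <- mutate_ltr_pair(te0$sequence, te0$ltr5, te0$ltr3, age = age,
                          mu = mu, seed = 3L)
  a5 <- strsplit(substr(aged, te0$ltr5[1L], te0$ltr5[2L]), "")[[1L]]
  a3 <- strsplit(substr(aged, te0$ltr3[1L], te0$ltr3[2L]), "")[[1L]]
  p <- mean(a5 != a3)
  expect_lt(abs(p - 0.01), 3 * sqrt(0.01 * 2 / 500))
  expect_identical(
    mutate_ltr_pair(te0$sequence, te0$ltr5, te0$ltr3, age, mu, seed = 3L),
    aged)
})

test_that("locus config round-trips through YAML", {
  cfg <- fx_config()
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_locus_config(cfg, yml)
  back <- read_locus_config(yml)
  expect_identical(back$templates$VvMybA1$sequence,
                   cfg$templates$VvMybA1$sequence)
  expect_identical(back$seed, cfg$seed)
})
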