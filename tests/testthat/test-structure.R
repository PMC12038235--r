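test_that("R2R3 probe discovery recovers the configured gene counts", {
  cfg <- fx_config()
  probe <- r2r3_probe(cfg)
  expect_gte(nchar(probe), 100L)

  hits_f2 <- find_myba_genes(fx_hap("HapF2")$sequence, probe)
  expect_equal(nrow(hits_f2), 9L)
  hits_fd <- find_myba_genes(fx_hap("HapF_DEL")$sequence, probe)
  expect_equal(nrow(hits_fd), 3L)
  expect_true(all(hits_fd$strand == "+"))

  # strand symmetry: the reverse-complemented contig gives the same hits
  # on the minus strand
  rc <- find_myba_genes(revcomp(fx_hap("HapF_DEL")$sequence), probe)
  expect_equal(nrow(rc), 3L)
  expect_true(all(rc$strand == "-"))
  L <- nchar(fx_hap("HapF_DEL")$sequence)
  expect_setequal(L - rc$end + 1L, hits_fd$start)

  # no homology, no hits; empty contig, empty result
  set.seed(5)
  expect_equal(nrow(find_myba_genes(random_dna(20000L), probe)), 0L)
  expect_equal(nrow(find_myba_genes("", probe)), 0L)
})

test_that("dotplot reports diagonals, anti-diagonals and planted blocks", {
  set.seed(12)
  s <- random_dna(400L)
  d_self <- dotplot(s, s, word_size = 12L)
  diag_hits <- d_self[d_self$strand == "+" & d_self$posA == d_self$posB, ]
  expect_equal(nrow(diag_hits), 400L - 12L + 1L)

  d_rc <- dotplot(s, revcomp(s), word_size = 12L)
  # the main diagonal becomes the '-' strand anti-diagonal:
  # posA + posB = L - w + 2
  anti <- d_rc[d_rc$strand == "-" &
                 d_rc$posA + d_rc$posB == 400L - 12L + 2L, ]
  expect_equal(nrow(anti), 400L - 12L + 1L)

  # one planted shared 500-bp block at known coordinates
  block <- random_dna(500L)
  a <- paste0(random_dna(200L), block, random_dna(150L))
  b <- paste0(random_dna(320L), block, random_dna(80L))
  d <- dotplot(a, b, word_size = 16L)
  run <- d[d$strand == "+", ]
  expect_true(all(run$posA - run$posB == 200L - 320L))
  expect_equal(min(run$posA), 201L)
  expect_equal(max(run$posA), 201L + 500L - 16L)
})

test_that("structural diff locates the HapF deletion and its flanks", {
  d <- detect_structural_diff(fx_hap("HapF2"), fx_hap("HapF_DEL"))
  expect_length(d$deletions, 1L)
  del <- d$deletions[[1L]]
  expect_setequal(del$genes_contained,
                  c("VvMybA3", "VvMybA11", "VvMybA10", "VvMybA2",
                    "VvMybA4a", "VvMybA4b"))
  expect_lt(abs(del$upstream_offset - 1400L), 25L)
  expect_lt(abs(del$downstream_offset - 10800L), 25L)
  expect_lt(abs(del$length - 76000L), 2500L)

  # mirror image
  m <- detect_structural_diff(fx_hap("HapF_DEL"), fx_hap("HapF2"))
  expect_length(m$deletions, 0L)
  expect_length(m$insertions, 1L)
  expect_setequal(m$insertions[[1L]]$genes_contained, del$genes_contained)

  # identical gene complements give an empty diff
  same <- detect_structural_diff(fx_hap("HapA"), fx_hap("HapC-N"))
  expect_length(same$deletions, 0L)
  expect_length(same$insertions, 0L)

  # removing a single gene model reports exactly that gene
  fd <- fx_hap("HapF_DEL")
  pruned <- fd
  pruned$genes$VvMybA9 <- NULL
  pruned$annotations <- pruned$annotations[
    !(pruned$annotations$name %in%
        c("VvMybA9", paste0("VvMybA9_exon", 1:3))), ]
  one <- detect_structural_diff(fd, pruned)
  expect_length(one$deletions, 1L)
  expect_equal(one$deletions[[1L]]$genes_contained, "VvMybA9")
})

test_that("translation reports protein lengths and broken frames", {
  cfg <- fx_config()
  sub <- build_allele(cfg$templates$VvMybA1,
                      cfg$alleles$VvMybA1_SUB$variants)
  tr <- translate_gene(sub)
  expect_equal(tr$length, 250L)
  expect_false(tr$premature_stop)

  hapf3 <- translate_gene(build_allele(cfg$templates$VvMybA3,
                                       cfg$alleles$VvMybA3_HapF$variants))
  expect_equal(hapf3$length, 250L)

  # minimal CDS: one codon then stop
  tiny <- gene_template("tiny", "ATGTAA", rbind(c(1L, 6L)), c(1L, 1L))
  tr_tiny <- translate_gene(tiny)
  expect_equal(tr_tiny$protein, "M")
  expect_equal(tr_tiny$length, 1L)
  expect_false(tr_tiny$premature_stop)

  # the 209-bp exon-3 deletion breaks the frame
  del <- translate_gene(build_allele(cfg$templates$VvMybA3,
                                     cfg$alleles$VvMybA3del$variants))
  expect_true(del$frameshift)
  expect_true(del$premature_stop)
  expect_lt(del$length, 250L)

  bad <- gene_template("bad", "TTGTAA", rbind(c(1L, 6L)), c(1L, 1L))
  expect_error(translate_gene(bad), "ATG")
})

test_that("LTR dating matches its closed form and scales with mu", {
  set.seed(31)
  ltr <- random_dna(5000L)
  x <- strsplit(ltr, "")[[1L]]
  flip <- sample.int(5000L, 129L)       # p = 129/5000 = 0.0258 exactly
  x[flip] <- vapply(x[flip], function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1L]
  }, character(1L))
  te <- list(name = "toy", sequence = paste0(ltr, random_dna(500L),
                                             paste(x, collapse = "")),
             ltr5 = c(1L, 5000L), ltr3 = c(5501L, 10500L))
  est <- ltr_age(te, mu = 1.3e-8)
  expect_equal(est$p_raw, 0.0258, tolerance = 1e-9)
  expect_equal(est$K, -0.75 * log(1 - 4 * 0.0258 / 3), tolerance = 1e-9)
  expect_equal(est$age_years, est$K / (2 * 1.3e-8), tolerance = 1e-6)
  expect_lt(abs(est$age_years - 1.01e6), 2e4)

  # age is exactly inversely proportional to mu
  est2 <- ltr_age(te, mu = 2.6e-8)
  expect_equal(est2$age_years, est$age_years / 2, tolerance = 1e-9)

  # identical LTRs date to zero
  fresh <- make_te("fresh", ltr_len = 300L, internal_len = 200L, age = 0,
                   seed = 2L)
  est0 <- ltr_age(fresh, mu = 1.3e-8)
  expect_equal(est0$K, 0)
  expect_equal(est0$age_years, 0)

  # monotone increasing in divergence
  ages <- vapply(c(0.2e6, 0.6e6, 1.2e6), function(a) {
    aged <- make_te("m", ltr_len = 2000L, internal_len = 100L, age = a,
                    seed = 9L)
    ltr_age(aged, mu = 1.3e-8)$age_years
  }, numeric(1L))
  expect_true(all(diff(ages) > 0))

  # unrelated "LTRs" are rejected as unreliable
  set.seed(77)
  junk <- list(name = "junk", sequence = paste0(random_dna(300L),
                                                random_dna(300L)),
               ltr5 = c(1L, 300L), ltr3 = c(301L, 600L))
  expect_error(ltr_age(junk, mu = 1.3e-8), "unreliable")
})

test_that("age recovery is unbiased within Monte-Carlo error", {
  mu <- 1.3e-8
  true_age <- 0.5e6
  est <- vapply(1:20, function(s) {
    te <- make_te("rep", ltr_len = 800L, internal_len = 100L,
                  age = true_age, mu = mu, seed = 1000L + s)
    ltr_age(te, mu = mu)$age_years
  }, numeric(1L))
  expect_lt(abs(mean(est) - true_age) / true_age, 0.10)
})

test_that("pairwise identity counts matches over aligned columns", {
  set.seed(6)
  s <- random_dna(100L)
  expect_equal(pairwise_identity(s, s), 1)
  x <- strsplit(s, "")[[1L]]
  x[10L] <- setdiff(c("A", "C", "G", "T"), x[10L])[1L]
  x[60L] <- setdiff(c("A", "C", "G", "T"), x[60L])[1L]
  expect_equal(pairwise_identity(s, paste(x, collapse = "")), 0.98)
  expect_lt(pairwise_identity(random_dna(300L), random_dna(300L)), 0.6)
})

test_that("allele comparison reports each indel event", {
  cfg <- fx_config()
  sub <- build_allele(cfg$templates$VvMybA1,
                      cfg$alleles$VvMybA1_SUB$variants)
  ev <- compare_alleles(sub$sequence, cfg$templates$VvMybA1$sequence)
  ins <- ev[ev$kind == "insertion", ]
  expect_equal(sort(ins$width), c(33L, 44L, 111L))
  expect_equal(nrow(compare_alleles(sub$sequence, sub$sequence)), 0L)
})
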