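test_that("TN93 distances match the closed form and its limits", {
  set.seed(14)
  s1 <- random_dna(800L)
  s2 <- mutate_dna(s1, 0.10)
  d <- tamura_nei_distance(c(x = s1, y = s2))
  expect_equal(as.numeric(d), tn93_oracle(s1, s2), tolerance = 1e-9)

  # zero for identical sequences, symmetric by construction
  d0 <- tamura_nei_distance(c(a = s1, b = s1))
  expect_equal(as.numeric(d0), 0)
  m3 <- tamura_nei_distance(c(a = s1, b = s2, c = mutate_dna(s1, 0.05)))
  dm <- as.matrix(m3)
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), c(a = 0, b = 0, c = 0))

  # reduces to Jukes-Cantor for equal-frequency, equal-rate data
  set.seed(15)
  long1 <- random_dna(20000L, gc = 0.5)
  long2 <- mutate_dna(long1, 0.08)
  d_tn <- as.numeric(tamura_nei_distance(c(a = long1, b = long2)))
  p <- mean(strsplit(long1, "")[[1L]] != strsplit(long2, "")[[1L]])
  d_jc <- -0.75 * log(1 - 4 * p / 3)
  expect_lt(abs(d_tn - d_jc) / d_jc, 0.02)

  # saturation gives +Inf with a warning, not a silent clip
  sat1 <- strrep("AC", 200L)
  sat2 <- strrep("CA", 200L)
  expect_warning(ds <- tamura_nei_distance(c(a = sat1, b = sat2)),
                 "saturated")
  expect_true(is.infinite(as.numeric(ds)))
})

test_that("UPGMA agglomerates by average linkage onto an ultrametric", {
  # two leaves at distance d split it evenly
  d2 <- stats::as.dist(matrix(c(0, 3, 3, 0), 2L,
                              dimnames = list(c("A", "B"), c("A", "B"))))
  t2 <- upgma_tree(d2)
  expect_equal(sort(t2$edge.length), c(1.5, 1.5))

  # hand-computed three-leaf case
  d3 <- stats::as.dist(matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3L,
                              dimnames = list(c("A", "B", "C"),
                                              c("A", "B", "C"))))
  t3 <- upgma_tree(d3)
  expect_true(ape::is.ultrametric(t3, tol = 1e-9))
  ab <- ape::getMRCA(t3, c("A", "B"))
  expect_equal(unname(ape::node.depth.edgelength(t3)[1:3]), c(3, 3, 3))
  expect_equal(t3$edge.length[t3$edge[, 2L] ==
                                which(t3$tip.label == "C")], 3)
  expect_equal(t3$edge.length[t3$edge[, 2L] ==
                                which(t3$tip.label == "A")], 1)

  # any valid matrix yields an ultrametric tree with n-1 merges
  set.seed(20)
  for (i in 1:5) {
    n <- sample(4:9, 1L)
    m <- matrix(stats::runif(n * n, 0.1, 2), n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:n], letters[1:n])
    tr <- upgma_tree(stats::as.dist(m))
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    expect_equal(tr$Nnode, n - 1L)
  }
  expect_error(upgma_tree(stats::as.dist(matrix(c(0, Inf, Inf, 0), 2L))),
               "non-finite")
})

test_that("bootstrap consensus scores, collapses and roots as specified", {
  # two strongly divergent clades: both are recovered at full support
  set.seed(25)
  anc <- random_dna(600L)
  cl1 <- mutate_dna(anc, 0.3)
  cl2 <- mutate_dna(anc, 0.3)
  aln <- c(a1 = mutate_dna(cl1, 0.01), a2 = mutate_dna(cl1, 0.01),
           a3 = mutate_dna(cl1, 0.01), b1 = mutate_dna(cl2, 0.01),
           b2 = mutate_dna(cl2, 0.01), og = mutate_dna(anc, 0.45))
  tr <- bootstrap_consensus(aln, n_reps = 200L, collapse_threshold = 90,
                            outgroup = "og", seed = 4L)
  expect_true(ape::is.monophyletic(tr, c("a1", "a2", "a3")))
  expect_true(ape::is.monophyletic(tr, c("b1", "b2")))
  supports <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(supports[!is.na(supports)] >= 0 &
                    supports[!is.na(supports)] <= 100))

  # the outgroup stays attached at the root
  root_children <- tr$edge[tr$edge[, 1L] == length(tr$tip.label) + 1L, 2L]
  expect_true(which(tr$tip.label == "og") %in% root_children)

  # collapse threshold 0 keeps the point-estimate topology
  t_full <- bootstrap_consensus(aln, n_reps = 50L, collapse_threshold = 0,
                                outgroup = "og", seed = 4L)
  point <- upgma_tree(tamura_nei_distance(aln))
  expect_equal(ape::dist.topo(ape::unroot(t_full), ape::unroot(point)), 0,
               ignore_attr = TRUE)

  # fixed seed reproduces identical supports
  tr_a <- bootstrap_consensus(aln, n_reps = 100L, collapse_threshold = 90,
                              outgroup = "og", seed = 9L)
  tr_b <- bootstrap_consensus(aln, n_reps = 100L, collapse_threshold = 90,
                              outgroup = "og", seed = 9L)
  expect_identical(write_newick(tr_a), write_newick(tr_b))

  expect_error(bootstrap_consensus(aln, n_reps = 10L, outgroup = "zz"),
               "outgroup")
})

test_that("collapsing produces polytomies but preserves tip heights", {
  set.seed(26)
  anc <- random_dna(500L)
  # three nearly identical sequences: their internal resolution is noise
  aln <- c(x1 = mutate_dna(anc, 0.002), x2 = mutate_dna(anc, 0.002),
           x3 = mutate_dna(anc, 0.002), far = mutate_dna(anc, 0.3))
  tr <- bootstrap_consensus(aln, n_reps = 200L, collapse_threshold = 90,
                            seed = 7L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
})

test_that("Newick output round-trips trees including polytomies", {
  txt <- write_newick(upgma_tree(stats::as.dist(
    matrix(c(0, 1, 1, 0), 2L, dimnames = list(c("A", "B"),
                                              c("A", "B"))))))
  expect_match(txt, "^\\(.*A:0.5.*B:0.5.*\\);$")

  set.seed(30)
  for (i in 1:4) {
    tr <- ape::rtree(8L)
    back <- read_newick(text = write_newick(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-8)
  }

  poly <- read_newick(text = "((A:1,B:1,C:1):1,D:2);")
  expect_equal(poly$Nnode, 2L)
  back <- read_newick(text = write_newick(poly))
  expect_equal(back$Nnode, 2L)
})

test_that("the synthetic MybA paralog groups form supported clades", {
  aln <- myba_cds_alignment(fx_config())
  tr <- bootstrap_consensus(aln, n_reps = 500L, collapse_threshold = 90,
                            outgroup = "AtMyb75", seed = 3L)
  grp1 <- c("VvMybA1", "VvMybA2", "VvMybA3", "VvMybA9")
  grp2 <- c("VvMybA4", "VvMybA10", "VvMybA11", "VvMybA5")
  expect_true(ape::is.monophyletic(tr, grp1))
  expect_true(ape::is.monophyletic(tr, grp2))
  # VvMybA13 sits outside both groups, as its divergence dictates
  expect_false(ape::is.monophyletic(tr, c(grp1, "VvMybA13")) &&
                 ape::is.monophyletic(tr, c(grp2, "VvMybA13")))
  sup <- function(tips) {
    as.numeric(tr$node.label[ape::getMRCA(tr, tips) -
                               length(tr$tip.label)])
  }
  expect_gte(sup(grp1), 90)
  expect_gte(sup(grp2), 90)
})
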