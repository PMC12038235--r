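#' Tamura-Nei (TN93) distance matrix from a DNA alignment
#'
#' TN93 allows unequal base frequencies and distinct transition rates for
#' purines and pyrimidines. Gap handling is complete deletion per pair by
#' default (only columns ungapped in both sequences of a pair are used);
#' `gap_handling = "global"` removes every column with any gap first.
#' Saturated pairs (logarithm of a non-positive argument) are returned as
#' `+Inf` with a warning, never silently clipped.
#'
#' @param alignment Named character vector of aligned sequences, a
#'   `DNAStringSet`, or a `DNAbin` matrix.
#' @param gap_handling `"pairwise"` (default) or `"global"`.
#' @return A `dist` object of substitutions/site.
#' @export
tamura_nei_distance <- function(alignment,
                                gap_handling = c("pairwise", "global")) {
  gap_handling <- match.arg(gap_handling)
  bin <- as_dnabin(alignment)
  stopifnot(nrow(bin) >= 2L)
  d <- ape::dist.dna(bin, model = "TN93",
                     pairwise.deletion = (gap_handling == "pairwise"))
  if (anyNA(d) || any(is.nan(d))) {
    warning("saturated sequence pair(s); distance set to +Inf")
    d[is.na(d) | is.nan(d)] <- Inf
  }
  if (all(is.finite(d)) && !length(d)) stop("no shared ungapped columns")
  d
}

as_dnabin <- function(alignment) {
  if (inherits(alignment, "DNAbin")) return(as.matrix(alignment))
  if (inherits(alignment, "DNAStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  stopifnot(is.character(alignment), !is.null(names(alignment)),
            length(unique(nchar(alignment))) == 1L)
  ape::as.DNAbin(matrix(unlist(strsplit(tolower(alignment), "",
                                        fixed = TRUE), use.names = FALSE),
                        nrow = length(alignment), byrow = TRUE,
                        dimnames = list(names(alignment), NULL)))
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; node heights are half the merge distance,
#' so the tree is ultrametric. Merge ties are broken by matrix order
#' (deterministic).
#'
#' @param dm A `dist` object (finite entries).
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgma_tree <- function(dm) {
  if (any(!is.finite(dm))) stop("non-finite distances; cannot build UPGMA")
  phangorn::upgma(dm)
}

#' Bootstrap UPGMA/TN93 consensus tree
#'
#' Builds the point-estimate tree from the full alignment, resamples
#' alignment columns with replacement `n_reps` times, recomputes the tree
#' for each replicate, scores each internal branch of the point-estimate
#' tree by the percentage of replicates containing the same bipartition,
#' collapses branches under `collapse_threshold` percent into polytomies
#' (redistributing the collapsed branch length onto its children so the
#' tree stays ultrametric), and roots on the outgroup.
#'
#' @param alignment As in [tamura_nei_distance()].
#' @param n_reps Bootstrap replicates (1000 in the reference protocol).
#' @param collapse_threshold Support percentage below which branches are
#'   collapsed (90 in the reference protocol; 0 keeps the full topology).
#' @param outgroup Tip label to root on (must be in the alignment).
#' @param seed Integer seed for the resampling.
#' @param gap_handling Passed to [tamura_nei_distance()].
#' @return A `phylo` tree; `node.label` holds integer support percentages
#'   for retained internal nodes.
#' @export
bootstrap_consensus <- function(alignment, n_reps = 1000L,
                                collapse_threshold = 90,
                                outgroup = NULL, seed = 1L,
                                gap_handling = "pairwise") {
  bin <- as_dnabin(alignment)
  if (!is.null(outgroup) && !outgroup %in% rownames(bin)) {
    stop("outgroup '", outgroup, "' missing from the alignment")
  }
  build <- function(m) {
    d <- ape::dist.dna(m, model = "TN93",
                       pairwise.deletion = (gap_handling == "pairwise"))
    bad <- !is.finite(d)
    if (any(bad)) d[bad] <- 2 * max(d[!bad], 1)  # saturated resample guard
    phangorn::upgma(d)
  }
  phy <- build(bin)
  set.seed(seed)
  counts <- ape::boot.phylo(phy, bin, build, B = n_reps, rooted = TRUE,
                            quiet = TRUE)
  support <- round(100 * counts / n_reps)
  ## boot.phylo scores internal nodes in node order (root first)
  phy$node.label <- as.character(support)
  phy <- collapse_low_support(phy, support, collapse_threshold)
  if (!is.null(outgroup)) phy <- root_on_outgroup(phy, outgroup)
  phy
}

# collapse internal (non-root) edges whose child node's support is below
# the threshold; the collapsed edge length is added to the child's edges so
# root-to-tip distances are preserved
collapse_low_support <- function(phy, support, threshold) {
  if (threshold <= 0) return(phy)
  repeat {
    ntip <- length(phy$tip.label)
    root <- ntip + 1L
    supp <- stats::setNames(as.numeric(phy$node.label),
                            ntip + seq_along(phy$node.label))
    child_internal <- phy$edge[, 2L] > ntip
    weak <- which(child_internal &
                    supp[as.character(phy$edge[, 2L])] < threshold &
                    phy$edge[, 2L] != root)
    if (!length(weak)) break
    e <- weak[1L]
    node <- phy$edge[e, 2L]
    parent <- phy$edge[e, 1L]
    elen <- phy$edge.length[e]
    kids <- phy$edge[, 1L] == node
    phy$edge[kids, 1L] <- parent
    phy$edge.length[kids] <- phy$edge.length[kids] + elen
    phy$edge <- phy$edge[-e, , drop = FALSE]
    phy$edge.length <- phy$edge.length[-e]
    phy$Nnode <- phy$Nnode - 1L
    ## renumber internal nodes > `node` down by one
    adj <- function(v) ifelse(v > node, v - 1L, v)
    phy$edge <- matrix(adj(phy$edge), ncol = 2L)
    drop_idx <- node - ntip
    phy$node.label <- phy$node.label[-drop_idx]
    attr(phy, "order") <- NULL
  }
  phy
}

root_on_outgroup <- function(phy, outgroup) {
  if (ape::is.rooted(phy)) {
    og_tip <- which(phy$tip.label == outgroup)
    root <- length(phy$tip.label) + 1L
    if (phy$edge[phy$edge[, 2L] == og_tip, 1L] == root) return(phy)
  }
  ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
}

#' Is a rooted tree ultrametric?
#'
#' @param phy A `phylo` tree.
#' @param tol Absolute tolerance on root-to-tip path differences.
#' @return Logical.
#' @export
is_ultrametric_tree <- function(phy, tol = 1e-9) {
  ape::is.ultrametric(phy, tol = tol)
}

#' Write / read Newick
#'
#' Thin wrappers that keep branch lengths and integer node supports and
#' round-trip polytomies.
#'
#' @param tree A `phylo` tree.
#' @param path Optional file; when `NULL` the Newick string is returned.
#' @return `write_newick`: the Newick text (invisibly when written to a
#'   file); `read_newick`: a `phylo` tree.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' @rdname write_newick
#' @param text Newick string (alternative to `path`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
}

#' Spliced-CDS alignment of the synthetic MybA paralogs
#'
#' One representative coding sequence per gene template plus the AtMyb75
#' outgroup, on the shared 753-bp frame (the VvMybA2 duplication block is
#' excluded), ungapped -- input for the gene-family trees.
#'
#' @param config A [default_locus_config()].
#' @param genes Which templates to include (default: all nine).
#' @return Named character vector of equal-length sequences.
#' @export
myba_cds_alignment <- function(config, genes = names(config$templates)) {
  base_cds <- function(tpl) {
    cds <- spliced_cds(tpl)
    if (nchar(cds) > 753L) {        # drop the VvMybA2 282-bp duplication
      cds <- paste0(substr(cds, 1L, 750L),
                    substr(cds, nchar(cds) - 2L, nchar(cds)))
    }
    cds
  }
  out <- vapply(config$templates[genes], base_cds, character(1L))
  c(out, AtMyb75 = base_cds(config$outgroup))
}
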