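#' Fitch parsimony score of binary characters on a tree
#'
#' Standard two-pass (bottom-up counting pass) Fitch/Hartigan dynamic
#' program: each presence/absence column of the matrix is a two-state
#' character, leaves take their observed state, and each internal node adds
#' one state change whenever its children's state sets cannot be
#' intersected. Polytomies (including the basal trifurcation of unrooted
#' trees) are handled exactly by the Hartigan majority-state rule, so the
#' returned score is the minimum number of changes over all ancestral-state
#' assignments, summed over characters.
#'
#' @param tree an [ape::phylo] tree whose tip labels match the matrix taxa.
#' @param mat logical/0-1 taxa x characters matrix.
#' @return total parsimony score (integer); per-character scores in
#'   attribute `"per_character"`.
#' @export
fitch_score <- function(tree, mat) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  taxa <- rownames(mat)
  if (!setequal(tree$tip.label, taxa))
    stop("tree tip labels and matrix taxa differ")
  m <- ncol(mat)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  present <- mat[tr$tip.label, , drop = FALSE] > 0

  # state sets as two indicator matrices over nodes x characters
  has0 <- matrix(FALSE, nnode, m)
  has1 <- matrix(FALSE, nnode, m)
  has0[seq_len(ntip), ] <- !present
  has1[seq_len(ntip), ] <- present

  cnt0 <- matrix(0L, nnode, m)
  cnt1 <- matrix(0L, nnode, m)
  nchild <- tabulate(edge[, 1L], nbins = nnode)
  changes <- rep(0L, m)
  done <- logical(nnode)
  remaining <- nchild
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    if (ch > ntip && !done[ch]) stop("edge order violates postorder")
    cnt0[p, ] <- cnt0[p, ] + has0[ch, ]
    cnt1[p, ] <- cnt1[p, ] + has1[ch, ]
    remaining[p] <- remaining[p] - 1L
    if (remaining[p] == 0L) {
      K <- pmax(cnt0[p, ], cnt1[p, ])
      changes <- changes + (nchild[p] - K)
      has0[p, ] <- cnt0[p, ] == K
      has1[p, ] <- cnt1[p, ] == K
      done[p] <- TRUE
    }
  }
  total <- sum(changes)
  attr(total, "per_character") <- changes
  total
}

# tip-set bipartition keys for the internal edges of an unrooted tree,
# canonicalized so the side not containing the first taxon is reported
.bipartitions <- function(tree, taxa = sort(tree$tip.label)) {
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tr$tip.label[i]
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  keys <- character()
  for (i in seq_len(nrow(edge))) {
    ch <- edge[i, 2L]
    if (ch <= ntip) next  # trivial split
    side <- desc[[ch]]
    if (taxa[1L] %in% side) side <- setdiff(taxa, side)
    if (length(side) < 2L || length(side) > length(taxa) - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Exhaustive maximum-parsimony tree search
#'
#' Enumerates every unrooted binary topology on the matrix taxa (feasible
#' only for small panels; 9 taxa already give 135,135 topologies) and
#' returns the tree(s) of minimal Fitch parsimony score.
#'
#' @param mat logical taxa x characters matrix.
#' @param max_taxa guard on the exhaustive enumeration; larger panels need a
#'   heuristic search tool instead.
#' @return list with `trees` (a `multiPhylo` of best topologies), `score`,
#'   and `n_topologies` examined.
#' @export
exhaustive_parsimony_search <- function(mat, max_taxa = 9L) {
  taxa <- rownames(mat)
  n <- length(taxa)
  if (n < 4L) stop("need at least 4 taxa for an unrooted topology")
  if (n > max_taxa)
    stop("matrix has ", n, " taxa (> max_taxa = ", max_taxa,
         "): exhaustive enumeration infeasible, use an external ",
         "heuristic-search tool")
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  scores <- vapply(trees, function(tr) as.integer(fitch_score(tr, mat)),
                   integer(1))
  best <- which(scores == min(scores))
  out_trees <- trees[best]
  class(out_trees) <- "multiPhylo"
  list(trees = out_trees, score = min(scores), n_topologies = length(trees))
}

#' Bootstrap support for a parsimony tree
#'
#' Resamples characters (matrix columns) with replacement `n_boot` times,
#' finds the maximum-parsimony topology set of each replicate by exhaustive
#' search, and reports, for every internal bipartition of the reference
#' tree, the fraction of replicates whose best-tree set contains it.
#'
#' @param mat logical taxa x characters matrix.
#' @param reference_tree the tree to annotate (defaults to the first best
#'   tree of the full matrix).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param max_taxa passed to [exhaustive_parsimony_search()].
#' @return list with `tree` (reference tree with `node.label` supports),
#'   `support` (named numeric per bipartition), `n_boot`.
#' @export
parsimony_bootstrap <- function(mat, reference_tree = NULL, n_boot = 100L,
                                seed = 1L, max_taxa = 9L) {
  set.seed(derive_seed(seed, "bootstrap"))
  if (is.null(reference_tree))
    reference_tree <- exhaustive_parsimony_search(mat, max_taxa)$trees[[1L]]
  taxa <- sort(reference_tree$tip.label)
  ref_bip <- .bipartitions(reference_tree, taxa)
  hits <- stats::setNames(numeric(length(ref_bip)), ref_bip)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    best <- exhaustive_parsimony_search(mat[, cols, drop = FALSE],
                                        max_taxa)$trees
    seen <- unique(unlist(lapply(best, .bipartitions, taxa = taxa)))
    hits[ref_bip %in% seen] <- hits[ref_bip %in% seen] + 1
  }
  support <- hits / n_boot
  tree <- .attach_support(reference_tree, support, taxa)
  list(tree = tree, support = support, n_boot = n_boot)
}

# write supports as node labels on the internal node of each bipartition
.attach_support <- function(tree, support, taxa) {
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  desc <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tr$tip.label[i]
  labels <- rep("", tr$Nnode)
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
    if (ch > ntip) {
      side <- desc[[ch]]
      if (taxa[1L] %in% side) side <- setdiff(taxa, side)
      key <- paste(sort(side), collapse = "|")
      if (key %in% names(support))
        labels[ch - ntip] <- format(support[[key]], digits = 3)
    }
  }
  tr$node.label <- labels
  tr
}
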