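#' Phyletic category definitions
#'
#' Categories are mutually exclusive and exhaustive, assigned by precedence
#' from broadest to narrowest: an ortholog present in at least the threshold
#' fraction of every defining group of a category receives the first category
#' it satisfies. `Other` collects orthologs meeting no definition.
#'
#' @return named list mapping category to its defining taxon groups.
#' @export
category_definitions <- function() {
  list(Universal = c("Bacteria", "Archaea", "Eukarya"),
       EA = c("Eukarya", "Archaea"),
       Archaea = "Archaea",
       TACK = "TACK",
       Sulfolobales = "Sulfolobales",
       Other = character())
}

.complete_groups <- function(taxon_groups) {
  if (is.null(taxon_groups$Archaea))
    taxon_groups$Archaea <- unique(c(taxon_groups$Euryarchaeota,
                                     taxon_groups$TACK))
  lens <- lengths(taxon_groups[c("Bacteria", "Archaea", "TACK",
                                 "Sulfolobales", "Eukarya")])
  if (any(lens == 0L))
    stop("empty taxon group(s): ",
         paste(names(lens)[lens == 0L], collapse = ", "))
  taxon_groups
}

#' Assign phyletic categories to ortholog presence profiles
#'
#' An ortholog is placed in a category iff its presence fraction is at least
#' `threshold` in *each* of the category's defining groups; categories are
#' tested broad to narrow (Universal, EA, Archaea, TACK, Sulfolobales) and
#' the first match wins, so e.g. a gene in most Sulfolobales *and* most of
#' all three domains is Universal. Orthologs matching nothing are `Other`.
#'
#' @param mat logical taxa x orthologs matrix (or a single named logical /
#'   0-1 presence vector for one ortholog).
#' @param taxon_groups named list of taxa per group; an `Archaea` group is
#'   derived as Euryarchaeota + TACK when absent.
#' @param threshold required presence fraction per defining group.
#' @return character vector of categories (one per ortholog column).
#' @export
assign_category <- function(mat, taxon_groups, threshold = 0.5) {
  if (is.vector(mat)) mat <- matrix(mat, ncol = 1,
                                    dimnames = list(names(mat), "ortholog"))
  taxon_groups <- .complete_groups(taxon_groups)
  defs <- category_definitions()
  taxa <- rownames(mat)
  if (is.null(taxa)) stop("presence matrix must have taxon rownames")
  frac <- function(group) {
    members <- intersect(taxon_groups[[group]], taxa)
    if (!length(members)) stop("empty taxon group: ", group)
    colSums(mat[members, , drop = FALSE]) / length(members)
  }
  group_frac <- vapply(c("Bacteria", "Archaea", "Eukarya", "TACK",
                         "Sulfolobales"),
                       frac, numeric(ncol(mat)))
  if (ncol(mat) == 1L) group_frac <- matrix(group_frac, nrow = 1,
                                            dimnames = list(NULL,
                                              c("Bacteria", "Archaea",
                                                "Eukarya", "TACK",
                                                "Sulfolobales")))
  out <- rep("Other", ncol(mat))
  for (cat in rev(setdiff(names(defs), "Other"))) {
    ok <- rep(TRUE, ncol(mat))
    for (g in defs[[cat]]) ok <- ok & group_frac[, g] >= threshold
    out[ok] <- cat
  }
  stats::setNames(out, colnames(mat))
}

#' Per-category ortholog counts for gene sets
#'
#' @param mat logical taxa x orthologs matrix.
#' @param taxon_groups named list of taxa per group.
#' @param sets named list of ortholog-id character vectors (e.g. `all`,
#'   `essential`, `poorly_characterized`); unknown ids raise an error.
#' @param threshold presence-fraction threshold.
#' @return integer matrix categories x sets; each column sums to its set
#'   size.
#' @export
category_counts <- function(mat, taxon_groups,
                            sets = list(all = colnames(mat)),
                            threshold = 0.5) {
  cats <- assign_category(mat, taxon_groups, threshold)
  lev <- names(category_definitions())
  out <- sapply(sets, function(ids) {
    unknown <- setdiff(ids, colnames(mat))
    if (length(unknown))
      stop("unknown ortholog id(s): ", paste(unknown, collapse = ", "))
    table(factor(cats[ids], levels = lev))
  })
  out <- matrix(out, nrow = length(lev),
                dimnames = list(lev, names(sets)))
  storage.mode(out) <- "integer"
  out
}

# redraw each ortholog's carrier taxa uniformly without replacement,
# preserving its presence count exactly
.permute_preserving_counts <- function(m) {
  k <- colSums(m)
  n_taxa <- nrow(m)
  perm <- m
  for (j in seq_len(ncol(m))) {
    col <- logical(n_taxa)
    if (k[j] > 0L) col[sample.int(n_taxa, k[j])] <- TRUE
    perm[, j] <- col
  }
  perm
}

#' Permutation null for phyletic category counts
#'
#' For each ortholog, its number of carrier taxa is held fixed while the
#' carriers are redrawn uniformly without replacement; categories and
#' per-category counts are recomputed for each of `n_perm` replicates.
#' One-sided empirical p-values use the literal fraction of replicates at or
#' beyond the observed count, with denominator exactly `n_perm`.
#'
#' @param mat logical taxa x orthologs matrix.
#' @param taxon_groups named list of taxa per group.
#' @param ortholog_ids optional subset of columns to analyse (default all).
#' @param n_perm number of permutation replicates.
#' @param seed integer seed.
#' @param threshold presence-fraction threshold.
#' @return an object of class `"permutation_null"`: list with `observed`
#'   (per-category counts), `simulated` (n_perm x categories matrix),
#'   `p_above` (fraction of replicates with count >= observed), `p_below`,
#'   `n_perm`, `seed`.
#' @export
permutation_null <- function(mat, taxon_groups, ortholog_ids = colnames(mat),
                             n_perm = 100L, seed = 1L, threshold = 0.5) {
  stopifnot(n_perm >= 1L)
  set.seed(derive_seed(seed, "permutation_null"))
  m <- mat[, ortholog_ids, drop = FALSE]
  lev <- names(category_definitions())
  observed <- table(factor(assign_category(m, taxon_groups, threshold),
                           levels = lev))
  sim <- matrix(0L, n_perm, length(lev), dimnames = list(NULL, lev))
  for (r in seq_len(n_perm)) {
    perm <- .permute_preserving_counts(m)
    sim[r, ] <- table(factor(assign_category(perm, taxon_groups, threshold),
                             levels = lev))
  }
  obs <- as.vector(observed)
  names(obs) <- lev
  structure(list(observed = obs,
                 simulated = sim,
                 p_above = colSums(sweep(sim, 2L, obs, `>=`)) / n_perm,
                 p_below = colSums(sweep(sim, 2L, obs, `<=`)) / n_perm,
                 n_perm = n_perm, seed = seed),
            class = "permutation_null")
}

#' Cross-organism shared/essential crosstab
#'
#' For each phyletic category, counts how many focal essential genes have an
#' ortholog present in another organism ("shared") and how many of those
#' orthologs are themselves essential there ("essential").
#'
#' @param categories named character vector: focal gene id -> category.
#' @param ortholog_map data.frame with columns `focal_id`, `other_id`; a
#'   focal gene is shared iff it appears here with a non-NA `other_id`.
#' @param other_essential_ids character vector of the other organism's
#'   essential gene ids.
#' @return integer matrix with rows `shared` and `essential`, one column per
#'   category (plus `total`); `essential <= shared` everywhere.
#' @export
shared_essential_crosstab <- function(categories, ortholog_map,
                                      other_essential_ids = character()) {
  lev <- names(category_definitions())
  map <- ortholog_map[!is.na(ortholog_map$other_id), , drop = FALSE]
  shared_ids <- intersect(names(categories), map$focal_id)
  ess_ids <- shared_ids[vapply(shared_ids, function(id)
    any(map$other_id[map$focal_id == id] %in% other_essential_ids),
    logical(1))]
  shared <- table(factor(categories[shared_ids], levels = lev))
  ess <- table(factor(categories[ess_ids], levels = lev))
  out <- rbind(shared = as.vector(shared), essential = as.vector(ess))
  colnames(out) <- lev
  cbind(out, total = c(length(shared_ids), length(ess_ids)))
}

#' Proportional subsampling of a presence/absence matrix
#'
#' Draws `n_sets` taxon subsamples, each containing `group_counts[g]` taxa
#' sampled without replacement from group `g`, to test whether category
#' counts are robust to the taxon panel composition.
#'
#' @param mat logical taxa x orthologs matrix.
#' @param taxon_groups named list of taxa per group.
#' @param group_counts named integer vector: taxa to draw per (disjoint)
#'   group.
#' @param n_sets number of subsampled matrices.
#' @param seed integer seed.
#' @return list of `n_sets` presence/absence matrices.
#' @export
subsample_matrix <- function(mat, taxon_groups, group_counts, n_sets = 100L,
                             seed = 1L) {
  set.seed(derive_seed(seed, "subsample"))
  for (g in names(group_counts)) {
    avail <- intersect(taxon_groups[[g]], rownames(mat))
    if (length(avail) < group_counts[[g]])
      stop("not enough taxa in group ", g, ": have ", length(avail),
           ", need ", group_counts[[g]])
  }
  lapply(seq_len(n_sets), function(i) {
    taxa <- unlist(lapply(names(group_counts), function(g)
      sample(intersect(taxon_groups[[g]], rownames(mat)),
             group_counts[[g]])), use.names = FALSE)
    mat[taxa, , drop = FALSE]
  })
}
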