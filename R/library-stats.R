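#' Colonies required for saturating mutagenesis
#'
#' Poisson saturation planning: the number of independent insertion mutants
#' needed so that a random insertion hits an average-size gene with
#' probability `P` is `N = ln(1 - P) / ln(1 - f)` with
#' `f = avg_gene_size / genome_size`. Rounded up — fractional colonies cannot
#' be plated.
#'
#' @param P target coverage probability, in `[0, 1)`.
#' @param avg_gene_size average gene length in bp.
#' @param genome_size genome length in bp.
#' @return integer number of colonies.
#' @export
required_colonies <- function(P, avg_gene_size, genome_size) {
  if (!is.numeric(P) || P < 0 || P >= 1) stop("P must be in [0, 1)")
  f <- avg_gene_size / genome_size
  if (f <= 0 || f >= 1) stop("avg_gene_size/genome_size must be in (0, 1)")
  as.integer(ceiling(log(1 - P) / log(1 - f)))
}

#' Insertion density summary of a library union
#'
#' @param events insertion event data.frame (already read-count filtered), or
#'   a single count of unique events.
#' @param genome_length genome size in bp.
#' @param avg_gene_size average gene length in bp used to express expected
#'   insertions per gene.
#' @return list: `n_unique`, `mean_spacing_bp` (= genome_length / n_unique),
#'   `expected_insertions_per_gene`.
#' @export
insertion_density <- function(events, genome_length, avg_gene_size = 900.64) {
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  if (n < 1) stop("need at least one insertion event")
  spacing <- genome_length / n
  list(n_unique = n,
       mean_spacing_bp = spacing,
       expected_insertions_per_gene = avg_gene_size / spacing)
}

#' Monte-Carlo check of gene coverage at a given library size
#'
#' Places `n_colonies` insertions uniformly on the genome `reps` times and
#' reports the mean (+/- sd) fraction of genes hit at least once, alongside
#' the analytic expectation `mean over genes of 1 - (1 - L_g/G)^N`.
#'
#' @param n_colonies insertions per replicate.
#' @param genes gene data.frame (`start`, `end`).
#' @param genome_length genome size in bp.
#' @param reps number of Monte-Carlo replicates.
#' @param seed integer seed.
#' @return list: `mean_fraction`, `sd_fraction`, `sd_of_mean`,
#'   `analytic_fraction`, `reps`.
#' @export
coverage_simulation <- function(n_colonies, genes, genome_length,
                                reps = 200L, seed = 1L) {
  stopifnot(reps >= 1L)
  set.seed(derive_seed(seed, "coverage"))
  G <- nrow(genes)
  if (n_colonies == 0L) {
    return(list(mean_fraction = 0, sd_fraction = 0, sd_of_mean = 0,
                analytic_fraction = 0, reps = reps))
  }
  # map positions to genes via interval lookup on sorted, non-overlapping genes
  o <- order(genes$start)
  starts <- genes$start[o]
  ends <- genes$end[o]
  frac <- numeric(reps)
  for (r in seq_len(reps)) {
    pos <- sample.int(genome_length, n_colonies, replace = TRUE)
    idx <- findInterval(pos, starts)
    hit <- idx >= 1L & pos <= ends[pmax(idx, 1L)]
    frac[r] <- length(unique(idx[hit])) / G
  }
  lens <- genes$end - genes$start + 1
  analytic <- mean(1 - (1 - lens / genome_length)^n_colonies)
  list(mean_fraction = mean(frac), sd_fraction = stats::sd(frac),
       sd_of_mean = stats::sd(frac) / sqrt(reps),
       analytic_fraction = analytic, reps = reps)
}

#' Nucleotide composition bias profile around insertion sites
#'
#' Extracts the `flank` bases on each side of every insertion junction
#' (reverse-complemented for minus-strand events so offset 0 is always the
#' junction-proximal base in insertion orientation), stacks them, and
#' compares per-offset nucleotide frequencies against (a) an equal number of
#' uniformly drawn random sites (with replacement) and (b) the overall genome
#' composition. Normalized enrichment is site frequency over genome
#' background. The profile flags whether any single offset is more than
#' two-fold enriched in any base.
#'
#' @param events insertion event data.frame (`position`, `strand`).
#' @param genome a [Biostrings::DNAString] or character scalar.
#' @param flank bases examined on each side of the junction.
#' @param seed seed for the random control.
#' @return an object of class `"bias_profile"`: list with `offsets`
#'   (-flank..flank), `site_freq`, `control_freq` (offset x base matrices),
#'   `background_freq` (per base), `enrichment`, `control_enrichment`,
#'   `max_enrichment`, `two_fold_flag`, `n_sites_used`, `n_dropped`.
#' @export
site_bias_profile <- function(events, genome, flank = 20L, seed = 1L) {
  stopifnot(flank >= 1L)
  seqc <- as.character(genome)
  L <- nchar(seqc)
  if (L < 2L * flank + 1L) stop("genome shorter than 2*flank + 1")
  set.seed(derive_seed(seed, "bias_control"))
  chars <- strsplit(seqc, "")[[1]]
  bases <- c("A", "C", "G", "T")
  bg <- table(factor(chars, levels = bases))
  bg <- as.vector(bg) / sum(bg)
  names(bg) <- bases

  complete <- events$position > flank & events$position <= L - flank
  n_dropped <- sum(!complete)
  ev <- events[complete, , drop = FALSE]
  if (!nrow(ev)) stop("no insertion site has complete flanks")

  offsets <- -flank:flank
  stack_freq <- function(pos, strand) {
    idx <- outer(pos, offsets, `+`)
    m <- matrix(chars[idx], nrow = length(pos))
    minus <- strand == "-"
    if (any(minus)) {
      # reverse-complement orientation: flip offsets and complement bases
      m[minus, ] <- chartr("ACGT", "TGCA", m[minus, ncol(m):1, drop = FALSE])
    }
    freq <- apply(m, 2L, function(col)
      as.vector(table(factor(col, levels = bases))) / length(col))
    t(freq)  # offsets x bases
  }
  site_freq <- stack_freq(ev$position, ev$strand)
  ctrl_pos <- sample.int(L - 2L * flank, nrow(ev), replace = TRUE) + flank
  control_freq <- stack_freq(ctrl_pos, rep("+", length(ctrl_pos)))
  dimnames(site_freq) <- dimnames(control_freq) <- list(offsets, bases)
  enrichment <- sweep(site_freq, 2L, bg, `/`)
  control_enrichment <- sweep(control_freq, 2L, bg, `/`)
  structure(list(offsets = offsets, site_freq = site_freq,
                 control_freq = control_freq, background_freq = bg,
                 enrichment = enrichment,
                 control_enrichment = control_enrichment,
                 max_enrichment = max(enrichment),
                 two_fold_flag = any(enrichment > 2),
                 n_sites_used = nrow(ev), n_dropped = n_dropped),
            class = "bias_profile")
}

#' G+C enrichment at a given offset of a bias profile
#'
#' @param profile a `"bias_profile"`.
#' @param offset junction-relative offset (0 = junction base).
#' @return the ratio of site G+C frequency to background G+C at that offset.
#' @export
gc_enrichment_at <- function(profile, offset = 0L) {
  i <- match(offset, profile$offsets)
  if (is.na(i)) stop("offset outside the profiled window")
  sum(profile$site_freq[i, c("C", "G")]) /
    sum(profile$background_freq[c("C", "G")])
}
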