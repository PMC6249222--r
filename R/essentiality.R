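#' Scoring configuration for per-gene essentiality calls
#'
#' @param head_trim proportion of the gene trimmed at the translation start
#'   (5' end), tolerating misannotated start codons.
#' @param tail_trim proportion trimmed at the 3' end, tolerating dispensable
#'   C-termini.
#' @param pseudocount reads added to observed and expected before the log
#'   ratio, avoiding minus infinity.
#' @param log2fc_cutoff genes with log2FC at or below this value meet the
#'   fold-change criterion.
#' @param ei_cutoff exclusive upper bound on the essentiality index: genes
#'   with `EI < ei_cutoff` meet the insertion-count criterion.
#' @param repeat_na_fraction genes with a larger repeat-masked fraction get an
#'   NA score (reads cannot be attributed uniquely).
#' @param min_reads_union minimum read count for an event to enter the pooled
#'   table used for fold-change scoring.
#' @param min_reads_scoring minimum read count for an insertion site to count
#'   toward the essentiality index.
#' @param manual_overrides named character vector `gene_id -> call` applied
#'   after automatic classification (e.g. removing genes whose depletion is a
#'   read-mapping artefact, or genes shown dispensable by targeted knockout).
#' @return an object of class `"scoring_config"`.
#' @export
scoring_config <- function(head_trim = 0.05,
                           tail_trim = 0.20,
                           pseudocount = 1,
                           log2fc_cutoff = -5.1,
                           ei_cutoff = 4L,
                           repeat_na_fraction = 0.5,
                           min_reads_union = 3L,
                           min_reads_scoring = 4L,
                           manual_overrides = character()) {
  .assert_scalar_prob(head_trim, "head_trim")
  .assert_scalar_prob(tail_trim, "tail_trim")
  if (head_trim + tail_trim >= 1)
    stop("head_trim + tail_trim must be < 1")
  if (ei_cutoff < 1L) stop("ei_cutoff must be >= 1")
  structure(list(head_trim = head_trim, tail_trim = tail_trim,
                 pseudocount = pseudocount, log2fc_cutoff = log2fc_cutoff,
                 ei_cutoff = as.integer(ei_cutoff),
                 repeat_na_fraction = repeat_na_fraction,
                 min_reads_union = as.integer(min_reads_union),
                 min_reads_scoring = as.integer(min_reads_scoring),
                 manual_overrides = manual_overrides),
            class = "scoring_config")
}

#' Trimmed gene body
#'
#' Returns the interval of each gene left after excluding the first
#' `head_trim` (default 5%) and last `tail_trim` (default 20%) of its length.
#' Trimming is strand-aware: the "first" fraction is always at the
#' translation start, i.e. the left end for `+` genes and the right end for
#' `-` genes. Intervals are 1-based inclusive.
#'
#' @param genes data.frame with `start`, `end`, `strand` (and optionally
#'   `gene_id`).
#' @param cfg a [scoring_config()].
#' @return data.frame with columns `gene_id` (if present), `start`, `end` of
#'   the trimmed bodies. Genes shorter than 4 bp are returned untrimmed with
#'   a warning.
#' @export
trimmed_body <- function(genes, cfg = scoring_config()) {
  stopifnot(all(genes$start <= genes$end))
  L <- genes$end - genes$start + 1L
  h <- as.integer(round(cfg$head_trim * L))
  t <- as.integer(round(cfg$tail_trim * L))
  plus <- genes$strand != "-"
  start <- ifelse(plus, genes$start + h, genes$start + t)
  end <- ifelse(plus, genes$end - t, genes$end - h)
  degenerate <- L < 4L
  if (any(degenerate)) {
    warning(sum(degenerate), " gene(s) shorter than 4 bp returned untrimmed")
    start[degenerate] <- genes$start[degenerate]
    end[degenerate] <- genes$end[degenerate]
  }
  out <- data.frame(start = as.integer(start), end = as.integer(end))
  if (!is.null(genes$gene_id)) out <- cbind(gene_id = genes$gene_id, out)
  out
}

# Pool events and return, per gene, indices of events inside its trimmed body.
.events_in_bodies <- function(events, genes, cfg) {
  tb <- trimmed_body(genes, cfg)
  q <- IRanges::IRanges(start = events$position, width = 1L)
  s <- IRanges::IRanges(start = tb$start, end = tb$end)
  IRanges::findOverlaps(q, s)
}

#' Essentiality index (EI): distinct insertion sites in the trimmed gene body
#'
#' Counts distinct (position, strand) insertion sites falling inside each
#' gene's trimmed body, pooling libraries. Sites supported by fewer than
#' `min_reads_scoring` reads (default 4) should be filtered out by the caller
#' (see [filter_by_reads()]); [score_genes()] does this automatically.
#' The index is monotone non-decreasing in the event set.
#'
#' @param events insertion event data.frame (`position`, `strand`, ...).
#' @param genes gene data.frame.
#' @param cfg a [scoring_config()].
#' @return integer vector of EI values, one per gene (named by `gene_id` when
#'   available).
#' @export
compute_ei <- function(events, genes, cfg = scoring_config()) {
  ei <- integer(nrow(genes))
  if (nrow(events)) {
    sites <- unique(events[, c("position", "strand")])
    hits <- .events_in_bodies(sites, genes, cfg)
    tab <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(genes))
    ei <- as.integer(tab)
  }
  if (!is.null(genes$gene_id)) names(ei) <- genes$gene_id
  ei
}

#' log2 fold change of observed over expected reads per gene
#'
#' For each gene, observed reads are the summed read counts of all events in
#' its trimmed body (all libraries pooled); expected reads assume a uniform
#' read density over the genome: `total_reads * trimmed_length /
#' genome_length`. The score is `log2((obs + pc) / (exp + pc))` with
#' pseudocount `pc` (default 1). Genes with
#' `repeat_masked_fraction > repeat_na_fraction` get NA: reads mapping to
#' repeated sequence cannot be attributed to one locus and spuriously deplete
#' the gene.
#'
#' @param events insertion event data.frame with `position` and `read_count`.
#' @param genes gene data.frame (optionally with `repeat_masked_fraction`).
#' @param genome_length genome size in bp.
#' @param cfg a [scoring_config()].
#' @return named numeric vector of log2FC values (NA for repeat-masked genes).
#' @export
compute_log2fc <- function(events, genes, genome_length,
                           cfg = scoring_config()) {
  stopifnot(genome_length > 0)
  total <- sum(events$read_count)
  obs <- numeric(nrow(genes))
  if (nrow(events)) {
    hits <- .events_in_bodies(events, genes, cfg)
    agg <- tapply(events$read_count[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), sum)
    obs[as.integer(names(agg))] <- agg
  }
  tb <- trimmed_body(genes, cfg)
  expd <- total * (tb$end - tb$start + 1) / genome_length
  pc <- cfg$pseudocount
  lfc <- log2((obs + pc) / (expd + pc))
  if (total == 0) {
    warning("zero total reads: all log2FC set to NA")
    lfc[] <- NA_real_
  }
  rmf <- genes$repeat_masked_fraction %||% rep(0, nrow(genes))
  lfc[!is.na(rmf) & rmf > cfg$repeat_na_fraction] <- NA_real_
  stats::setNames(lfc, genes$gene_id)
}

#' Repeat-uniqueness mask of a genome
#'
#' Marks every base covered by a k-mer (default k = 50) that occurs two or
#' more times in the genome, counting forward and reverse-complement
#' occurrences as the same k-mer. Reads of length ~k mapping inside masked
#' regions are ambiguous, so genes overlapping them should not be scored.
#'
#' @param genome a [Biostrings::DNAString] or character scalar.
#' @param k k-mer length in bp.
#' @return logical vector (length = genome length): TRUE where masked.
#' @export
uniqueness_mask <- function(genome, k = 50L) {
  seqc <- as.character(genome)
  L <- nchar(seqc)
  if (k > L) stop("k must not exceed the genome length")
  n <- L - k + 1L
  starts <- seq_len(n)
  fwd <- substring(seqc, starts, starts + k - 1L)
  rcseq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqc)))
  rc_k <- substring(rcseq, starts, starts + k - 1L)
  # revcomp of the k-mer at position i is the rc-genome k-mer at n - i + 1
  canon <- pmin(fwd, rev(rc_k))
  dup <- canon %in% canon[duplicated(canon)]
  mask <- logical(L)
  if (any(dup)) {
    r <- IRanges::reduce(IRanges::IRanges(start = starts[dup], width = k))
    for (i in seq_along(r)) {
      mask[IRanges::start(r)[i]:IRanges::end(r)[i]] <- TRUE
    }
  }
  mask
}

#' Fraction of each gene covered by a mask
#'
#' @param mask logical per-base mask (from [uniqueness_mask()]).
#' @param genes gene data.frame with `start`, `end`.
#' @return numeric vector of masked fractions, one per gene.
#' @export
masked_fraction <- function(mask, genes) {
  cm <- c(0, cumsum(mask))
  (cm[genes$end + 1L] - cm[genes$start]) / (genes$end - genes$start + 1L)
}

#' Detect the valley between bimodal score distributions
#'
#' Fits a Gaussian kernel density (Silverman's rule-of-thumb bandwidth,
#' 512-point grid) to the finite scores and returns the grid argmin of the
#' density between the two highest local maxima — the natural cutoff
#' separating the essential (low) and non-essential (high) score modes.
#'
#' @param scores numeric scores; NAs and infinities are dropped.
#' @param mode cutoff mode; only `"lower_valley"` is defined.
#' @return list with `cutoff`, `modes` (the two mode locations, ascending),
#'   and `density` (the [stats::density] fit). Errors with "no bimodality"
#'   when the density has no interior minimum between two maxima.
#' @export
find_cutoff <- function(scores, mode = c("lower_valley")) {
  mode <- match.arg(mode)
  x <- scores[is.finite(scores)]
  if (length(x) < 50L) stop("need at least 50 finite scores")
  if (stats::sd(x) == 0) stop("no bimodality: all scores identical")
  d <- stats::density(x, bw = "nrd0", n = 512L)
  y <- d$y
  ddy <- diff(sign(diff(y)))
  maxima <- which(ddy == -2) + 1L
  if (y[1] > y[2]) maxima <- c(1L, maxima)
  if (y[512] > y[511]) maxima <- c(maxima, 512L)
  if (length(maxima) < 2L)
    stop("no bimodality: density has fewer than two local maxima")
  top2 <- sort(maxima[order(y[maxima], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  valley <- between[which.min(y[between])]
  if (valley == top2[1] || valley == top2[2])
    stop("no bimodality: no interior minimum between the two main modes")
  # prominence guard: sampling wiggles of a unimodal density produce shallow
  # spurious maxima; a genuine inter-mode valley must dip well below the
  # smaller of the two peaks
  if (y[valley] > 0.8 * min(y[top2]))
    stop("no bimodality: valley is not prominent relative to the modes")
  list(cutoff = d$x[valley], modes = d$x[top2], density = d)
}

#' Consensus essentiality classification
#'
#' Applies the dual-score consensus: a gene is called `essential` only when it
#' meets both criteria (`log2FC <= log2fc_cutoff` and `EI < ei_cutoff`),
#' `non_essential` when it meets neither, and `unassigned` when it meets
#' exactly one — the conservative treatment of one-criterion candidates.
#' Genes with NA log2FC (repeat-masked) are called `NA`. Manual overrides are
#' applied last and reported separately.
#'
#' @param genes gene data.frame.
#' @param log2fc named numeric vector from [compute_log2fc()].
#' @param ei named integer vector from [compute_ei()].
#' @param cfg a [scoring_config()]; `cfg$manual_overrides` is a named vector
#'   `gene_id -> call`.
#' @return data.frame of class `"gene_scores"`: `gene_id`, `log2FC`, `EI`,
#'   `call`, `overridden` (logical).
#' @export
classify <- function(genes, log2fc, ei, cfg = scoring_config()) {
  ids <- genes$gene_id
  lfc <- log2fc[ids]
  e <- ei[ids]
  meets_lfc <- !is.na(lfc) & lfc <= cfg$log2fc_cutoff
  meets_ei <- e < cfg$ei_cutoff
  call <- ifelse(is.na(lfc), NA_character_,
          ifelse(meets_lfc & meets_ei, "essential",
          ifelse(!meets_lfc & !meets_ei, "non_essential", "unassigned")))
  overridden <- rep(FALSE, length(ids))
  ov <- cfg$manual_overrides
  if (length(ov)) {
    unknown <- setdiff(names(ov), ids)
    if (length(unknown))
      stop("manual override for unknown gene(s): ",
           paste(unknown, collapse = ", "))
    idx <- match(names(ov), ids)
    call[idx] <- unname(ov)
    overridden[idx] <- TRUE
  }
  out <- data.frame(gene_id = ids, log2FC = unname(lfc), EI = unname(e),
                    call = call, overridden = overridden,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_scores", "data.frame")
  out
}

#' Score all genes from an insertion table
#'
#' Convenience wrapper running the full per-gene scoring: the pooled event
#' table is filtered at `min_reads_union` (default 3 reads) for fold-change
#' scoring and at `min_reads_scoring` (default 4 reads) for the essentiality
#' index, then [classify()] produces the consensus call.
#'
#' @param events insertion event data.frame (all libraries).
#' @param genes gene data.frame.
#' @param genome_length genome size in bp.
#' @param cfg a [scoring_config()].
#' @return a `"gene_scores"` data.frame with additional columns
#'   `observed_reads` and `expected_reads`.
#' @export
score_genes <- function(events, genes, genome_length, cfg = scoring_config()) {
  ev_union <- filter_by_reads(events, cfg$min_reads_union)
  ev_ei <- filter_by_reads(events, cfg$min_reads_scoring)
  lfc <- compute_log2fc(ev_union, genes, genome_length, cfg)
  ei <- compute_ei(ev_ei, genes, cfg)
  scores <- classify(genes, lfc, ei, cfg)
  tb <- trimmed_body(genes, cfg)
  obs <- numeric(nrow(genes))
  if (nrow(ev_union)) {
    hits <- .events_in_bodies(ev_union, genes, cfg)
    agg <- tapply(ev_union$read_count[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), sum)
    obs[as.integer(names(agg))] <- agg
  }
  scores$observed_reads <- obs
  scores$expected_reads <-
    sum(ev_union$read_count) * (tb$end - tb$start + 1) / genome_length
  scores[, c("gene_id", "observed_reads", "expected_reads", "log2FC", "EI",
             "call", "overridden")]
}

#' Summarize a consensus partition
#'
#' @param scores a `"gene_scores"` data.frame.
#' @return named integer vector with counts of essential, unassigned,
#'   non_essential and NA calls; sums to the number of genes.
#' @export
partition_counts <- function(scores) {
  calls <- factor(ifelse(is.na(scores$call), "NA", scores$call),
                  levels = c("essential", "unassigned", "non_essential", "NA"))
  table(calls)
}
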