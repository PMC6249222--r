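#' Read-filtering configuration
#'
#' Thresholds for junction-read preprocessing and insertion extraction:
#' reads shorter than `min_read_length`, with summary Phred quality below
#' `min_mean_quality`, or lacking an exact match to the transposon end
#' sequence are discarded; alignments shorter than `min_alignment_length` or
#' multi-mapping are set aside.
#'
#' @param min_read_length minimum read length in bp.
#' @param min_mean_quality minimum per-read Phred quality.
#' @param quality_summary how "read quality" is summarized: `"mean"`
#'   (default) or `"min"` over bases.
#' @param transposon_tag transposon end sequence that must occur verbatim in
#'   a kept read (default: a 19-bp mosaic-end inverted repeat plus 4 junction
#'   bases, 23 bp total).
#' @param min_alignment_length minimum reference-aligned length in bp.
#' @param mapq_min minimum mapping quality; lower values mark a read
#'   multi-mapping.
#' @param min_reads_union minimum reads for an event to count in
#'   library-level statistics.
#' @param min_reads_scoring minimum reads for an insertion site to enter
#'   essentiality-index scoring.
#' @return an object of class `"filter_config"`.
#' @export
filter_config <- function(min_read_length = 50L,
                          min_mean_quality = 30,
                          quality_summary = c("mean", "min"),
                          transposon_tag = "CTGTCTCTTATACACATCTGACG",
                          min_alignment_length = 11L,
                          mapq_min = 2L,
                          min_reads_union = 3L,
                          min_reads_scoring = 4L) {
  if (!nzchar(transposon_tag)) stop("transposon_tag must be non-empty")
  stopifnot(min_read_length >= 0, min_mean_quality >= 0,
            min_alignment_length >= 0)
  structure(list(min_read_length = as.integer(min_read_length),
                 min_mean_quality = min_mean_quality,
                 quality_summary = match.arg(quality_summary),
                 transposon_tag = toupper(transposon_tag),
                 min_alignment_length = as.integer(min_alignment_length),
                 mapq_min = as.integer(mapq_min),
                 min_reads_union = as.integer(min_reads_union),
                 min_reads_scoring = as.integer(min_reads_scoring)),
            class = "filter_config")
}

.phred_scores <- function(quality) {
  lapply(strsplit(quality, ""), function(ch) utf8ToInt(paste(ch, collapse = "")) - 33L)
}

#' Preprocess junction reads
#'
#' Keeps a read iff (1) its length is at least `min_read_length`, (2) its
#' summary Phred quality is at least `min_mean_quality`, and (3) it contains
#' the transposon tag as an exact substring. Kept reads are trimmed: the tag
#' and everything 5' of it are removed, leaving genomic sequence only.
#' Rejection reasons are tallied with precedence length > quality > no_tag
#' (each rejected read is counted once).
#'
#' @param reads data.frame with columns `id`, `sequence`, `quality`
#'   (Phred+33 strings), e.g. from [read_fastq()].
#' @param cfg a [filter_config()].
#' @return list with `kept` (data.frame of trimmed reads) and `tally`
#'   (named counts: kept, length, quality, no_tag).
#' @export
preprocess_reads <- function(reads, cfg = filter_config()) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$quality)))
  n <- nrow(reads)
  len_ok <- nchar(reads$sequence) >= cfg$min_read_length
  q <- vapply(strsplit(reads$quality, ""), function(ch)
    do.call(cfg$quality_summary, list(utf8ToInt(paste(ch, collapse = "")) - 33)),
    numeric(1))
  qual_ok <- q >= cfg$min_mean_quality
  tag_at <- regexpr(cfg$transposon_tag, toupper(reads$sequence), fixed = TRUE)
  tag_ok <- tag_at > 0L
  keep <- len_ok & qual_ok & tag_ok
  reason <- ifelse(keep, "kept",
            ifelse(!len_ok, "length", ifelse(!qual_ok, "quality", "no_tag")))
  trim_from <- tag_at + nchar(cfg$transposon_tag)
  kept <- reads[keep, , drop = FALSE]
  kept$sequence <- substring(kept$sequence, trim_from[keep])
  kept$quality <- substring(kept$quality, trim_from[keep])
  tally <- c(kept = sum(keep),
             length = sum(reason == "length"),
             quality = sum(reason == "quality"),
             no_tag = sum(reason == "no_tag"))
  stopifnot(sum(tally) == n)
  rownames(kept) <- NULL
  list(kept = kept, tally = tally)
}

#' Read a SAM file into an alignment table
#'
#' Thin wrapper converting a text SAM to BAM and scanning the fields needed
#' for insertion extraction: flag, position, MAPQ, CIGAR (reference-aligned
#' width) and the NH tag.
#'
#' @param sam_path path to a SAM file (with header).
#' @return data.frame: `qname`, `flag`, `pos`, `mapq`, `cigar`,
#'   `aligned_width`, `strand`, `secondary`, `unmapped`, `nh`.
#' @export
read_sam_alignments <- function(sam_path) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "mapq", "cigar"),
    tag = "NH")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  nh <- x$tag$NH %||% rep(NA_integer_, n)
  if (length(nh) == 0L) nh <- rep(NA_integer_, n)
  aw <- rep(NA_integer_, n)
  has_cigar <- !is.na(x$cigar)
  aw[has_cigar] <-
    GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar[has_cigar])
  data.frame(qname = x$qname, flag = x$flag, pos = x$pos, mapq = x$mapq,
             cigar = x$cigar, aligned_width = aw,
             strand = ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+"),
             secondary = bitwAnd(x$flag, 256L) > 0L,
             unmapped = bitwAnd(x$flag, 4L) > 0L,
             nh = nh, stringsAsFactors = FALSE)
}

#' Extract insertion events from alignments
#'
#' Drops unmapped, multi-mapping (secondary hit, NH > 1, or MAPQ below
#' `mapq_min`) and short (`aligned_width < min_alignment_length`) records,
#' maps each remaining read to its transposon junction coordinate — the
#' leftmost reference base for `+` alignments, the rightmost for `-` — and
#' groups reads by (position, strand). Events at the same position on
#' opposite strands are distinct, independent events.
#'
#' @param alignments data.frame from [read_sam_alignments()] (or any table
#'   with the same columns).
#' @param cfg a [filter_config()].
#' @param library_id library label attached to every event.
#' @return insertion event data.frame: `library_id`, `position`, `strand`,
#'   `read_count`, ordered by (position, strand).
#' @export
extract_insertions <- function(alignments, cfg = filter_config(),
                               library_id = "lib1") {
  a <- alignments
  bad <- is.na(a$pos) | is.na(a$flag)
  if (any(bad)) {
    warning(sum(bad), " malformed alignment record(s) skipped")
    a <- a[!bad, , drop = FALSE]
  }
  multi <- a$secondary | (!is.na(a$nh) & a$nh > 1L) |
    (!is.na(a$mapq) & a$mapq < cfg$mapq_min)
  keep <- !a$unmapped & !multi &
    !is.na(a$aligned_width) & a$aligned_width >= cfg$min_alignment_length
  a <- a[keep, , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(library_id = character(), position = integer(),
                      strand = character(), read_count = integer(),
                      stringsAsFactors = FALSE))
  }
  junction <- ifelse(a$strand == "+", a$pos, a$pos + a$aligned_width - 1L)
  key <- paste(junction, a$strand)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  out <- data.frame(library_id = library_id,
                    position = as.integer(vapply(parts, `[`, "", 1L)),
                    strand = vapply(parts, `[`, "", 2L),
                    read_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Filter insertion events by read count
#'
#' @param events insertion event data.frame.
#' @param threshold minimum `read_count` (>= 1) to keep an event.
#' @return the kept events, stably ordered by (position, strand, library).
#' @export
filter_by_reads <- function(events, threshold) {
  stopifnot(threshold >= 1)
  out <- events[events$read_count >= threshold, , drop = FALSE]
  out <- out[order(out$position, out$strand, out$library_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- on-disk formats -------------------------------------------------------

#' Read/write a genome FASTA
#' @param path file path.
#' @param genome a [Biostrings::DNAString] (write) to store under `name`.
#' @param name sequence name.
#' @return `read_genome_fasta` returns a [Biostrings::DNAString].
#' @export
write_genome_fasta <- function(genome, path, name = "synthetic_genome") {
  x <- Biostrings::DNAStringSet(as.character(genome))
  names(x) <- name
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L) stop("expected a single-sequence FASTA: ", path)
  x[[1]]
}

#' Read a FASTQ file into a read table
#' @param path FASTQ path.
#' @return data.frame with `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a read table to FASTQ
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Write gene models to GFF3
#'
#' Genes are written as `gene` features with `ID`, `product` and, when truth
#' labels are supplied, an `essentiality_truth` attribute.
#'
#' @param genes gene data.frame.
#' @param path output path.
#' @param seqname chromosome name.
#' @param essential_ids optional character vector of ground-truth essential
#'   gene ids.
#' @export
write_genes_gff3 <- function(genes, path, seqname = "synthetic_genome",
                             essential_ids = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$product <- genes$product %||% rep("hypothetical protein", nrow(genes))
  gr$repeat_masked_fraction <-
    as.character(genes$repeat_masked_fraction %||% rep(0, nrow(genes)))
  if (!is.null(essential_ids))
    gr$essentiality_truth <-
      ifelse(genes$gene_id %in% essential_ids, "essential", "non_essential")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#' @param path GFF3 path.
#' @return gene data.frame (`gene_id`, `start`, `end`, `strand`, `product`,
#'   `repeat_masked_fraction`, and `essentiality_truth` when present).
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  out <- data.frame(gene_id = gr$ID,
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    product = if (!is.null(gr$product)) gr$product else
                      NA_character_,
                    repeat_masked_fraction =
                      if (!is.null(gr$repeat_masked_fraction))
                        as.numeric(gr$repeat_masked_fraction) else 0,
                    stringsAsFactors = FALSE)
  if (!is.null(gr$essentiality_truth))
    out$essentiality_truth <- gr$essentiality_truth
  out
}

#' Read/write insertion event tables (TSV)
#'
#' Columns: `library_id`, `position`, `strand`, `read_count`. Round-trips
#' exactly.
#'
#' @param events insertion event data.frame.
#' @param path file path.
#' @return `read_insertions_tsv` returns the event data.frame.
#' @export
write_insertions_tsv <- function(events, path) {
  utils::write.table(events[, c("library_id", "position", "strand",
                                "read_count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_insertions_tsv
#' @export
read_insertions_tsv <- function(path) {
  x <- utils::read.delim(path, colClasses = c("character", "integer",
                                              "character", "integer"))
  bad <- which(!(x$strand %in% c("+", "-")) | is.na(x$position) |
                 is.na(x$read_count))
  if (length(bad))
    stop("malformed insertion record(s) at line(s): ",
         paste(bad + 1L, collapse = ", "), " in ", path)
  x
}

#' Read/write presence/absence matrices (TSV)
#'
#' Taxa as rows, orthologs as columns, cells 0/1; first column `taxon`.
#'
#' @param mat logical or 0/1 matrix with dimnames.
#' @param path file path.
#' @return `read_pa_matrix_tsv` returns a logical matrix.
#' @export
write_pa_matrix_tsv <- function(mat, path) {
  df <- data.frame(taxon = rownames(mat),
                   `+`(mat, 0L), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pa_matrix_tsv
#' @export
read_pa_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE]) > 0
  rownames(m) <- df$taxon
  m
}

#' Read/write taxon-group maps (TSV)
#'
#' Two columns: `taxon`, `group`; one row per (taxon, group) membership.
#'
#' @param groups named list of character vectors (taxa per group).
#' @param path file path.
#' @return `read_taxon_groups_tsv` returns the named list.
#' @export
write_taxon_groups_tsv <- function(groups, path) {
  df <- data.frame(taxon = unlist(groups, use.names = FALSE),
                   group = rep(names(groups), lengths(groups)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_taxon_groups_tsv
#' @export
read_taxon_groups_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  split(df$taxon, df$group)
}

#' Write a binary character matrix as NEXUS
#'
#' @param mat logical taxa x characters matrix.
#' @param path output path.
#' @export
write_pa_nexus <- function(mat, path) {
  rows <- apply(`+`(mat, 0L), 1L, paste, collapse = "")
  dat <- strsplit(rows, "")
  names(dat) <- rownames(mat)
  ape::write.nexus.data(dat, file = path, format = "standard",
                        interleaved = FALSE)
  invisible(path)
}

#' Read/write gene score tables (TSV)
#' @param scores a `"gene_scores"` data.frame.
#' @param path file path.
#' @return `read_scores_tsv` returns the score data.frame.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
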