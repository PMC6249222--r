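TAG <- filter_config()$transposon_tag

make_read <- function(sequence, q = "I") {
  data.frame(id = "r", sequence = sequence,
             quality = strrep(q, nchar(sequence)), stringsAsFactors = FALSE)
}

test_that("short reads are rejected by length even when they carry the tag", {
  r <- make_read(paste0(TAG, strrep("A", 17)))  # 40 bp total
  out <- preprocess_reads(r)
  expect_equal(nrow(out$kept), 0L)
  expect_equal(unname(out$tally["length"]), 1L)
})

test_that("a clean 160-nt read is kept and trimmed to the sequence 3' of the tag", {
  r <- make_read(paste0(TAG, strrep("G", 137)))  # 160 nt, high quality
  out <- preprocess_reads(r)
  expect_equal(nrow(out$kept), 1L)
  expect_equal(nchar(out$kept$sequence), 137L)
  expect_equal(out$kept$sequence, strrep("G", 137))
  expect_equal(nchar(out$kept$quality), 137L)
})

test_that("tag matching is exact: every 1-mismatch variant is rejected", {
  bases <- c("A", "C", "G", "T")
  variants <- unlist(lapply(seq_len(nchar(TAG)), function(i) {
    orig <- substr(TAG, i, i)
    vapply(setdiff(bases, orig), function(b) {
      v <- TAG
      substr(v, i, i) <- b
      v
    }, "")
  }))
  reads <- data.frame(id = sprintf("r%02d", seq_along(variants)),
                      sequence = paste0(variants, strrep("A", 40)),
                      quality = strrep("I", nchar(TAG) + 40),
                      stringsAsFactors = FALSE)
  out <- preprocess_reads(reads)
  expect_equal(nrow(out$kept), 0L)
  expect_equal(unname(out$tally["no_tag"]), length(variants))
})

test_that("quality filtering honours the configured summary (mean vs min)", {
  # mean quality 31: half the bases at Q37 ("F"), half at Q25 (":")
  seqs <- paste0(TAG, strrep("A", 37))
  qual <- paste0(strrep("F", 30), strrep(":", 30))
  r <- data.frame(id = "r", sequence = seqs, quality = qual)
  expect_equal(nrow(preprocess_reads(r, filter_config())$kept), 1L)
  out_min <- preprocess_reads(r, filter_config(quality_summary = "min"))
  expect_equal(unname(out_min$tally["quality"]), 1L)
})

test_that("rejection tallies always sum to the input read count", {
  set.seed(4)
  n <- 60
  seqs <- vapply(seq_len(n), function(i) {
    core <- paste(sample(c("A", "C", "G", "T"), sample(30:90, 1),
                         replace = TRUE), collapse = "")
    if (i %% 2 == 0) paste0(core, TAG, "ACGTACGT") else core
  }, "")
  reads <- data.frame(id = sprintf("r%02d", 1:n), sequence = seqs,
                      quality = vapply(nchar(seqs), function(k)
                        paste(sample(c("I", "F", "5"), k, TRUE),
                              collapse = ""), ""))
  out <- preprocess_reads(reads)
  expect_equal(sum(out$tally), n)
  expect_equal(unname(out$tally["kept"]), nrow(out$kept))
})

test_that("insertion extraction applies strand, length and uniqueness rules", {
  sam <- write_test_sam(list(
    c("a1", 0, 100, 42, "30M", ""),          # + strand junction at 100
    c("a2", 16, 100, 42, "30M", ""),         # - strand junction at 129
    c("b1", 0, 300, 42, "10M", ""),          # too short: dropped
    c("c1", 0, 500, 42, "25M", ""), c("c2", 0, 500, 42, "25M", ""),
    c("c3", 0, 500, 42, "25M", ""), c("c4", 0, 500, 42, "25M", ""),
    c("c5", 0, 500, 42, "25M", ""),          # 5 identical -> one event
    c("d1", 0, 700, 0, "30M", ""),           # MAPQ 0: multi-mapping
    c("e1", 256, 800, 42, "30M", ""),        # secondary hit
    c("f1", 0, 900, 42, "30M", "NH:i:2")))   # NH > 1
  aln <- read_sam_alignments(sam)
  ev <- extract_insertions(aln, filter_config(), "L1")
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$position, c(100L, 129L, 500L))
  expect_equal(ev$strand, c("+", "-", "+"))
  expect_equal(ev$read_count, c(1L, 1L, 5L))
})

test_that("extraction is invariant to alignment record order", {
  sam <- write_test_sam(list(
    c("a1", 0, 100, 42, "30M", ""), c("a2", 16, 100, 42, "30M", ""),
    c("a3", 0, 250, 42, "20M", ""), c("a4", 0, 100, 42, "30M", "")))
  aln <- read_sam_alignments(sam)
  set.seed(9)
  shuffled <- aln[sample.int(nrow(aln)), , drop = FALSE]
  expect_equal(extract_insertions(aln, library_id = "x"),
               extract_insertions(shuffled, library_id = "x"))
})

test_that("an 11-bp alignment is kept but a 10-bp one is not", {
  sam <- write_test_sam(list(c("a", 0, 50, 42, "11M", ""),
                             c("b", 0, 80, 42, "10M", "")))
  ev <- extract_insertions(read_sam_alignments(sam))
  expect_equal(ev$position, 50L)
})

test_that("read-count filtering keeps the histogram tail", {
  ev <- data.frame(library_id = "l", position = 1:4, strand = "+",
                   read_count = c(1L, 2L, 3L, 4L))
  expect_equal(nrow(filter_by_reads(ev, 3L)), 2L)
  expect_equal(filter_by_reads(ev, 1L), ev)
  set.seed(2)
  big <- data.frame(library_id = "l", position = sample.int(1e6, 500),
                    strand = "+",
                    read_count = stats::rgeom(500, 1 / 20) + 1L)
  tail_sum <- sum(table(big$read_count)[as.integer(names(table(big$read_count))) >= 4])
  expect_equal(nrow(filter_by_reads(big, 4L)), unname(tail_sum))
})

test_that("insertion tables round-trip through TSV unchanged", {
  ev <- data.frame(library_id = c("l1", "l1", "l2"),
                   position = c(10L, 10L, 99L),
                   strand = c("+", "-", "+"),
                   read_count = c(3L, 7L, 1L))
  f <- tempfile(fileext = ".tsv")
  write_insertions_tsv(ev, f)
  expect_identical(read_insertions_tsv(f), ev)
})

test_that("malformed insertion rows are reported with their line numbers", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("library_id\tposition\tstrand\tread_count",
               "l1\t10\t+\t3", "l1\t20\t?\t2"), f)
  expect_error(read_insertions_tsv(f), "line.*3")
})

test_that("gene models round-trip through GFF3 with strand and attributes", {
  genes <- random_gene_table(6, 10000L, seed = 2L)
  genes$strand[1] <- "-"
  f <- tempfile(fileext = ".gff3")
  write_genes_gff3(genes, f, essential_ids = genes$gene_id[2])
  back <- read_genes_gff3(f)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$strand, genes$strand)
  expect_equal(back$strand[1], "-")
  expect_equal(back$essentiality_truth,
               ifelse(genes$gene_id == genes$gene_id[2], "essential",
                      "non_essential"))
})

test_that("presence/absence matrices and taxon groups round-trip through TSV", {
  pa <- simulate_presence_absence(seed = 4L)
  f <- tempfile(); g <- tempfile()
  write_pa_matrix_tsv(pa$matrix, f)
  expect_identical(read_pa_matrix_tsv(f), pa$matrix)
  write_taxon_groups_tsv(pa$taxon_groups, g)
  back <- read_taxon_groups_tsv(g)
  for (grp in names(pa$taxon_groups))
    expect_setequal(back[[grp]], pa$taxon_groups[[grp]])
})

test_that("FASTQ reads round-trip with qualities intact", {
  reads <- data.frame(id = c("x", "y"),
                      sequence = c("ACGTACGT", "GGGGCCCC"),
                      quality = c("IIIIFFFF", "!!!!IIII"))
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  expect_equal(read_fastq(f), reads)
})
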