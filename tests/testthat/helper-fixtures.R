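# Shared fixtures, built in code at test time.

# minimal single-reference SAM file; records = list of c(qname, flag, pos,
# mapq, cigar, extra-tag-or-"")
write_test_sam <- function(records, ref_len = 10000L) {
  path <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:chr\tLN:%d", ref_len))
  body <- vapply(records, function(r) {
    width <- sum(as.integer(
      regmatches(r[5], gregexpr("[0-9]+(?=[MX=])", r[5], perl = TRUE))[[1]]))
    seq <- strrep("A", max(width, 1L))
    line <- paste(r[1], r[2], "chr", r[3], r[4], r[5], "*", 0, 0, seq, "*",
                  sep = "\t")
    if (nchar(r[6])) line <- paste(line, r[6], sep = "\t")
    line
  }, "")
  writeLines(c(header, body), path)
  path
}

# deterministic small gene table on a linear genome
random_gene_table <- function(n, genome_length, seed = 1L,
                              mean_len = 300L) {
  set.seed(seed)
  lens <- pmax(20L, as.integer(round(stats::rgamma(n, 3, scale = mean_len / 3))))
  gap <- as.integer((genome_length - sum(lens)) / (n + 1L))
  stopifnot(gap >= 1L)
  starts <- as.integer(gap + cumsum(c(0L, lens[-n] + gap)) + 1L)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             start = starts, end = starts + lens - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             product = "hypothetical protein",
             repeat_masked_fraction = 0,
             stringsAsFactors = FALSE)
}

# tiny nested taxon panel for phyletic unit tests; each subgroup is kept
# below half of its parent so narrow categories do not bleed upward
tiny_taxon_groups <- function() {
  sulf <- c("S1", "S2", "S3")
  tack <- c(sulf, "T1", "T2", "T3", "T4")
  eury <- paste0("E", 1:8)
  list(Sulfolobales = sulf,
       TACK = tack,
       Euryarchaeota = eury,
       Archaea = c(tack, eury),
       Bacteria = c("B1", "B2", "B3", "B4"),
       Eukarya = c("K1", "K2", "K3", "K4"))
}

tiny_taxa <- function() unique(unlist(tiny_taxon_groups(), use.names = FALSE))

# exhaustive minimum over all ancestral state assignments; the independent
# oracle for Fitch scoring
brute_force_parsimony <- function(tree, mat) {
  nint <- tree$Nnode
  edge <- tree$edge
  tip_states <- mat[tree$tip.label, , drop = FALSE] > 0
  total <- 0L
  assignments <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nint)))
  for (j in seq_len(ncol(mat))) {
    best <- Inf
    for (a in seq_len(nrow(assignments))) {
      states <- c(tip_states[, j], assignments[a, ])
      changes <- sum(states[edge[, 1]] != states[edge[, 2]])
      best <- min(best, changes)
    }
    total <- total + best
  }
  total
}
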