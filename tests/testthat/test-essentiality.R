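test_that("gene bodies are trimmed 5%/20% in a strand-aware way", {
  plus <- data.frame(gene_id = "p", start = 1001L, end = 2000L, strand = "+")
  minus <- data.frame(gene_id = "m", start = 1001L, end = 2000L, strand = "-")
  tb_p <- trimmed_body(plus)
  expect_equal(c(tb_p$start, tb_p$end), c(1051L, 1800L))
  tb_m <- trimmed_body(minus)
  expect_equal(c(tb_m$start, tb_m$end), c(1201L, 1950L))
})

test_that("trimmed length is 75% of gene length within rounding", {
  set.seed(8)
  genes <- data.frame(gene_id = sprintf("g%d", 1:100),
                      start = seq(1, by = 2000, length.out = 100))
  genes$end <- genes$start + sample(20:1500, 100, replace = TRUE) - 1L
  genes$strand <- sample(c("+", "-"), 100, TRUE)
  tb <- trimmed_body(genes)
  L <- genes$end - genes$start + 1
  expect_true(all(abs((tb$end - tb$start + 1) - round(0.75 * L)) <= 1))
})

test_that("degenerate genes are returned untrimmed with a warning", {
  g <- data.frame(gene_id = "t", start = 10L, end = 12L, strand = "+")
  expect_warning(tb <- trimmed_body(g), "shorter than 4")
  expect_equal(c(tb$start, tb$end), c(10L, 12L))
})

test_that("EI counts distinct strand-aware sites inside the trimmed body", {
  gene <- data.frame(gene_id = "g", start = 1001L, end = 2000L, strand = "+")
  ev <- data.frame(library_id = "l",
                   position = c(1100L, 1100L, 1500L, 1025L),
                   strand = c("+", "-", "+", "+"),
                   read_count = 10L)
  expect_equal(unname(compute_ei(ev, gene)), 3L)
  expect_equal(unname(compute_ei(ev[0, ], gene)), 0L)
  head_only <- ev[ev$position == 1025L, ]
  expect_equal(unname(compute_ei(head_only, gene)), 0L)
})

test_that("log2FC is zero when observed equals expected", {
  cfg <- scoring_config(head_trim = 0, tail_trim = 0)
  gene <- data.frame(gene_id = "g", start = 1L, end = 1000L, strand = "+")
  ev <- data.frame(library_id = "l", position = seq(10, 990, by = 10),
                   strand = "+", read_count = 10L)
  lfc <- compute_log2fc(ev, gene, genome_length = 1000L, cfg)
  expect_equal(unname(lfc), 0)
})

test_that("a fully depleted gene scores the closed-form log ratio", {
  cfg <- scoring_config(head_trim = 0, tail_trim = 0)
  genes <- data.frame(gene_id = c("empty", "rest"),
                      start = c(1001L, 1L), end = c(2000L, 1000L),
                      strand = "+")
  ev <- data.frame(library_id = "l", position = seq(1, 1000, length.out = 200),
                   strand = "+", read_count = 10L)
  lfc <- compute_log2fc(ev, genes, genome_length = 2000L, cfg)
  # expected = 2000 * 1000/2000 = 1000; observed = 0
  expect_equal(unname(lfc["empty"]), log2(1 / 1001), tolerance = 1e-12)
  expect_equal(round(unname(lfc["empty"]), 3), -9.967)
})

test_that("repeat-masked genes get NA regardless of read counts", {
  genes <- data.frame(gene_id = "r", start = 1L, end = 1000L, strand = "+",
                      repeat_masked_fraction = 0.9)
  ev <- data.frame(library_id = "l", position = 1:50 * 10, strand = "+",
                   read_count = 100L)
  expect_true(is.na(compute_log2fc(ev, genes, 2000L)))
})

test_that("zero total reads warns and yields all-NA scores", {
  genes <- data.frame(gene_id = "g", start = 1L, end = 100L, strand = "+")
  ev <- data.frame(library_id = character(), position = integer(),
                   strand = character(), read_count = integer())
  expect_warning(lfc <- compute_log2fc(ev, genes, 1000L), "zero total reads")
  expect_true(all(is.na(lfc)))
})

test_that("EI and observed reads agree with a brute-force recount on toys", {
  set.seed(21)
  genes <- random_gene_table(40, 60000L, seed = 21)
  ev <- data.frame(library_id = sample(c("l1", "l2"), 800, TRUE),
                   position = sample.int(60000L, 800, replace = TRUE),
                   strand = sample(c("+", "-"), 800, TRUE),
                   read_count = stats::rgeom(800, 1 / 10) + 1L)
  cfg <- scoring_config()
  tb <- trimmed_body(genes, cfg)
  ei <- compute_ei(ev, genes, cfg)
  lfc <- compute_log2fc(ev, genes, 60000L, cfg)
  for (i in seq_len(nrow(genes))) {
    inside <- ev$position >= tb$start[i] & ev$position <= tb$end[i]
    brute_ei <- nrow(unique(ev[inside, c("position", "strand")]))
    expect_identical(unname(ei[i]), as.integer(brute_ei))
    brute_obs <- sum(ev$read_count[inside])
    brute_exp <- sum(ev$read_count) * (tb$end[i] - tb$start[i] + 1) / 60000
    expect_equal(unname(lfc[i]), log2((brute_obs + 1) / (brute_exp + 1)))
  }
})

test_that("adding an insertion in the trimmed body never lowers EI or log2FC", {
  set.seed(31)
  genes <- random_gene_table(10, 20000L, seed = 31)
  tb <- trimmed_body(genes)
  ev <- data.frame(library_id = "l",
                   position = sample.int(20000L, 200),
                   strand = sample(c("+", "-"), 200, TRUE),
                   read_count = stats::rgeom(200, 1 / 10) + 1L)
  for (rep in 1:20) {
    i <- sample.int(nrow(genes), 1)
    new <- data.frame(library_id = "l",
                      position = sample(tb$start[i]:tb$end[i], 1),
                      strand = sample(c("+", "-"), 1),
                      read_count = sample(1:30, 1))
    ev2 <- rbind(ev, new)
    expect_gte(compute_ei(ev2, genes)[i], compute_ei(ev, genes)[i])
    l1 <- compute_log2fc(ev, genes, 20000L)[i]
    l2 <- compute_log2fc(ev2, genes, 20000L)[i]
    expect_gte(l2, l1)
  }
})

test_that("duplicated sequence is masked on both copies, forward or reverse", {
  set.seed(5)
  seg <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  g <- paste0(pad(500), seg, pad(300), seg, pad(100))
  m <- uniqueness_mask(g, 50L)
  expect_true(all(m[501:900]))
  expect_true(all(m[1201:1600]))
  rcseg <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seg)))
  g2 <- paste0(pad(500), seg, pad(300), rcseg, pad(100))
  m2 <- uniqueness_mask(g2, 50L)
  expect_true(all(m2[501:900]))
  expect_true(all(m2[1201:1600]))
})

test_that("a random genome is essentially unmasked", {
  set.seed(6)
  g <- paste(sample(c("A", "C", "G", "T"), 50000, TRUE), collapse = "")
  expect_equal(sum(uniqueness_mask(g, 50L)), 0L)
})

test_that("mask positions match a quadratic brute-force scan on a tiny genome", {
  set.seed(7)
  core <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  g <- paste0(paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""),
              core,
              paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
              core,
              paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""))
  k <- 50L
  L <- nchar(g)
  kmer_at <- function(i) substr(g, i, i + k - 1L)
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  brute <- logical(L)
  for (i in seq_len(L - k + 1L)) {
    ki <- kmer_at(i)
    hits <- 0L
    for (j in seq_len(L - k + 1L)) {
      kj <- kmer_at(j)
      if (kj == ki || rc(kj) == ki) hits <- hits + 1L
    }
    if (hits >= 2L) brute[i:(i + k - 1L)] <- TRUE
  }
  expect_identical(uniqueness_mask(g, k), brute)
  expect_identical(masked_fraction(uniqueness_mask(g, k),
                                   data.frame(start = 1L, end = L)),
                   mean(brute))
})

test_that("the valley of an equal-weight Gaussian mixture lies at the midpoint", {
  set.seed(12)
  x <- c(stats::rnorm(2000, -10), stats::rnorm(2000, 0))
  res <- find_cutoff(x)
  expect_lt(abs(res$cutoff - (-5)), 0.5)
  expect_equal(length(res$modes), 2L)
  expect_lt(abs(res$modes[1] - (-10)), 1)
  expect_lt(abs(res$modes[2] - 0), 1)
})

test_that("unimodal or degenerate score sets raise a no-bimodality error", {
  expect_error(find_cutoff(rep(1.5, 100)), "no bimodality")
  set.seed(13)
  expect_error(find_cutoff(stats::rnorm(5000)), "no bimodality")
  expect_error(find_cutoff(stats::rnorm(10)), "at least 50")
})

test_that("an unequal mixture valley matches the analytic density minimum", {
  set.seed(14)
  x <- c(stats::rnorm(800, -8), stats::rnorm(3200, 0))
  mixture_density <- function(t) 0.2 * stats::dnorm(t, -8) +
    0.8 * stats::dnorm(t, 0)
  grid <- seq(-8, 0, length.out = 20001)
  truth <- grid[which.min(mixture_density(grid))]
  expect_lt(abs(find_cutoff(x)$cutoff - truth), 0.5)
})

test_that("consensus classification fills the four-way partition correctly", {
  genes <- data.frame(gene_id = c("a", "b", "c", "d"),
                      start = 1L, end = 100L, strand = "+")
  lfc <- c(a = -6, b = -6, c = 0, d = NA)
  ei <- c(a = 2L, b = 10L, c = 50L, d = 0L)
  sc <- classify(genes, lfc, ei)
  expect_equal(sc$call, c("essential", "unassigned", "non_essential",
                          NA_character_))
  pc <- partition_counts(sc)
  expect_equal(sum(pc), nrow(genes))
  expect_equal(unname(pc["unassigned"]), 1L)
})

test_that("one-criterion genes are never called essential", {
  set.seed(15)
  n <- 300
  genes <- data.frame(gene_id = sprintf("g%03d", 1:n), start = 1L,
                      end = 100L, strand = "+")
  lfc <- stats::setNames(stats::runif(n, -12, 2), genes$gene_id)
  ei <- stats::setNames(sample(0:30, n, TRUE), genes$gene_id)
  sc <- classify(genes, lfc, ei)
  one_criterion <- xor(lfc <= -5.1, ei < 4L)
  expect_true(all(sc$call[one_criterion] == "unassigned"))
  expect_equal(sum(partition_counts(sc)), n)
})

test_that("manual overrides are applied last, reported, and validated", {
  genes <- data.frame(gene_id = c("a", "b"), start = 1L, end = 100L,
                      strand = "+")
  lfc <- c(a = -7, b = -7)
  ei <- c(a = 1L, b = 1L)
  cfg <- scoring_config(manual_overrides = c(a = "non_essential"))
  sc <- classify(genes, lfc, ei, cfg)
  expect_equal(sc$call, c("non_essential", "essential"))
  expect_equal(sc$overridden, c(TRUE, FALSE))
  bad <- scoring_config(manual_overrides = c(zz = "essential"))
  expect_error(classify(genes, lfc, ei, bad), "unknown gene")
})
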