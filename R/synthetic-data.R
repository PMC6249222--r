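#' Simulation configuration for synthetic Tn-seq libraries
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate a
#' saturating Tn5 mutagenesis experiment on a 2.59-Mb thermoacidophilic
#' archaeal chromosome: ~2300 protein-coding genes of mean length 900.64 bp at
#' 35% G+C, three independent insertion libraries of 30,000 junctions each,
#' a heavy-tailed (geometric) per-site read-count distribution, and essential
#' genes whose trimmed bodies are depleted of insertions apart from a small
#' leak rate.
#'
#' @param genome_length genome size in bp.
#' @param n_genes number of protein-coding genes to annotate.
#' @param gene_length_mean mean gene length in bp (gamma-distributed lengths,
#'   shape 3, truncated below at 90 bp).
#' @param essential_fraction proportion of genes that are essential.
#' @param n_insertions_per_library unique insertion events emitted per library.
#' @param n_libraries number of independent libraries.
#' @param read_count_distribution name of the per-site read-count law;
#'   currently `"geometric"` (support 1, 2, ...).
#' @param read_count_mean mean of the read-count distribution.
#' @param essential_leak_rate per-essential-gene, per-library probability of a
#'   single stray insertion landing in the trimmed gene body.
#' @param site_bias_strength target fold-enrichment of G/C at the insertion
#'   junction (offset 0) relative to genome background; 1 = unbiased. The
#'   flanking +/-1..5 bases receive a mild, palindromic A/T preference scaling
#'   with the same strength.
#' @param gc_content genome G+C proportion.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return an object of class `"sim_config"` (a validated list).
#' @export
simulation_config <- function(genome_length = 2586647L,
                              n_genes = 2300L,
                              gene_length_mean = 900.64,
                              essential_fraction = 440 / 2300,
                              n_insertions_per_library = 30000L,
                              n_libraries = 3L,
                              read_count_distribution = "geometric",
                              read_count_mean = 30,
                              essential_leak_rate = 0.005,
                              site_bias_strength = 1,
                              gc_content = 0.35,
                              seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              gene_length_mean = gene_length_mean,
              essential_fraction = essential_fraction,
              n_insertions_per_library = as.integer(n_insertions_per_library),
              n_libraries = as.integer(n_libraries),
              read_count_distribution = match.arg(read_count_distribution,
                                                  "geometric"),
              read_count_mean = read_count_mean,
              essential_leak_rate = essential_leak_rate,
              site_bias_strength = site_bias_strength,
              gc_content = gc_content,
              seed = as.integer(seed))
  .assert_scalar_prob(cfg$essential_fraction, "essential_fraction")
  .assert_scalar_prob(cfg$essential_leak_rate, "essential_leak_rate")
  .assert_scalar_prob(cfg$gc_content, "gc_content")
  if (cfg$genome_length < 1L) stop("genome_length must be positive")
  if (cfg$n_genes < 0L || cfg$n_insertions_per_library < 0L ||
      cfg$n_libraries < 0L)
    stop("counts must be non-negative")
  if (cfg$site_bias_strength <= 0) stop("site_bias_strength must be positive")
  if (cfg$read_count_mean < 1) stop("read_count_mean must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic genome with annotated genes and essentiality truth
#'
#' Draws a random nucleotide sequence at the configured G+C content and packs
#' `n_genes` non-overlapping genes on both strands, separated by random
#' intergenic gaps. Gene lengths are gamma-distributed (shape 3) around
#' `gene_length_mean` with a 90-bp floor. A random subset of genes (without
#' replacement) is labelled essential in the returned ground truth.
#'
#' @param config a [simulation_config()].
#' @return a list of class `"tn_simulation"` with elements `genome`
#'   (a [Biostrings::DNAString]), `genes` (data.frame: `gene_id`, `start`,
#'   `end`, `strand`, `product`, `repeat_masked_fraction`), `truth` (list with
#'   `essential_gene_ids`) and `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  L <- config$genome_length
  gc <- config$gc_content
  seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  genome <- Biostrings::DNAString(paste(seq_chars, collapse = ""))

  n <- config$n_genes
  if (n == 0L) {
    genes <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        product = character(),
                        repeat_masked_fraction = numeric(),
                        stringsAsFactors = FALSE)
    truth <- list(essential_gene_ids = character())
    return(structure(list(genome = genome, genes = genes, truth = truth,
                          config = config), class = "tn_simulation"))
  }

  lens <- pmax(90L, as.integer(round(
    stats::rgamma(n, shape = 3, scale = config$gene_length_mean / 3))))
  slack <- L - sum(lens)
  if (slack < 0)
    stop("infeasible packing: total gene length exceeds genome_length")
  gaps <- as.vector(stats::rmultinom(1, slack, rep(1, n + 1L)))
  starts <- if (n == 1L) gaps[1L] + 1L else
    gaps[1L] + 1L + c(0L, cumsum(lens[-n] + gaps[2:n]))
  ends <- starts + lens - 1L
  ids <- sprintf("gene_%04d", seq_len(n))
  genes <- data.frame(gene_id = ids,
                      start = as.integer(starts),
                      end = as.integer(ends),
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      product = "hypothetical protein",
                      repeat_masked_fraction = 0,
                      stringsAsFactors = FALSE)
  n_ess <- as.integer(round(config$essential_fraction * n))
  truth <- list(essential_gene_ids = sort(sample(ids, n_ess)))
  structure(list(genome = genome, genes = genes, truth = truth,
                 config = config), class = "tn_simulation")
}

# Odds weight giving a target fold-enrichment b of a class with background
# frequency p: solve w*p / (w*p + (1-p)) = b*p  =>  w = b*(1-p)/(1-b*p).
.bias_odds_weight <- function(target_fold, background_freq) {
  b <- target_fold
  p <- background_freq
  if (b * p >= 1)
    stop("site_bias_strength too large for the genome composition")
  b * (1 - p) / (1 - b * p)
}

#' Simulate transposon insertion libraries over a synthetic genome
#'
#' Places `n_insertions_per_library` unique (position, strand) insertion
#' events per library, uniformly over the genome excluding essential trimmed
#' gene bodies (which receive insertions only via `essential_leak_rate`),
#' optionally weighted by a palindromic insertion-site composition bias (G/C
#' preferred at the junction base, A/T mildly preferred at offsets 1..5 on
#' both sides). Per-site read counts are i.i.d. from the configured
#' distribution. The same (position, strand) may recur across libraries;
#' libraries are independent.
#'
#' @param sim a `"tn_simulation"` from [generate_genome()].
#' @param config optional [simulation_config()] overriding `sim$config`.
#' @return a data.frame of insertion events: `library_id`, `position`,
#'   `strand`, `read_count`, sorted by library then position.
#' @export
simulate_insertions <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "tn_simulation"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "insertions"))
  L <- config$genome_length
  genes <- sim$genes
  ess <- genes[genes$gene_id %in% sim$truth$essential_gene_ids, , drop = FALSE]

  blocked <- logical(L)
  ess_bodies <- NULL
  if (nrow(ess)) {
    tb <- trimmed_body(ess)
    ess_bodies <- tb
    for (i in seq_len(nrow(tb))) blocked[tb$start[i]:tb$end[i]] <- TRUE
  }
  allowed <- which(!blocked)

  w <- NULL
  if (config$site_bias_strength != 1) {
    chars <- strsplit(as.character(sim$genome), "")[[1]]
    is_gc <- chars == "G" | chars == "C"
    w_center <- .bias_odds_weight(config$site_bias_strength, config$gc_content)
    # mild palindromic A/T preference in the 5-bp flanks on both sides
    w_flank <- config$site_bias_strength^0.1
    logw <- ifelse(is_gc, log(w_center), 0)
    at <- as.numeric(!is_gc)
    flank_at <- numeric(L)
    for (d in 1:5) {
      flank_at <- flank_at +
        c(rep(0, d), at[seq_len(L - d)]) + c(at[-seq_len(d)], rep(0, d))
    }
    logw <- logw + flank_at * log(w_flank)
    w <- exp(logw)[allowed]
  }

  pick_sites <- function(n) {
    # sample (position, strand) without replacement within a library;
    # strand carries no weight, so sample over 2x the allowed positions
    m <- length(allowed)
    if (n > 2L * m) stop("more insertions requested than available sites")
    if (is.null(w)) {
      idx <- sample.int(2L * m, n)
    } else {
      # exponential-race weighted sampling without replacement
      keys <- stats::rexp(2L * m) / rep(w, 2L)
      idx <- order(keys)[seq_len(n)]
    }
    pos <- allowed[(idx - 1L) %% m + 1L]
    strand <- c("+", "-")[(idx - 1L) %/% m + 1L]
    list(pos = pos, strand = strand)
  }

  draw_reads <- function(n) {
    stats::rgeom(n, prob = 1 / config$read_count_mean) + 1L
  }

  out <- vector("list", config$n_libraries)
  for (lib in seq_len(config$n_libraries)) {
    n <- config$n_insertions_per_library
    leak_pos <- integer()
    leak_strand <- character()
    if (!is.null(ess_bodies) && config$essential_leak_rate > 0 && n > 0) {
      leak <- which(stats::runif(nrow(ess_bodies)) < config$essential_leak_rate)
      if (length(leak) > n) leak <- leak[seq_len(n)]
      if (length(leak)) {
        leak_pos <- vapply(leak, function(i)
          sample(ess_bodies$start[i]:ess_bodies$end[i], 1L), integer(1))
        leak_strand <- sample(c("+", "-"), length(leak), replace = TRUE)
      }
    }
    n_rest <- n - length(leak_pos)
    sites <- pick_sites(n_rest)
    pos <- c(leak_pos, sites$pos)
    strand <- c(leak_strand, sites$strand)
    ord <- order(pos, strand)
    out[[lib]] <- data.frame(library_id = sprintf("lib%d", lib),
                             position = pos[ord], strand = strand[ord],
                             read_count = draw_reads(n),
                             stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, out)
  rownames(events) <- NULL
  events
}

.PHYLETIC_GROUPS <- c("Bacteria", "Euryarchaeota", "TACK", "Sulfolobales",
                      "Eukarya")

#' Default taxon-group sizes for phyletic simulations
#'
#' Mirrors the relative representation of bacteria, euryarchaeota, TACK
#' archaea (including Sulfolobales) and eukaryotes in genome panels used for
#' cross-domain presence/absence profiling.
#'
#' @return a named integer vector of taxa per group; `Sulfolobales` counts are
#'   a subset of `TACK`.
#' @export
default_group_sizes <- function() {
  c(Bacteria = 40L, Euryarchaeota = 30L, TACK = 25L, Sulfolobales = 8L,
    Eukarya = 25L)
}

#' Default ortholog counts per phyletic category
#'
#' Proportions follow the characteristic profile of an archaeal essential
#' genome: most orthologs universal across the three domains, a substantial
#' Eukarya/Archaea-shared set, then archaea-, TACK- and Sulfolobales-specific
#' tiers plus an unclassifiable remainder.
#'
#' @return named integer vector over categories Universal, EA, Archaea, TACK,
#'   Sulfolobales, Other.
#' @export
default_category_sizes <- function() {
  c(Universal = 141L, EA = 80L, Archaea = 55L, TACK = 18L, Sulfolobales = 73L,
    Other = 74L)
}

#' Build the taxon table for a phyletic simulation
#' @keywords internal
.make_taxa <- function(group_sizes) {
  need <- c("Bacteria", "Euryarchaeota", "TACK", "Sulfolobales", "Eukarya")
  if (!all(need %in% names(group_sizes)))
    stop("group_sizes must name all of: ", paste(need, collapse = ", "))
  extra <- setdiff(names(group_sizes), need)
  if (length(extra)) stop("unknown group name(s): ", paste(extra, collapse = ", "))
  if (group_sizes[["Sulfolobales"]] > group_sizes[["TACK"]])
    stop("Sulfolobales taxa must be a subset of TACK taxa")
  n_sulf <- group_sizes[["Sulfolobales"]]
  n_tack_only <- group_sizes[["TACK"]] - n_sulf
  taxa <- c(sprintf("Sulfolobales_%02d", seq_len(n_sulf)),
            sprintf("TACK_%02d", seq_len(n_tack_only)),
            sprintf("Eury_%02d", seq_len(group_sizes[["Euryarchaeota"]])),
            sprintf("Bact_%02d", seq_len(group_sizes[["Bacteria"]])),
            sprintf("Euk_%02d", seq_len(group_sizes[["Eukarya"]])))
  groups <- list(
    Sulfolobales = taxa[grepl("^Sulfolobales", taxa)],
    TACK = taxa[grepl("^(Sulfolobales|TACK)", taxa)],
    Euryarchaeota = taxa[grepl("^Eury", taxa)],
    Archaea = taxa[grepl("^(Sulfolobales|TACK|Eury)", taxa)],
    Bacteria = taxa[grepl("^Bact", taxa)],
    Eukarya = taxa[grepl("^Euk", taxa)])
  list(taxa = taxa, groups = groups)
}

#' Simulate a taxa-by-ortholog presence/absence matrix with known categories
#'
#' Each ortholog belongs to a ground-truth phyletic category; it is present in
#' each taxon of the category's defining groups with probability
#' `retention_prob` and in every other taxon with probability `noise_prob`.
#' The focal taxon (first Sulfolobales genome) always carries every ortholog.
#' `Other` orthologs are present only in the focal taxon (plus noise).
#'
#' @param group_sizes named counts of taxa per group
#'   (Bacteria/Euryarchaeota/TACK/Sulfolobales/Eukarya); Sulfolobales within
#'   TACK within Archaea nesting is constructed automatically.
#' @param n_orthologs_per_category named counts per category
#'   (Universal/EA/Archaea/TACK/Sulfolobales/Other).
#' @param retention_prob presence probability inside defining groups.
#' @param noise_prob presence probability outside defining groups.
#' @param seed integer seed.
#' @return list with `matrix` (logical taxa x orthologs), `taxon_groups`
#'   (named list of taxa per group, including the derived `Archaea` group),
#'   `focal_taxon`, and `truth` (list with `category_labels`).
#' @export
simulate_presence_absence <- function(group_sizes = default_group_sizes(),
                                      n_orthologs_per_category =
                                        default_category_sizes(),
                                      retention_prob = 0.9,
                                      noise_prob = 0.02,
                                      seed = 1L) {
  .assert_scalar_prob(retention_prob, "retention_prob")
  .assert_scalar_prob(noise_prob, "noise_prob")
  set.seed(derive_seed(seed, "presence_absence"))
  tg <- .make_taxa(group_sizes)
  taxa <- tg$taxa
  groups <- tg$groups
  focal <- groups$Sulfolobales[1L]
  if (is.na(focal)) stop("need at least one Sulfolobales taxon (focal)")

  defining <- list(
    Universal = c("Bacteria", "Archaea", "Eukarya"),
    EA = c("Eukarya", "Archaea"),
    Archaea = "Archaea",
    TACK = "TACK",
    Sulfolobales = "Sulfolobales",
    Other = character())
  cats <- names(defining)
  bad <- setdiff(names(n_orthologs_per_category), cats)
  if (length(bad)) stop("unknown category name(s): ", paste(bad, collapse = ", "))

  labels <- rep(names(n_orthologs_per_category), n_orthologs_per_category)
  n_orth <- length(labels)
  orth_ids <- sprintf("OG%04d", seq_len(n_orth))
  mat <- matrix(FALSE, length(taxa), n_orth,
                dimnames = list(taxa, orth_ids))
  for (j in seq_len(n_orth)) {
    inside <- unique(unlist(groups[defining[[labels[j]]]], use.names = FALSE))
    p <- ifelse(taxa %in% inside, retention_prob, noise_prob)
    mat[, j] <- stats::runif(length(taxa)) < p
  }
  mat[focal, ] <- TRUE
  list(matrix = mat, taxon_groups = groups, focal_taxon = focal,
       truth = list(category_labels = stats::setNames(labels, orth_ids)))
}
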