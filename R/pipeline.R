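#' Run the full synthetic Tn-seq analysis pipeline
#'
#' Orchestrates simulate -> score -> stats -> phyletics into one reproducible
#' run directory. Each stage derives its own seed from the global seed and
#' its name, writes TSV/FASTA/GFF3 outputs, and is recorded in a JSON
#' manifest with row counts and file checksums; rerunning with the same
#' configuration and seed reproduces every file byte-identically.
#'
#' @param outdir output directory (created if missing).
#' @param sim_config a [simulation_config()].
#' @param scoring_cfg a [scoring_config()].
#' @param stages character subset of
#'   `c("simulate", "score", "stats", "phyletics")`; later stages require the
#'   outputs of earlier ones within the same run.
#' @param seed global seed; overrides `sim_config$seed`.
#' @return (invisibly) the manifest list; side effect: files under `outdir`.
#' @export
run_pipeline <- function(outdir,
                         sim_config = simulation_config(),
                         scoring_cfg = scoring_config(),
                         stages = c("simulate", "score", "stats",
                                    "phyletics"),
                         seed = sim_config$seed) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim_config$seed <- as.integer(seed)
  manifest <- list(package = "tnseqr",
                   version = as.character(utils::packageVersion("tnseqr")),
                   seed = as.integer(seed), stages = list())
  paths <- list(fasta = file.path(outdir, "genome.fasta"),
                gff = file.path(outdir, "genes.gff3"),
                insertions = file.path(outdir, "insertions.tsv"),
                scores = file.path(outdir, "scores.tsv"),
                stats = file.path(outdir, "library_stats.json"),
                bias = file.path(outdir, "site_bias.tsv"),
                pa = file.path(outdir, "presence_absence.tsv"),
                groups = file.path(outdir, "taxon_groups.tsv"),
                categories = file.path(outdir, "category_counts.tsv"))

  note_stage <- function(name, files, extra = list()) {
    info <- c(list(files = vapply(files, identity, ""),
                   checksums = unname(tools::md5sum(files))), extra)
    manifest$stages[[name]] <<- info
  }
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  sim <- NULL
  events <- NULL
  if ("simulate" %in% stages) {
    tryCatch({
      sim <- generate_genome(sim_config)
      events <- simulate_insertions(sim)
      write_genome_fasta(sim$genome, paths$fasta)
      write_genes_gff3(sim$genes, paths$gff,
                       essential_ids = sim$truth$essential_gene_ids)
      write_insertions_tsv(events, paths$insertions)
      note_stage("simulate",
                 c(paths$fasta, paths$gff, paths$insertions),
                 list(n_genes = nrow(sim$genes), n_events = nrow(events),
                      n_essential_truth =
                        length(sim$truth$essential_gene_ids)))
    }, error = function(e) fail("simulate", e))
  }
  if ("score" %in% stages) {
    tryCatch({
      genes <- read_genes_gff3(paths$gff)
      events <- read_insertions_tsv(paths$insertions)
      genome <- read_genome_fasta(paths$fasta)
      scores <- score_genes(events, genes, length(genome), scoring_cfg)
      write_scores_tsv(scores, paths$scores)
      note_stage("score", paths$scores,
                 list(partition = as.list(partition_counts(scores))))
    }, error = function(e) fail("score", e))
  }
  if ("stats" %in% stages) {
    tryCatch({
      events <- read_insertions_tsv(paths$insertions)
      genome <- read_genome_fasta(paths$fasta)
      genes <- read_genes_gff3(paths$gff)
      union3 <- filter_by_reads(events, scoring_cfg$min_reads_union)
      dens <- insertion_density(union3, length(genome),
                                mean(genes$end - genes$start + 1))
      prof <- site_bias_profile(union3, genome,
                                seed = derive_seed(seed, "stats"))
      sat_N <- required_colonies(0.9999,
                                 mean(genes$end - genes$start + 1),
                                 length(genome))
      js <- list(n_unique = dens$n_unique,
                 mean_spacing_bp = dens$mean_spacing_bp,
                 expected_insertions_per_gene =
                   dens$expected_insertions_per_gene,
                 required_colonies_P9999 = sat_N,
                 max_bias_enrichment = prof$max_enrichment,
                 two_fold_flag = prof$two_fold_flag)
      jsonlite::write_json(js, paths$stats, auto_unbox = TRUE, digits = NA)
      bias_tab <- data.frame(offset = rep(prof$offsets, times = 4L),
                             base = rep(colnames(prof$site_freq),
                                        each = length(prof$offsets)),
                             site_freq = as.vector(prof$site_freq),
                             bg_freq = rep(prof$background_freq,
                                           each = length(prof$offsets)),
                             enrichment = as.vector(prof$enrichment))
      utils::write.table(bias_tab, paths$bias, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note_stage("stats", c(paths$stats, paths$bias), list(summary = js))
    }, error = function(e) fail("stats", e))
  }
  if ("phyletics" %in% stages) {
    tryCatch({
      scores <- read_scores_tsv(paths$scores)
      ess <- scores$gene_id[!is.na(scores$call) & scores$call == "essential"]
      pa <- simulate_presence_absence(
        n_orthologs_per_category = .scale_categories(length(ess)),
        seed = derive_seed(seed, "phyletics"))
      write_pa_matrix_tsv(pa$matrix, paths$pa)
      write_taxon_groups_tsv(pa$taxon_groups, paths$groups)
      counts <- category_counts(pa$matrix, pa$taxon_groups)
      utils::write.table(data.frame(category = rownames(counts), counts,
                                    check.names = FALSE),
                         paths$categories, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note_stage("phyletics", c(paths$pa, paths$groups, paths$categories),
                 list(n_orthologs = ncol(pa$matrix),
                      n_essential_focal = length(ess)))
    }, error = function(e) fail("phyletics", e))
  }
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

# scale the default category profile to a given total ortholog count
.scale_categories <- function(total) {
  base <- default_category_sizes()
  x <- round(base * total / sum(base))
  x[1] <- x[1] + (total - sum(x))
  x
}

#' Summarize a completed pipeline run
#'
#' Recomputes headline numbers from the stage output files (never from
#' internal state): consensus call counts, insertion spacing, saturation
#' planning numbers, bias flags and phyletic category counts. Missing stage
#' outputs are reported as absent.
#'
#' @param outdir a [run_pipeline()] output directory.
#' @return list of per-stage summaries; printed compactly.
#' @export
report_run <- function(outdir) {
  out <- list()
  f <- function(p) file.path(outdir, p)
  if (file.exists(f("scores.tsv"))) {
    scores <- read_scores_tsv(f("scores.tsv"))
    out$calls <- as.list(partition_counts(scores))
    out$n_genes <- nrow(scores)
  } else out$calls <- "absent"
  if (file.exists(f("library_stats.json"))) {
    out$library_stats <- jsonlite::read_json(f("library_stats.json"))
  } else out$library_stats <- "absent"
  if (file.exists(f("category_counts.tsv"))) {
    cc <- utils::read.delim(f("category_counts.tsv"), check.names = FALSE)
    out$category_counts <- stats::setNames(as.list(cc$all), cc$category)
  } else out$category_counts <- "absent"
  if (file.exists(f("manifest.json"))) {
    out$manifest_stages <-
      names(jsonlite::read_json(f("manifest.json"))$stages)
  }
  out
}
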