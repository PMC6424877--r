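# End-to-end composition: simulate (or load) -> classify -> consensus ->
# recruit -> presence -> assembly -> bin curation -> pathway scoring.

#' Build a pipeline run configuration
#'
#' A declarative configuration for [run_pipeline()]. All analysis parameters
#' surface here with their standard defaults: the whole-metagenome LCA
#' preset, 60/60 recruitment identity/coverage thresholds, 0.5% minority and
#' 0.1% selection thresholds, and the 1000 bp contig filter. With
#' `simulate = TRUE` (the default) the built-in synthetic community supplies
#' every input; otherwise file paths for the stages to run are given
#' (`taxonomy`, `hits`, `tools` — a named list of assignment TSVs —,
#' `reference`, `contigs`, plus optional `pathway_definitions` /
#' `gene_statuses`).
#'
#' @param sample sample label.
#' @param seed integer seed controlling every stochastic stage.
#' @param n_reads reads to simulate.
#' @param out_dir output directory (`NULL` = don't write).
#' @param simulate use the built-in synthetic community.
#' @param lca_preset preset name for [lca_params()].
#' @param priority tool priority order (highest first).
#' @param minority_threshold,selection_threshold consensus thresholds (%).
#' @param recruitment a [recruitment_params()].
#' @param min_contig_len contig length filter (bp).
#' @param target_genus genus taxon id for bin curation.
#' @param files named list of input file paths (non-simulated runs).
#' @return list of class `run_config`.
#' @export
run_config <- function(sample = "synthetic", seed = 1, n_reads = 20000,
                       out_dir = NULL, simulate = TRUE,
                       lca_preset = "megan-main",
                       priority = c("kaiju", "kraken", "blastn_nt",
                                    "blastn_refseq", "blastx_nr"),
                       minority_threshold = 0.5, selection_threshold = 0.1,
                       recruitment = recruitment_params(),
                       min_contig_len = 1000,
                       target_genus = "g_oenococcus",
                       files = list()) {
  for (f in unlist(files))
    if (!file.exists(f)) stop_kefirmg("input file not found: ", f)
  structure(list(sample = sample, seed = seed, n_reads = n_reads,
                 out_dir = out_dir, simulate = simulate,
                 lca_preset = lca_preset, priority = priority,
                 minority_threshold = minority_threshold,
                 selection_threshold = selection_threshold,
                 recruitment = recruitment,
                 min_contig_len = min_contig_len,
                 target_genus = target_genus, files = files),
            class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$recruitment)) y$recruitment <- do.call(recruitment_params,
                                                        y$recruitment)
  do.call(run_config, y)
}

#' Run the full profiling pipeline
#'
#' Executes every stage on one sample and (when `out_dir` is set) writes the
#' report bundle: per-read assignments, assignment summary, consensus genus
#' table and bar plot, recruitment table, matrix, plot and presence calls,
#' assembly statistics, the curated target-genus bin, the pathway call
#' matrix, and a manifest listing every output with an MD5 content hash,
#' the parameters and the seed. Re-running with the same configuration
#' reproduces identical payloads.
#'
#' @param config a [run_config()] (or YAML path).
#' @return Invisibly, a list with the per-stage results.
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(seed = 7, n_reads = 2000))
#' res$presence$gen_o_oeni$status     # "novel_relative"
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  f <- config$files

  tax <- if (!is.null(f$taxonomy)) read_taxonomy(f$taxonomy) else
    example_taxonomy()
  db <- if (!is.null(f$reference)) reference_db(read_tsv_schema(f$reference))
  else example_reference_db()

  if (config$simulate) {
    community <- example_community()
    sim <- generate_reads(community, config$n_reads, config$seed)
    hits <- generate_alignment_hits(sim$reads, db, config$seed + 1L)
    tools <- generate_tool_assignments(sim$truth, example_tool_profiles(),
                                       tax, config$seed + 2L)
    truth <- sim$truth
    total_reads <- config$n_reads
  } else {
    if (is.null(f$hits)) stop_kefirmg("non-simulated runs need files$hits")
    hits <- read_hits(f$hits)
    tools <- lapply(f$tools, read_assignments)
    truth <- NULL
    total_reads <- config$n_reads
  }

  params <- lca_params(preset = config$lca_preset)
  lca_assign <- assign_reads(hits, tax, params, source = "lca")
  lca_summary <- summarize_assignments(lca_assign, total_reads)

  priority <- intersect(config$priority, names(tools))
  consensus <- consensus_assign(tools, priority = priority,
                                reads = if (!is.null(truth)) truth$read_id)
  genus_table <- build_genus_table(
    consensus, tax, total_reads, sample = config$sample,
    minority_threshold = config$minority_threshold)

  recruited <- recruit_top_hits(hits, db, config$recruitment)
  recr_table <- recruitment_percentages(recruited, total_reads, db)
  matrix <- build_matrix(recruited, db,
                         genomes = db$genome_id[db$genus ==
                                                  config$target_genus],
                         params = config$recruitment)
  presence <- lapply(stats::setNames(db$genome_id, db$genome_id),
                     function(g) call_presence(recruited, db, g,
                                               config$recruitment))

  contigs <- if (!is.null(f$contigs)) contig_set(read_tsv_schema(f$contigs))
  else generate_contig_set(800, config$seed + 3L)$contigs
  contigs_kept <- filter_contigs(contigs, config$min_contig_len)
  asm_stats <- compute_stats(contigs_kept)

  bin_fix <- generate_bin_fixture(config$seed + 4L, tax = tax,
                                  target_genus = config$target_genus)
  curated <- purify_bin(bin_fix$bin, bin_fix$contigs, tax)
  curated <- add_rrna_contigs(curated, bin_fix$contigs, config$target_genus)

  defs <- if (!is.null(f$pathway_definitions))
    read_pathway_definitions(f$pathway_definitions) else example_pathways()
  statuses <- if (!is.null(f$gene_statuses)) read_gene_statuses(f$gene_statuses)
  else generate_gene_status_table(defs, unique(db$species),
                                  config$seed + 5L)$statuses
  pathway_calls <- score_matrix(statuses, defs)

  results <- list(config = config, taxonomy = tax, db = db,
                  lca_assignments = lca_assign, lca_summary = lca_summary,
                  consensus = consensus, genus_table = genus_table,
                  recruited = recruited, recruitment_table = recr_table,
                  matrix = matrix, presence = presence,
                  assembly_stats = asm_stats, curated_bin = curated,
                  pathway_calls = pathway_calls, truth = truth)
  if (!is.null(config$out_dir)) write_report(results, config$out_dir)
  invisible(results)
}

#' Write the report bundle of a pipeline run
#'
#' Stage-scoped subdirectories, headered TSVs with stable column orders,
#' floats at two decimals in report tables (full precision retained in the
#' returned objects), and a `manifest.json` hashing every file.
#'
#' @param results the list returned by [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_report <- function(results, out_dir) {
  dirs <- file.path(out_dir, c("classify", "consensus", "recruitment",
                               "assembly", "pathways"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  out <- character()
  emit <- function(path, writer) { writer(path); out <<- c(out, path); path }

  emit(file.path(out_dir, "classify", "assignments.tsv"),
       function(p) write_assignments(results$lca_assignments, p))
  emit(file.path(out_dir, "classify", "summary.tsv"), function(p)
    write_tsv_schema(transform(results$lca_summary,
                               percent = round(percent, 2)),
                     p, "assignment_summary v1"))
  emit(file.path(out_dir, "consensus", "consensus_assignments.tsv"),
       function(p) write_assignments(results$consensus, p))
  emit(file.path(out_dir, "consensus", "genus_table.tsv"),
       function(p) write_genus_table(results$genus_table, p))
  emit(file.path(out_dir, "consensus", "genus_bars.png"),
       function(p) plot_genus_bars(list(results$genus_table), p))
  emit(file.path(out_dir, "recruitment", "recruitment_table.tsv"),
       function(p) write_tsv_schema(
         transform(results$recruitment_table, percent = round(percent, 2)),
         p, "recruitment_table v1"))
  emit(file.path(out_dir, "recruitment", "matrix.tsv"),
       function(p) write_matrix(results$matrix, p))
  emit(file.path(out_dir, "recruitment", "recruitment_plot.png"),
       function(p) plot_recruitment(results$matrix, p))
  emit(file.path(out_dir, "recruitment", "presence_calls.json"),
       function(p) jsonlite::write_json(results$presence, p,
                                        auto_unbox = TRUE, digits = NA))
  emit(file.path(out_dir, "assembly", "assembly_stats.json"),
       function(p) jsonlite::write_json(unclass(results$assembly_stats), p,
                                        auto_unbox = TRUE, digits = NA))
  emit(file.path(out_dir, "assembly", "assembly_stats.tsv"), function(p)
    write_tsv_schema(format_assembly_stats(results$assembly_stats), p,
                     "assembly_stats v1"))
  emit(file.path(out_dir, "assembly", "curated_bin.tsv"), function(p)
    write_tsv_schema(data.frame(contig_id = results$curated_bin), p,
                     "curated_bin v1"))
  emit(file.path(out_dir, "pathways", "pathway_calls.tsv"), function(p)
    write_tsv_schema(transform(results$pathway_calls,
                               call = as.character(call)),
                     p, "pathway_calls v1"))
  emit(file.path(out_dir, "pathways", "pathway_matrix.png"),
       function(p) plot_pathway_matrix(results$pathway_calls, p))

  manifest <- list(
    schema = "kefirmg_manifest v1",
    sample = results$config$sample,
    seed = results$config$seed,
    parameters = results$config[c("lca_preset", "priority",
                                  "minority_threshold",
                                  "selection_threshold", "min_contig_len",
                                  "target_genus")],
    recruitment_params = unclass(results$config$recruitment),
    created = format(Sys.time(), tz = "UTC"),
    files = lapply(out, function(p)
      list(path = sub(paste0("^", out_dir, "/?"), "", p),
           md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
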