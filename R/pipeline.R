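#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML (or plain list) with:
#'
#' * `mode` — `"cell"` or `"nucleus"`; `seed` — integer, recorded in every
#'   output;
#' * `inputs` — `gtf`, `sam`, optional `genome` (FASTA, enables the polyA
#'   diagnostic), optional `groups` (TSV barcode/label) and `bulk`
#'   (gene x sample TSV of counts, enables the correlation report);
#' * `whitelist_min_reads` — barcode threshold (default 30000);
#' * `qc` — overrides for [qc_config()] fields;
#' * `polya` — `min_len`, `flank`, `bin_width` (defaults 5, 20, 5);
#' * `loading` — optional `concentration` (per mL) and `droplet_volume`
#'   (pL) for the Poisson loading report.
#'
#' Every referenced input file must exist at validation time.
#'
#' @param config Path to a YAML file, or a list with the fields above.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s",
                                            config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$mode <- match.arg(config$mode %||% "nucleus", c("cell", "nucleus"))
  config$seed <- as.integer(config$seed %||% 1L)
  config$whitelist_min_reads <-
    as.integer(config$whitelist_min_reads %||% 30000L)
  qc_args <- config$qc %||% list()
  config$qc <- do.call(qc_config, qc_args)
  pa <- config$polya %||% list()
  config$polya <- list(min_len = as.integer(pa$min_len %||% 5L),
                       flank = as.integer(pa$flank %||% 20L),
                       bin_width = as.integer(pa$bin_width %||% 5L))
  req <- c("gtf", "sam")
  for (f in req) {
    if (is.null(config$inputs[[f]])) {
      abort(sprintf("config inputs must name a '%s' file", f))
    }
  }
  for (f in c("gtf", "sam", "genome", "groups", "bulk")) {
    p <- config$inputs[[f]]
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("input '%s' does not exist: %s", f, p))
    }
  }
  structure(config, class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(
    config[sort(names(config))], tmp,
    auto_unbox = TRUE, digits = NA, force = TRUE
  )
  unname(tools::md5sum(tmp))
}

#' Run the full quantification pipeline
#'
#' Executes the pipeline end to end: annotation parsing and intron
#' derivation, alignment import, barcode whitelisting, feature assignment,
#' UMI counting in both exon-only and exon+intron modes, QC filtering and
#' summaries, the polyA internal-priming diagnostic (when a genome is
#' supplied), the Poisson loading report (when loading parameters are
#' supplied), and a pseudo-bulk correlation report (when group labels and a
#' bulk table are supplied). Every output directory gets a
#' `manifest.json` recording inputs, parameters, the seed, the config hash
#' and md5 checksums of all outputs; deterministic stages reproduce their
#' checksums on a re-run with the same config.
#'
#' @param config A [pipeline_config()] (or path / list accepted by it).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest` (the manifest path).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  outputs <- character()
  emit <- function(name) {
    p <- file.path(out_dir, name)
    outputs <<- c(outputs, p)
    p
  }

  inform("stage 1/6: annotation")
  genes <- derive_introns(read_gene_models(config$inputs$gtf))
  write_intervals(genes, "exon", emit("exons.bed"))
  write_intervals(genes, "intron", emit("introns.bed"))

  inform("stage 2/6: alignments + whitelist")
  reads <- read_sam(config$inputs$sam)
  bc <- reads |> count(barcode = .data$cell_barcode, name = "reads")
  wl <- build_whitelist(bc, min_reads = config$whitelist_min_reads)
  n_in <- nrow(reads)
  reads <- filter(reads, .data$cell_barcode %in% wl$barcode)
  inform(sprintf("  %d/%d reads on %d whitelisted barcodes",
                 nrow(reads), n_in, nrow(wl)))

  inform("stage 3/6: feature assignment")
  assignments <- assign_reads(reads, genes)
  fr <- region_fractions(assignments)
  utils::write.table(fr, emit("region_fractions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  inform("stage 4/6: UMI counting")
  both <- count_umis(assignments, "exon_plus_intron")
  exon <- count_umis(assignments, "exon_only",
                     gene_ids = rownames(both$counts),
                     cell_barcodes = colnames(both$counts))
  write_counts(both, file.path(out_dir, "counts_exon_plus_intron"))
  write_counts(exon, file.path(out_dir, "counts_exon_only"))
  outputs <- c(outputs, file.path(out_dir, paste0(
    "counts_", rep(c("exon_plus_intron", "exon_only"), each = 4),
    c(".mtx", ".genes.tsv", ".barcodes.tsv", ".meta.json")
  )))

  inform("stage 5/6: QC")
  filtered <- filter_matrix(both, config$qc, mode = config$mode)
  summaries <- per_cell_summary(both, assignments)
  utils::write.table(summaries, emit("cell_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gain <- glance(detection_gain(exon, both))
  qc_report <- list(
    seed = config$seed, mode = config$mode,
    n_reads = n_in, n_whitelisted_reads = nrow(reads),
    region_fractions = setNames(as.list(fr$fraction), fr$region),
    cells_before_filter = ncol(both$counts),
    cells_after_filter = ncol(filtered$counts),
    genes_after_filter = nrow(filtered$counts),
    mean_detection_gain = gain$mean_gain,
    top_genes = top_gene_fractions(both)
  )
  jsonlite::write_json(qc_report, emit("qc_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  priming <- NULL
  if (!is.null(config$inputs$genome)) {
    inform("stage 6/6: polyA internal-priming diagnostic")
    tracts <- scan_polya(config$inputs$genome,
                         min_len = config$polya$min_len)
    hits <- intersect_intronic(tracts, assignments,
                               flank = config$polya$flank)
    hist <- motif_position_histogram(hits, flank = config$polya$flank,
                                     bin_width = config$polya$bin_width)
    utils::write.table(as_tibble(hist), emit("priming_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    priming <- list(
      n_tracts = nrow(tracts),
      polya_read_fraction = polya_read_fraction(hits, assignments),
      enrichment_3prime = glance(hist)$enrichment_3prime
    )
    jsonlite::write_json(priming, emit("priming_report.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    inform("stage 6/6: no genome supplied; skipping polyA diagnostic")
  }

  loading <- NULL
  if (!is.null(config$loading)) {
    lam <- loading_lambda(config$loading$concentration,
                          config$loading$droplet_volume)
    loading <- list(
      lambda = lam,
      droplets_per_ml = droplets_per_ml(config$loading$droplet_volume)$raw,
      doublet_fraction = doublet_fraction(lam)
    )
    jsonlite::write_json(loading, emit("loading_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  correlation <- NULL
  if (!is.null(config$inputs$groups) && !is.null(config$inputs$bulk)) {
    groups <- utils::read.table(config$inputs$groups, header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
    bulk <- as.matrix(utils::read.table(config$inputs$bulk, header = TRUE,
                                        sep = "\t", row.names = 1,
                                        check.names = FALSE))
    bulk_log <- log1p(sweep(bulk, 2, colSums(bulk), "/") * 1e4)
    pb <- pseudobulk_profiles(filtered, groups)
    gs <- select_correlation_genes(pb, bulk_log)
    correlation <- correlate_profiles(pb, bulk_log, gs)
    utils::write.table(unclass(correlation), emit("correlation.tsv"),
                       sep = "\t", quote = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("nucquant")),
    seed = config$seed,
    mode = config$mode,
    config_hash = config_hash(unclass(config)),
    inputs = config$inputs,
    input_checksums = as.list(tools::md5sum(unlist(config$inputs))),
    parameters = list(
      whitelist_min_reads = config$whitelist_min_reads,
      qc = unclass(config$qc), polya = config$polya
    ),
    read_conservation = list(
      input = n_in, whitelisted = nrow(reads),
      assigned = setNames(as.list(fr$reads), fr$region)
    ),
    outputs = as.list(tools::md5sum(outputs))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(
    genes = genes, assignments = assignments,
    counts_both = both, counts_exon = exon, filtered = filtered,
    qc_report = qc_report, priming = priming, loading = loading,
    correlation = correlation, manifest = manifest_path
  ))
}

#' Write a complete synthetic dataset to disk
#'
#' Convenience wrapper: generates genome, annotation, tracts, reads, and
#' truth under one seed and writes FASTA, GTF, BED, SAM, and truth TSV into
#' a directory, ready for [run_pipeline()].
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list of the written paths plus the in-memory
#'   simulation objects.
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_genome_annotation(config)
  expr <- simulate_expression(config, ann)
  sim <- simulate_reads(config, ann, expr)
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gtf = file.path(out_dir, "annotation.gtf"),
    tracts = file.path(out_dir, "planted_tracts.bed"),
    sam = file.path(out_dir, "reads.sam"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_sim_fasta(ann, paths$genome)
  write_sim_gtf(ann, paths$gtf)
  write_sim_tracts(ann, paths$tracts)
  write_sam(sim$reads, ann$chrom_lengths, paths$sam)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, list(ann = ann, expr = expr, sim = sim)))
}
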