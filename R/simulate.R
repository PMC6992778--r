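#' Configuration for the synthetic droplet RNA-seq generator
#'
#' The generator emulates the two library types the package compares:
#' `"cell"` mode mimics a whole-cell (Drop-seq style) run — ~7% intronic
#' reads, mitochondrial/ribosomal genes enriched, ~1474 mean UMIs per cell —
#' and `"nucleus"` mode mimics a single-nucleus (DroNc-seq style) run —
#' ~50% intronic reads from unspliced transcripts, lncRNAs enriched, a
#' shallower ~721 mean UMIs per nucleus. PolyA tracts are planted inside
#' introns and a configurable fraction of intronic reads is emitted with its
#' 3' end at a planted tract, emulating internal priming on the polydT
#' primer.
#'
#' @param seed Mandatory random seed; every generator output is
#'   deterministic given the seed.
#' @param mode `"nucleus"` or `"cell"`.
#' @param n_chroms,chrom_length Number and length (bp) of synthetic
#'   chromosomes.
#' @param n_genes Number of non-overlapping genes.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene
#'   (default 2-4, so every gene has at least one intron).
#' @param exon_length,intron_length Ranges (bp) for exon and intron lengths.
#'   Introns default to at least 300 bp, comfortably above read length plus
#'   both flanks, so intronic reads are unambiguous.
#' @param read_length cDNA read length (default 60).
#' @param n_cells Number of cell barcodes.
#' @param mean_umis Mean molecules per cell; default 721 (nucleus) or 1474
#'   (cell).
#' @param umi_dispersion Negative-binomial size for per-cell totals.
#' @param intronic_fraction Probability a molecule's read is intronic;
#'   default 0.50 (nucleus) or 0.07 (cell).
#' @param internal_priming_rate Fraction of intronic reads emitted with
#'   their 3' end at a planted polyA tract (default 0.4).
#' @param tract_density Probability an intron receives one planted polyA
#'   tract (default 1).
#' @param tract_length Range (bp) of planted tract lengths.
#' @param lncrna_fraction,mito_fraction,ribo_fraction Biotype composition
#'   of the gene set (remainder protein-coding).
#' @param lncrna_enrichment Expression multiplier for lncRNA genes in
#'   nucleus mode (nuclear retention).
#' @param mito_ribo_enrichment Multiplier for mitochondrial/ribosomal genes
#'   in cell mode (cytoplasmic abundance).
#' @param n_populations Number of cell populations with distinct expression
#'   profiles.
#' @param population_de_fraction,population_effect Fraction of genes
#'   up-weighted per population and the multiplier applied.
#' @param duplication_rate Mean extra PCR-duplicate reads per molecule.
#' @param doublet_rate Fraction of barcodes merging two cells' molecules.
#' @param species_mixing_fraction If non-`NULL`, barnyard mode: each
#'   underlying cell is species A with this probability, else species B.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       mode = c("nucleus", "cell"),
                       n_chroms = 2L,
                       chrom_length = 250000L,
                       n_genes = 120L,
                       exons_per_gene = c(2L, 4L),
                       exon_length = c(150L, 300L),
                       intron_length = c(300L, 800L),
                       read_length = 60L,
                       n_cells = 500L,
                       mean_umis = NULL,
                       umi_dispersion = 10,
                       intronic_fraction = NULL,
                       internal_priming_rate = 0.4,
                       tract_density = 1,
                       tract_length = c(8L, 14L),
                       lncrna_fraction = 0.15,
                       mito_fraction = 0.05,
                       ribo_fraction = 0.05,
                       lncrna_enrichment = 4,
                       mito_ribo_enrichment = 4,
                       n_populations = 2L,
                       population_de_fraction = 0.2,
                       population_effect = 4,
                       duplication_rate = 0.3,
                       doublet_rate = 0,
                       species_mixing_fraction = NULL) {
  if (missing(seed)) abort("a seed is mandatory")
  mode <- match.arg(mode)
  cfg <- list(
    seed = as.integer(seed), mode = mode,
    n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    read_length = as.integer(read_length),
    n_cells = as.integer(n_cells),
    mean_umis = mean_umis %||% if (mode == "nucleus") 721 else 1474,
    umi_dispersion = umi_dispersion,
    intronic_fraction = intronic_fraction %||%
      if (mode == "nucleus") 0.50 else 0.07,
    internal_priming_rate = internal_priming_rate,
    tract_density = tract_density,
    tract_length = as.integer(tract_length),
    lncrna_fraction = lncrna_fraction,
    mito_fraction = mito_fraction,
    ribo_fraction = ribo_fraction,
    lncrna_enrichment = lncrna_enrichment,
    mito_ribo_enrichment = mito_ribo_enrichment,
    n_populations = as.integer(n_populations),
    population_de_fraction = population_de_fraction,
    population_effect = population_effect,
    duplication_rate = duplication_rate,
    doublet_rate = doublet_rate,
    species_mixing_fraction = species_mixing_fraction
  )
  fr <- c(cfg$intronic_fraction, cfg$internal_priming_rate, cfg$tract_density,
          cfg$lncrna_fraction, cfg$mito_fraction, cfg$ribo_fraction,
          cfg$population_de_fraction, cfg$doublet_rate)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (!is.null(cfg$species_mixing_fraction) &&
      (cfg$species_mixing_fraction <= 0 || cfg$species_mixing_fraction >= 1)) {
    abort("species_mixing_fraction must be in (0, 1)")
  }
  if (cfg$intron_length[1] < cfg$read_length + 2L * 20L + 2L) {
    abort("minimum intron length must exceed read length plus both flanks")
  }
  structure(cfg, class = "sim_config")
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_kmers <- function(n, k) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), nrow = n)
  out <- do.call(paste0, as.data.frame(m))
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    m <- matrix(sample(c("A", "C", "G", "T"), length(dup) * k, replace = TRUE),
                nrow = length(dup))
    out[dup] <- do.call(paste0, as.data.frame(m))
  }
  out
}

#' Generate a synthetic genome and annotation with planted polyA tracts
#'
#' Builds `n_chroms` random-sequence chromosomes carrying non-overlapping
#' genes with known exon/intron structure, plants a polyA tract (A-run on
#' `+` genes, T-run on `-` genes, i.e. an A-run on the transcript strand)
#' inside introns at the configured density, and records everything in
#' generator truth. Deterministic under the config seed: identical configs
#' give byte-identical FASTA/GTF output.
#'
#' Planted tracts keep >= 80 bp clearance to both intron boundaries so an
#' internally primed read and its flanks always fit inside the intron.
#'
#' @param config A [sim_config()].
#' @return A `sim_annotation` list: `genome` (`DNAStringSet`), `genes`
#'   (a `gene_models` tibble with introns populated), `tracts` (tibble of
#'   planted tracts), `chrom_lengths`, `config`.
#' @export
simulate_genome_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))

  # per-gene structure
  n <- config$n_genes
  k <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]),
              n, replace = TRUE)
  structures <- map(k, function(ki) {
    ex <- sample(seq(config$exon_length[1], config$exon_length[2]), ki,
                 replace = TRUE)
    iv <- if (ki > 1) {
      sample(seq(config$intron_length[1], config$intron_length[2]), ki - 1,
             replace = TRUE)
    } else integer(0)
    list(exons = ex, introns = iv)
  })

  # biotypes
  n_lnc <- round(config$lncrna_fraction * n)
  n_mito <- round(config$mito_fraction * n)
  n_ribo <- round(config$ribo_fraction * n)
  biotype <- sample(c(
    rep("lncRNA", n_lnc), rep("mitochondrial", n_mito),
    rep("ribosomal", n_ribo),
    rep("protein_coding", n - n_lnc - n_mito - n_ribo)
  ))

  # place genes round-robin across chromosomes, left to right
  chrom_of <- rep(chroms, length.out = n)
  cursor <- setNames(rep(500L, length(chroms)), chroms)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    st <- structures[[i]]
    glen <- sum(st$exons) + sum(st$introns)
    ch <- chrom_of[i]
    gap <- sample(200:600, 1)
    gstart <- cursor[ch] + gap
    if (gstart + glen > config$chrom_length) {
      abort(sprintf(
        "genes do not fit on %s (need > %d bp); increase chrom_length",
        ch, gstart + glen
      ))
    }
    cursor[ch] <- gstart + glen
    # alternate exon/intron blocks from the gene start
    block_len <- as.vector(rbind(
      c(st$exons, NA)[seq_along(st$exons)],
      c(st$introns, NA)[seq_along(st$exons)]
    ))
    block_len <- block_len[!is.na(block_len)]
    ends <- unname(gstart + cumsum(block_len))
    starts <- unname(c(gstart, ends[-length(ends)]))
    is_exon <- seq_along(block_len) %% 2 == 1
    rows[[i]] <- list(
      chrom = ch, start = gstart, end = gstart + glen,
      strand = sample(c("+", "-"), 1),
      exons = tibble(start = starts[is_exon], end = ends[is_exon]),
      introns = if (any(!is_exon)) {
        tibble(start = starts[!is_exon], end = ends[!is_exon])
      } else tibble(start = integer(), end = integer())
    )
  }

  name_of <- function(bt, i) {
    switch(bt,
      mitochondrial = sprintf("MT-G%04d", i),
      ribosomal = sprintf("RPL%04d", i),
      lncRNA = sprintf("LINC%04d", i),
      sprintf("GENE%04d", i)
    )
  }
  genes <- tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    gene_name = map_chr(seq_len(n), function(i) name_of(biotype[i], i)),
    biotype = biotype,
    chrom = map_chr(rows, "chrom"),
    start = map_int(rows, function(r) as.integer(r$start)),
    end = map_int(rows, function(r) as.integer(r$end)),
    strand = map_chr(rows, "strand"),
    exons = map(rows, "exons"),
    introns = map(rows, "introns")
  )
  genes <- new_gene_models(genes)

  # random genome, then plant tracts inside introns
  seqs <- setNames(
    vapply(chroms, function(ch) rand_seq(config$chrom_length), character(1)),
    chroms
  )
  margin <- 80L
  tract_rows <- list()
  for (i in seq_len(n)) {
    ivs <- genes$introns[[i]]
    if (nrow(ivs) == 0) next
    for (j in seq_len(nrow(ivs))) {
      if (stats::runif(1) > config$tract_density) next
      L <- sample(seq(config$tract_length[1], config$tract_length[2]), 1)
      lo <- ivs$start[j] + margin
      hi <- ivs$end[j] - margin - L
      if (hi <= lo) next
      ts <- sample(lo:hi, 1)
      base <- if (genes$strand[i] == "+") "A" else "T"
      ch <- genes$chrom[i]
      substr(seqs[[ch]], ts + 1L, ts + L) <-
        paste(rep(base, L), collapse = "")
      tract_rows[[length(tract_rows) + 1]] <- tibble(
        chrom = ch, start = ts, end = ts + L, strand = genes$strand[i],
        length = L, gene_id = genes$gene_id[i]
      )
    }
  }
  tracts <- bind_rows(tract_rows)
  if (nrow(tracts) == 0) {
    tracts <- tibble(chrom = character(), start = integer(), end = integer(),
                     strand = character(), length = integer(),
                     gene_id = character())
  }

  structure(list(
    genome = Biostrings::DNAStringSet(seqs),
    genes = genes,
    tracts = tracts,
    chrom_lengths = setNames(rep(config$chrom_length, length(chroms)),
                             chroms),
    config = config
  ), class = "sim_annotation")
}

#' Write simulator outputs to standard formats
#'
#' @param ann A `sim_annotation` from [simulate_genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_fasta <- function(ann, path) {
  Biostrings::writeXStringSet(ann$genome, path)
  invisible(path)
}

#' @rdname write_sim_fasta
#' @export
write_sim_gtf <- function(ann, path) {
  g <- ann$genes
  lines <- character()
  for (i in seq_len(nrow(g))) {
    attrs <- sprintf(
      'gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
      g$gene_id[i], g$gene_name[i], g$biotype[i]
    )
    lines <- c(lines, sprintf(
      "%s\tnucquant_sim\tgene\t%d\t%d\t.\t%s\t.\t%s",
      g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i], attrs
    ))
    ex <- g$exons[[i]]
    lines <- c(lines, sprintf(
      "%s\tnucquant_sim\texon\t%d\t%d\t.\t%s\t.\t%s",
      g$chrom[i], ex$start + 1L, ex$end, g$strand[i], attrs
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_fasta
#' @export
write_sim_tracts <- function(ann, path) {
  tr <- ann$tracts
  if (nrow(tr) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- intervals_to_granges(tr)
  names(gr) <- tr$gene_id
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Simulate per-cell true molecule counts
#'
#' Gamma-Poisson style expression: gene weights are Gamma-distributed with
#' biotype enrichment applied (lncRNA up in nucleus mode, mitochondrial and
#' ribosomal genes up in cell mode), per-population multipliers create
#' distinct cell populations, per-cell totals are negative-binomial around
#' `mean_umis`, and molecules are multinomially allocated to genes.
#'
#' @param config A [sim_config()].
#' @param ann A `sim_annotation`.
#' @return A `sim_expression` list: `cells` (tibble `cell_barcode`,
#'   `population`, `species`, `is_doublet`), `molecules` (tibble
#'   `cell_barcode`, `gene_id`, `molecules`, `species`), and
#'   `population_profiles` (genes x populations expected-weight matrix).
#' @export
simulate_expression <- function(config, ann) {
  stopifnot(inherits(config, "sim_config"), inherits(ann, "sim_annotation"))
  set.seed(config$seed + 1L)
  genes <- ann$genes
  ng <- nrow(genes)

  w <- rgamma(ng, shape = 0.6, rate = 1) + 1e-4
  if (config$mode == "nucleus") {
    w[genes$biotype == "lncRNA"] <-
      w[genes$biotype == "lncRNA"] * config$lncrna_enrichment
  } else {
    sel <- genes$biotype %in% c("mitochondrial", "ribosomal")
    w[sel] <- w[sel] * config$mito_ribo_enrichment
  }

  pops <- paste0("pop", seq_len(config$n_populations))
  pop_w <- vapply(pops, function(p) {
    wp <- w
    up <- sample(ng, round(config$population_de_fraction * ng))
    wp[up] <- wp[up] * config$population_effect
    wp / sum(wp)
  }, numeric(ng))
  rownames(pop_w) <- genes$gene_id

  n_doublets <- round(config$doublet_rate * config$n_cells)
  n_source <- config$n_cells + n_doublets
  src_pop <- sample(pops, n_source, replace = TRUE)
  src_species <- if (is.null(config$species_mixing_fraction)) {
    rep("A", n_source)
  } else {
    ifelse(stats::runif(n_source) < config$species_mixing_fraction, "A", "B")
  }
  src_total <- stats::rnbinom(n_source, mu = config$mean_umis,
                              size = config$umi_dispersion)
  src_total <- pmax(src_total, 1L)

  barcodes <- rand_kmers(config$n_cells, 12L)
  # barcode i < n_doublets additionally receives source cell n_cells + i
  src_barcode <- c(
    barcodes,
    if (n_doublets > 0) barcodes[seq_len(n_doublets)] else character(0)
  )

  mol <- map(seq_len(n_source), function(s) {
    cnt <- rmultinom(1, src_total[s], pop_w[, src_pop[s]])[, 1]
    nz <- cnt > 0
    tibble(
      cell_barcode = src_barcode[s],
      gene_id = genes$gene_id[nz],
      molecules = as.integer(cnt[nz]),
      species = src_species[s]
    )
  })
  molecules <- bind_rows(mol)

  cells <- tibble(
    cell_barcode = barcodes,
    population = src_pop[seq_len(config$n_cells)],
    species = src_species[seq_len(config$n_cells)],
    is_doublet = seq_len(config$n_cells) <= n_doublets
  )
  structure(list(
    cells = cells, molecules = molecules, population_profiles = pop_w
  ), class = "sim_expression")
}

#' Emit aligned reads with generator-known truth
#'
#' Every molecule becomes one or more reads sharing its (cell, UMI). Each
#' molecule's read is intronic with probability `intronic_fraction`
#' (requires the gene to have an intron) and exonic otherwise; reads are
#' placed entirely inside a single exon or intron, on the gene's strand.
#' Among intronic reads, a fraction `internal_priming_rate` is placed so its
#' 3' end sits 40-75 bp downstream of the read 5' end at a planted polyA
#' tract's 3' end — the internal-priming signature. Genes without introns
#' are skipped (with a warning) when an intronic fraction is requested.
#'
#' @param config A [sim_config()].
#' @param ann A `sim_annotation`.
#' @param expr A `sim_expression`.
#' @return A `sim_reads` list: `reads` (aligned-read tibble: `read_id`,
#'   `cell_barcode`, `umi`, `chrom`, `start`, `end`, `strand`,
#'   `is_primary`) and `truth` (same rows plus `gene_id`, `region`,
#'   `primed`, `species`).
#' @export
simulate_reads <- function(config, ann, expr) {
  stopifnot(inherits(config, "sim_config"), inherits(ann, "sim_annotation"),
            inherits(expr, "sim_expression"))
  set.seed(config$seed + 2L)
  genes <- ann$genes
  rl <- config$read_length

  has_intron <- vapply(genes$introns, nrow, integer(1)) > 0
  mol <- expr$molecules
  if (config$intronic_fraction > 0 && any(!has_intron)) {
    dropped <- genes$gene_id[!has_intron]
    n_drop <- sum(mol$gene_id %in% dropped)
    if (n_drop > 0) {
      warn(sprintf(
        "intronic fraction > 0: skipping %d molecule(s) of %d intron-less gene(s)",
        n_drop, length(dropped)
      ))
      mol <- filter(mol, !.data$gene_id %in% dropped)
    }
  }

  # expand to one row per molecule
  per_mol <- tibble(
    cell_barcode = rep(mol$cell_barcode, mol$molecules),
    gene_id = rep(mol$gene_id, mol$molecules),
    species = rep(mol$species, mol$molecules)
  )
  nm <- nrow(per_mol)
  per_mol$umi <- rand_umis(nm)
  per_mol$region <- ifelse(stats::runif(nm) < config$intronic_fraction,
                           "intronic", "exonic")
  per_mol$primed <- per_mol$region == "intronic" &
    stats::runif(nm) < config$internal_priming_rate

  gene_lut <- setNames(seq_len(nrow(genes)), genes$gene_id)
  tract_by_gene <- split(ann$tracts, ann$tracts$gene_id)

  placed <- map(split(per_mol, per_mol$gene_id), function(block) {
    gi <- gene_lut[[block$gene_id[1]]]
    place_reads_for_gene(block, genes[gi, ], tract_by_gene, rl)
  })
  truth <- bind_rows(placed)

  # PCR duplicates: extra reads identical to their molecule's read
  extra <- rpois(nrow(truth), config$duplication_rate)
  truth <- truth[rep(seq_len(nrow(truth)), 1L + extra), , drop = FALSE]
  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  truth$read_id <- seq_len(nrow(truth))
  truth$is_primary <- TRUE
  truth <- as_tibble(truth)

  reads <- select(truth, "read_id", "cell_barcode", "umi", "chrom",
                  "start", "end", "strand", "is_primary")
  structure(list(reads = reads, truth = truth), class = "sim_reads")
}

rand_umis <- function(n) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * 8L, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m))
}

# place every read of one gene; block has region/primed flags already drawn
place_reads_for_gene <- function(block, gene, tract_by_gene, rl) {
  n <- nrow(block)
  strand <- gene$strand
  ex <- gene$exons[[1]]
  iv <- gene$introns[[1]]
  tr <- tract_by_gene[[gene$gene_id]]

  pick_interval <- function(pool, m) {
    fit <- pool[pool$end - pool$start >= rl, , drop = FALSE]
    wts <- fit$end - fit$start - rl + 1L
    idx <- sample.int(nrow(fit), m, replace = TRUE, prob = wts)
    start <- fit$start[idx] +
      floor(stats::runif(m) * (fit$end[idx] - fit$start[idx] - rl + 1L))
    as.integer(start)
  }

  start <- integer(n)
  is_ex <- block$region == "exonic"
  if (any(is_ex)) start[is_ex] <- pick_interval(ex, sum(is_ex))

  primed <- block$primed
  plain_in <- !is_ex & !primed
  if (any(plain_in)) start[plain_in] <- pick_interval(iv, sum(plain_in))

  if (any(primed)) {
    if (is.null(tr) || nrow(tr) == 0) {
      # no planted tract in this gene: fall back to plain intronic placement
      start[primed] <- pick_interval(iv, sum(primed))
      block$primed[primed] <- FALSE
    } else {
      m <- sum(primed)
      ti <- sample.int(nrow(tr), m, replace = TRUE)
      off <- sample(40:75, m, replace = TRUE)
      if (strand == "+") {
        # offset = tract_end - read_start
        start[primed] <- as.integer(tr$end[ti] - off)
      } else {
        # offset = read_end - tract_start (mirrored orientation)
        start[primed] <- as.integer(tr$start[ti] + off - rl)
      }
    }
  }

  tibble(
    cell_barcode = block$cell_barcode,
    umi = block$umi,
    gene_id = block$gene_id,
    species = block$species,
    region = block$region,
    primed = block$primed,
    chrom = gene$chrom,
    start = start,
    end = start + rl,
    strand = strand
  )
}

#' Per-barcode species read counts from generator truth
#'
#' @param truth Truth tibble from [simulate_reads()].
#' @return Tibble with `barcode`, `species_a`, `species_b` for
#'   [species_mixing_doublets()].
#' @export
barnyard_counts <- function(truth) {
  truth |>
    group_by(barcode = .data$cell_barcode) |>
    summarise(
      species_a = sum(.data$species == "A"),
      species_b = sum(.data$species == "B"),
      .groups = "drop"
    )
}

#' Generator-truth recovery references
#'
#' Quantities computed straight from the truth table (and, for the polyA
#' fraction, from the emitted genome sequence itself), against which the
#' pipeline's estimates are compared in parameter-recovery tests.
#'
#' `truth_detection_gain()`: per cell, genes with any molecule over genes
#' with at least one exonic read, averaged over cells with nonzero exonic
#' detection. `truth_polya_fraction()`: fraction of emitted intronic reads
#' whose 20 bp-flanked window contains a >= `min_len` A-run (T-run for `-`
#' reads), found by direct substring inspection of the genome — an
#' independent route from the interval-intersection pipeline.
#'
#' @param truth Truth tibble from [simulate_reads()].
#' @param ann A `sim_annotation`.
#' @param flank,min_len Window flank and minimum run length.
#' @return A single number.
#' @export
truth_detection_gain <- function(truth) {
  per_cell <- truth |>
    group_by(.data$cell_barcode) |>
    summarise(
      genes_all = dplyr::n_distinct(.data$gene_id),
      genes_exon = dplyr::n_distinct(.data$gene_id[.data$region == "exonic"]),
      .groups = "drop"
    ) |>
    filter(.data$genes_exon > 0)
  mean(per_cell$genes_all / per_cell$genes_exon)
}

#' @rdname truth_detection_gain
#' @export
truth_polya_fraction <- function(truth, ann, flank = 20L, min_len = 5L) {
  intronic <- filter(truth, .data$region == "intronic")
  if (nrow(intronic) == 0) abort("truth table contains no intronic reads")
  # regex scan per chromosome and strand base, then a sorted-interval
  # overlap check (runs are disjoint, so starts and ends are both sorted
  # and the candidate with the largest start < window end suffices)
  run_table <- function(chrom, base) {
    s <- as.character(ann$genome[[chrom]])
    m <- gregexpr(sprintf("%s{%d,}", base, min_len), s)[[1]]
    if (m[1] == -1) return(NULL)
    list(start = as.integer(m) - 1L,
         end = as.integer(m) - 1L + attr(m, "match.length"))
  }
  n_hit <- 0L
  for (ch in unique(intronic$chrom)) {
    for (st in c("+", "-")) {
      block <- intronic[intronic$chrom == ch & intronic$strand == st, ]
      if (nrow(block) == 0) next
      runs <- run_table(ch, if (st == "+") "A" else "T")
      if (is.null(runs)) next
      ws <- block$start - flank
      we <- block$end + flank
      idx <- findInterval(we - 0.5, runs$start)
      hit <- idx >= 1 & runs$end[pmax(idx, 1L)] > ws
      n_hit <- n_hit + sum(hit)
    }
  }
  n_hit / nrow(intronic)
}
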