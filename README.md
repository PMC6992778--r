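# nucquant

Intron-aware UMI quantification and QC for droplet single-cell and
single-nucleus 3' RNA-seq.

## Why

Single-nucleus RNA-seq (DroNc-seq style) is the only way to profile tissues
that cannot be dissociated into intact cells, but nuclear RNA is dominated
by unspliced transcripts: up to ~50% of reads land in introns, versus ~7%
for whole-cell Drop-seq, and an exon-only counter throws them away.
Counting a gene's UMIs over its exons *and* its introns — where the intron
set is the gene span minus the exon union, per strand — recovers those
reads and raises per-cell gene detection by roughly 1.5x in nuclear
libraries.

`nucquant` implements that quantification as a tested, reusable pipeline
for R, together with the analyses that surround it in a single-cell vs
single-nucleus comparison:

* **Annotation** — parse GTF, derive per-gene introns by strand-aware
  interval subtraction, write BED.
* **Tagging** — cell-barcode whitelisting by read-count threshold, fusing
  read pairs into barcode/UMI-tagged records, 3' polyA trimming.
* **Quantification** — assign aligned reads to exonic/intronic features,
  build deduplicated sparse UMI matrices in `exon_only` and
  `exon_plus_intron` modes, merge runs, MatrixMarket I/O.
* **QC** — the 400/300 detected-gene cell/nucleus filters, gene filtering,
  per-cell summaries, region fractions, top-gene shares, detection gain.
* **Internal priming** — scan a genome for polyA tracts (A-runs and
  T-runs, ≥ 5 bp), intersect with flank-extended intronic reads
  strand-specifically, and histogram tract 3' positions along reads. For a
  gene on the forward strand the polydT primer anneals to genomic A-runs;
  mass piled toward the read 3' end is the internal-priming signature.
* **Expression comparison** — TP10k / log1p / standardized normalization,
  binned-dispersion variable-gene selection, pseudo-bulk profiles, Pearson
  correlation profiles, bi-clustering.
* **Droplet loading** — Poisson occupancy with
  `lambda = concentration x volume x 1e-9`, doublet fraction among
  occupied droplets `(1 - e^-lam - lam e^-lam)/(1 - e^-lam)`, a Monte-Carlo
  twin, and the two-species (barnyard) doublet estimator with the
  `1 / (2 f (1 - f))` mixing correction.
* **Synthetic data** — a seeded generator emulating cytoplasmic
  (mito/ribo-enriched, 7% intronic) versus nuclear (lncRNA-enriched, 50%
  intronic, shallower) libraries, with planted polyA tracts, internal
  priming, doublets and species mixing, plus a per-read truth table so
  every stage is testable without downloads.

Everything is tidyverse-native: functions take and return tibbles, results
have `tidy()` / `glance()` methods and `autoplot()` / `plot_*()` figures.
The one matrix container, `umi_counts`, wraps a sparse `Matrix` with a
counting mode.

## Worked example

Simulate a nuclear library at study-like conditions, quantify it both
ways, and run the priming diagnostic:

```r
library(nucquant)

cfg  <- sim_config(seed = 42, mode = "nucleus", n_cells = 200, mean_umis = 400)
ann  <- simulate_genome_annotation(cfg)
expr <- simulate_expression(cfg, ann)
sim  <- simulate_reads(cfg, ann, expr)

asn <- assign_reads(sim$reads, ann$genes)
region_fractions(asn)
#> # A tibble: 4 × 3
#>   region     reads fraction
#>   <chr>      <int>    <dbl>
#> 1 exonic     53124    0.498
#> 2 intronic   53604    0.502
#> 3 ambiguous      0    0
#> 4 intergenic     0    0
```

Half the reads are intronic, as configured for nucleus mode. Exon-only
counting loses them; intron-aware counting does not:

```r
both <- count_umis(asn, "exon_plus_intron")
exon <- count_umis(asn, "exon_only",
                   gene_ids = rownames(both$counts),
                   cell_barcodes = colnames(both$counts))
both
#> <umi_counts[exon_plus_intron]> 119 genes x 200 cells, 14026 nonzero, 82199 total UMIs

glance(detection_gain(exon, both))
#> # A tibble: 1 × 3
#>   mean_gain n_cells n_infinite
#>       <dbl>   <int>      <int>
#> 1      1.29     200          0
```

Including introns detects 1.29x more genes per nucleus at this depth. The
priming diagnostic finds the planted polyA tracts at read 3' ends:

```r
hits <- intersect_intronic(scan_polya(ann$genome), asn)
polya_read_fraction(hits, asn)
#> [1] 0.584
glance(motif_position_histogram(hits))
#> # A tibble: 1 × 4
#>   n_hits mass_3prime mass_5prime enrichment_3prime
#>    <int>       <int>       <int>             <dbl>
#> 1  33783       27197        6586              4.13
```

58% of intronic reads carry a polyA tract within their 20 bp flanks, and
tract 3' ends are 4.1x enriched in the 3' half of reads — internal priming.
Finally, the loading model at the canonical operating point (200,000
cells/mL, ~380 pL droplets):

```r
lam <- loading_lambda(200000, 380)   # 0.076
doublet_fraction(lam)                # 0.0375 among occupied droplets
```

`run_pipeline()` chains all stages from a YAML config and writes count
matrices, QC/priming/loading reports, and a `manifest.json` with seeds,
parameters, and output checksums (re-runs reproduce the checksums).

## Scope

Alignment (STAR et al.), graph clustering, UMAP/tSNE, marker-gene testing,
and trajectory inference are out of scope: the package consumes aligned
records and stops where those established tools begin. The methods
vignette (`vignettes/intron-aware-quantification.Rmd`) documents the
models, parameter choices, and limitations.
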