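---
title: "Intron-aware UMI quantification for single-cell and single-nucleus RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intron-aware UMI quantification for single-cell and single-nucleus RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucquant)
```

## The problem

Droplet microfluidic 3' RNA-seq tags each captured mRNA molecule with a
12 bp cell barcode (identifying the droplet of origin) and an 8 bp unique
molecular identifier (UMI, collapsing PCR duplicates to one count). Two
flavours of the assay differ in what they capture: whole-cell protocols
(Drop-seq style) sample total cellular RNA, while single-nucleus protocols
(DroNc-seq style) sample nuclear RNA — the only option for tissues such as
heart or brain that cannot be dissociated into intact cells.

Nuclear RNA is dominated by unspliced transcripts, so a large share of
single-nucleus reads — around half, versus under a tenth for whole cells —
falls in introns and is discarded by a conventional exon-only counter.
`nucquant` implements the intron-aware alternative: derive per-gene intron
intervals by subtracting the exon union from the gene span, assign reads to
exonic *or* intronic features, and count a gene's UMIs as the union over
both. On nuclear libraries this raises per-cell gene detection by roughly
1.5x. The package also implements the accompanying diagnostics: a genomic
polyA-tract scan that explains part of the intronic signal as internal
priming of the polydT primer, the QC filters of the assay comparison, a
pseudo-bulk Pearson correlation analysis, and the Poisson droplet-loading
model.

## Intron derivation

A gene's intron set is defined operationally, not biologically: the gene
span minus the union of the exons of *all* of its transcripts, on the same
strand. This matches the subtraction recipe exactly and needs no transcript
model. Consequences worth noting:

* A base alternatively spliced (exonic in one isoform, intronic in another)
  is exonic here, because the exon union covers it.
* Overlapping genes are processed independently: one base may be exonic in
  gene A and intronic in gene B. Resolving reads over such bases is the
  assigner's job, not the annotation's.
* Exons and introns tile the span exactly — the package tests this
  invariant against a per-base oracle.

Internally every interval is 0-based half-open; GTF (1-based closed) is
converted at the boundary and nowhere else. No GENCODE level or biotype
filter is applied before the subtraction: nothing in the procedure requires
one, and applying one silently would change which bases count as intronic.

```{r introns, eval = FALSE}
genes <- read_gene_models("annotation.gtf") |> derive_introns()
write_intervals(genes, "intron", "introns.bed")
```

## Read tagging and whitelisting

A cell barcode enters the whitelist when it carries at least `min_reads`
read pairs (default 30,000, suited to a run at 30k-40k reads per cell; the
synthetic examples below lower it). The rule is a hard threshold — no
knee-point detection, no barcode error correction — so it is deterministic
and monotone. Barcodes containing `N` are excluded as ambiguous cells; this
is a package decision where the upstream tools are silent. `trim_polya()`
removes a maximal 3'-terminal run of at least 6 adenines: at 60 bp read
length, a terminal hexamer run is the shortest tail unlikely to occur by
chance, and only the polyA rule (not general adapter trimming) is in scope.

## Assignment and UMI counting

Reads are treated as genomic intervals (alignment is upstream; the package
consumes SAM/BAM whose read names carry `barcode_umi_serial`). The
assignment rules, in order:

1. exon overlap with exactly one gene → exonic for that gene (an overlap
   with the *same* gene's intron does not demote the read: after UMI
   deduplication the gene-level count is identical either way);
2. intron overlap with exactly one gene and exons of none → intronic;
3. features of two or more genes → ambiguous (by default; with
   `exon_priority = TRUE` a unique exonic gene wins over other genes'
   introns);
4. no overlap → intergenic.

Assignment is unstranded by default (the common counter default); a
`stranded` flag restricts to same-strand features. Only primary alignments
are counted. `count_umis()` then counts, per (gene, cell), the number of
*distinct* UMI strings among reads in the admitted regions. A UMI observed
in both an exonic and an intronic read of one gene counts once — the
molecule was captured once; the "sum of exon and intron UMIs" is read as a
union, not a double count. UMI identity is exact string match; no
edit-distance collapsing. With these rules `exon_plus_intron` counts
dominate `exon_only` counts entrywise by construction, which the tests
assert.

## QC

`filter_matrix()` removes cells below the mode's detection threshold
(400 genes for cells, 300 for nuclei, strict inequality) *first*, then
genes detected in fewer than 10 of the surviving cells. The order changes
the result, so it is fixed and documented. A gene counts as detected at
1 UMI. `select_top_cells()` keeps `ceiling(fraction * n)` cells by detected
genes with ties broken by total UMIs then barcode — published selections of
"top 30%" do not always equal exactly 30%, so the fraction is a parameter
and the tie-break deterministic. In `detection_gain()`, cells with zero
exon-only detection have an infinite ratio; they are reported separately
and excluded from the mean.

## The polyA internal-priming diagnostic

The polydT capture primer can hybridize to genomically encoded A-rich
tracts instead of the true polyA tail, generating intronic reads whose 3'
ends sit at such tracts. The diagnostic:

1. `scan_polya()` finds every maximal run of ≥ 5 A's (reported on `+`) and
   ≥ 5 T's (an A-run on the reverse strand, reported on `-`). Merging
   overlapping 5-mers is implicit in reporting maximal runs. Both strands
   are scanned by default (`strands = "forward"` restricts to A-runs);
   soft-masked lowercase bases count as ordinary bases; `N` breaks runs.
2. `intersect_intronic()` extends each intronic read by 20 bp per side and
   intersects with the tracts, strand-specifically: priming happens on
   A-runs of the transcript strand, so tract strand must equal read strand.
3. `polya_read_fraction()` is the share of intronic reads with ≥ 1 hit
   (~40% in nuclear libraries).
4. `motif_position_histogram()` bins, per hit, the offset of the tract's 3'
   end relative to the read's 5' end in read orientation (`tract_end -
   read_start` for `+` reads, mirrored `read_end - tract_start` for `-`
   reads), over `[-flank, read_len + flank]` in 5 bp bins. The anchoring
   convention is fixed here because only "3' positions" is specified
   upstream. Offsets from tracts running past the window are clamped into
   the edge bins so counts always sum to the number of intersections; as a
   consequence, flatness under the no-priming null holds for the *interior*
   bins, and that is what the tests check (a chi-square at alpha 0.01).
   Internal priming shows as mass piled toward the 3' end.

## Normalization, variable genes, pseudo-bulk correlation

The normalization ladder is explicit: TP10k (per-cell totals scaled to
10^4), then natural `log(x + 1)`, then per-gene standardization (constant
genes become zero rows and are flagged). Highly variable genes use the
variance-over-mean dispersion on the exponentiated scale, z-standardized
within 20 equal-frequency mean bins (bin count is a config field; the
upstream convention is unstated), with thresholds 1.5 on the dispersion
z-score and 0.15 on log mean expression.

Pseudo-bulk profiles sum raw counts over a group's cells and convert the
sums to log1p-TP10k, the same ladder applied to the aggregate. Pearson
correlation of each query profile against each reference forms its
"correlation profile"; gene sets default to the genes detected on both
sides, optionally capped to the top N by mean expression, since the
published ~6,000/~2,500-gene sets come with no stated rule.
`bicluster()` clusters rows and columns independently — complete linkage
on Euclidean distance, the defaults of the classic heatmap function, with
average linkage on `1 - r` selectable.

## Droplet loading

With cells at concentration $c$ (mL$^{-1}$) in droplets of volume $V$ (pL),
occupancy is Poisson with $\lambda = c \, V \times 10^{-9}$; the canonical
operating point, 200,000 cells/mL into ~380 pL droplets, gives
$\lambda = 0.076$ and ~2.6 million droplets per mL. The doublet rate is
defined among *occupied* droplets — what a sequencing run can observe:

$$d(\lambda) = \frac{1 - e^{-\lambda} - \lambda e^{-\lambda}}{1 - e^{-\lambda}} \approx 3.75\% \text{ at } \lambda = 0.076,$$

consistent with the observed sub-5% doublet rates. `simulate_loading()` is
the Monte-Carlo twin of the closed forms. For two-species (barnyard)
mixing, a barcode is a cross-species collision when its minor-species read
fraction exceeds `1 - purity_threshold` (default 0.9), and the total rate
is the observed collision rate divided by $2f(1-f)$, capped at 1 — the
published experiment describes no classifier, so both the threshold and
the correction are explicit parameters here.

```{r loading}
lam <- loading_lambda(200000, 380)
c(lambda = lam, doublet = doublet_fraction(lam))
```

## What the synthetic generator emulates — and what it does not

`sim_config()` encodes the study conditions as defaults: nucleus mode has a
mean of 721 UMIs per cell and 50% intronic reads with lncRNA genes
up-weighted (nuclear retention, MALAT1-like); cell mode has 1474 mean UMIs,
7% intronic reads, and mitochondrial/ribosomal genes up-weighted. Defaults
chosen where no value is stated upstream: 40% of intronic reads internally
primed (matching the observed ~40% polyA-adjacent fraction), gamma-Poisson
expression (Gamma gene weights, negative-binomial cell totals, multinomial
allocation — standard overdispersion for UMI counts; no expression model is
fitted upstream), two cell populations differing in 20% of genes by a
factor of 4, a mean PCR-duplication rate of 0.3 extra reads per molecule,
and 120 genes on two 250 kb chromosomes — large enough that intron
structure, biotype composition, and per-cell sampling are all exercised,
small enough that a full pipeline run takes seconds.

Planted polyA tracts (8-14 bp, one per intron by default, A's on `+`
genes and T's on `-` genes) keep ≥ 80 bp clearance from intron boundaries
so a primed read plus flanks always fits inside the intron; primed reads
place the tract 3' end 40-75 bp from the read 5' end, i.e. in the 3' half.
Intron lengths start at 300 bp, above read length plus both flanks, so
intronic reads are unambiguous; genes do not overlap by default, which is
what makes "assignment recovers 100% of true regions" a meaningful test
(overlapping-gene ambiguity is exercised by dedicated fixtures instead).

The generator deliberately does *not* emulate sequencing errors, base
qualities, barcode errors, splice-junction reads, or a realistic human
transcriptome. Passing parameter-recovery tests therefore demonstrates that
the pipeline's arithmetic is right under the stated sampling model, not
that it is robust to artifacts the model omits.

Generator truth for the polyA fraction is computed by an independent route
(per-chromosome regex scan plus a sorted-interval overlap check), using the
same partial-overlap boundary semantics as the pipeline's intersection, so
pipeline and truth agree exactly up to the stochastic placement of reads.

## Numerical and testing choices

* Deterministic everywhere: every generator function takes one seed;
  derived stage seeds are small fixed offsets. Identical configs produce
  byte-identical FASTA/GTF/SAM output.
* Problem sizes: the parameter-recovery run uses the study-condition
  defaults (500 nuclei at 721 mean UMIs, about half a million reads);
  oracle-equivalence checks use 200 random gene structures, a 1 Mb
  polyA-scan sequence, and 500 planted UMI triplets. A full test run takes
  on the order of two minutes.
* Stochastic assertions use 3 binomial standard errors around generator
  truth; detection gain is held to ±0.1 of truth.
* Ties are always broken deterministically (documented sort keys), so
  re-runs reproduce manifests checksum-for-checksum.

## Limitations

* Reads are intervals: split (spliced) alignments are not modelled, so a
  junction read overlapping exon and intron of its gene is simply exonic.
* The whitelist is a hard threshold; knee-point methods will differ near
  the boundary.
* Internal priming is diagnosed, not corrected: counts are unadjusted.
* The exact gene-set rules behind published "~6,000-gene" correlation
  panels are unknown; `select_correlation_genes()` makes the rule explicit
  and parameterized instead of guessing at a reproduction.
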