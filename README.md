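# skewscape

Comparative genome-architecture analysis of circular bacterial
chromosomes, centred on the question of where gene transfer agent (GTA)
gene clusters and core genes sit relative to the replication-driven
compositional structure of the chromosome.

## The problem

A circular bacterial chromosome is replicated bidirectionally from one
origin (*ori*) to one terminus (*ter*), splitting it into a right and a
left replichore. Replication leaves a compositional fingerprint, the GC
skew

> skew = (G − C) / (G + C),

computed in sliding windows along the reference strand: typically
positive on the right replichore and negative on the left. Genes can then
be classified by replichore, by leading/lagging (co-directional/head-on)
orientation relative to the replication fork, and by whether their local
skew sign follows the typical pattern — a deviation flags a *potential
inversion* from the other strand. Local extremes of the skew ("GC-skew
peaks", the upper and lower 3 % of values within a 150 kb sliding
neighbourhood) mark regions where both core genes and GTA gene clusters
concentrate, and the codon usage of peak genes shows a preference for
codons with an excess of G over C — a GC-skew effect distinct from GC
content. Two further architecture signals round out the picture: gene
distance to long repeats (> 800 bp, > 90 % identity; "far" means more
than 1/1000 of the genome size away), a proxy for local plasticity, and
the density profile of the CcrM methylation motif GANTC along the
ori-oriented chromosome.

`skewscape` implements this entire analysis stack as composable R
functions — chromosome reorientation, skew tracks and sliding-quantile
peak calling, architecture classification, codon-usage comparison,
core-gene calling from orthologue matrices with peak-enrichment ratios,
repeat-distance classes, and motif profiles — plus a seedable synthetic
genome generator that plants every one of these signals with known
parameters, so the whole pipeline is testable end to end without any
external data.

## Worked example

Generate a 300 kb chromosome with two planted high-skew segments, a
5-gene GTA-like cluster inside the first segment, and a 1.5× bias toward
G-skewed codons in peak regions; then run the main stages:

```r
library(skewscape)

segs <- data.frame(start = c(40000, 200000), end = c(70000, 230000),
                   extra_amplitude = 0.3)
sp <- synthetic_spec(length = 300000, n_genes = 250, peak_segments = segs,
                     cluster = list(position = 45000, n_genes = 5,
                                    strand = "+"),
                     peak_codon_bias = 1.5, skew_amplitude = 0.1,
                     gene_length_codons = c(250, 60), seed = 11)
g <- generate_genome(sp)
g$record
#> <genome_record> synth_chr: 300,000 bp circular, 255 CDS
#>   ori = 1, ter = 150001
#>   synthetic (seed 11)

tr <- skew_track(g$record, window = 10000, step = 1000)
tr
#> <skew_track> synth_chr: 300 windows of 10000 bp (step 1000)
#>   skew range -0.1212 .. 0.426

pk <- detect_skew_peaks(tr, quantile = 0.03, local_window = 150000)
pk
#> <peak_annotation> synth_chr: 7 high / 3 low intervals (q = 0.03,
#>   local window 150000 bp)

table(assign_genes_to_peaks(g$record, pk)$label)
#> non_peak     peak
#>      238       17

cls <- classify_gene_architecture(g$record)
round(100 * mean(cls$typical, na.rm = TRUE), 1)
#> [1] 87.8

tg <- g$truth$genes
ru <- relative_codon_usage(codon_counts(g$record, tg$gene_id[tg$in_peak]),
                           codon_counts(g$record, tg$gene_id[!tg$in_peak]))
usage_correlations(ru, "gc_skew")
#> rho = 0.558, p = 1.1e-05, n = 54 codons

nrow(find_motif_sites(g$record, "GANTC"))
#> [1] 1029
```

Reading the numbers: the background replichore skew is ±0.1 and the
planted segments push local windows up to ≈ 0.43; the peak caller flags
the extreme tail of each 150 kb neighbourhood, and 17 genes (including
the planted cluster) sit in flagged intervals. 87.8 % of genes follow
the typical skew pattern, and the positive Spearman correlation between
relative codon usage (peak vs non-peak genes) and per-codon GC skew
recovers the planted preference for G-ending codons.

`run_pipeline()` orchestrates the same stages over a cohort from one
configuration (YAML or an R list) and writes self-describing TSV outputs
plus a `summary.json`; see `?run_pipeline` and `?validate_config`.

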