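# readthroughr

Strand-specific RNA-seq of perturbation experiments — the motivating case
is knockdown of the 7SK snRNA in mouse embryonic stem cells with antisense
oligonucleotides (ASOs) — reveals transcriptional changes that extend
beyond annotated gene boundaries: divergent transcription upstream of
promoters (upstream divergent RNAs, udRNAs) and failed transcriptional
termination (readthrough) downstream of polyadenylation sites (PAS).
These signals confound naive differential expression: a gene seated inside
the readthrough region of an upstream locus looks upregulated even though
nothing changed at its own promoter.

`readthroughr` implements, as a reusable and tested R package plus an
analysis workflow, the computational procedures such a study needs:

- **Background-adjusted expression calling.** For gene *i* with normalized
  count *g<sub>i</sub>* and exonic length *l<sub>i</sub>*, local
  transcription is estimated from five 2 kb windows at 1–3, 3–5, 5–7, 7–9
  and 9–11 kb upstream of the gene on its own strand, with annotated exons
  of other genes masked out (counts *a<sub>ij</sub>*, unmasked sizes
  *b<sub>ij</sub>*), and the adjusted count is

  max(0, *g<sub>i</sub>* − *l<sub>i</sub>* · median<sub>j</sub>(*a<sub>ij</sub>*/*b<sub>ij</sub>*)).

- **udRNA detection.** The 5 kb window immediately upstream of each
  eligible protein-coding TSS (closely spaced divergent pairs, TSS-to-TSS
  < 10 kb, are excluded) is screened for antisense reads in a balanced
  control/knockdown sample set. A region is called when some sample
  reaches max(10, 2 · 5000 · max<sub>j</sub>(*c<sub>ij</sub>*/*d<sub>ij</sub>*))
  normalized reads, where *c*, *d* describe five exon-masked antisense
  background windows downstream of the final TSS — a two-fold-over-background
  rule that rejects failed-termination sweeps across promoters.

- **Readthrough detection and extent.** Gene bodies are cut into 100
  bins and each 100 kb flank into 500 bins of 200 bp; downstream regions
  of enrichment are maximal runs of bins whose covering 10-bin window has
  mean normalized density ≥ 0.005. Genes with a downstream region > 1 kb
  and a floored fold change > 1.5 in a knockdown-pair comparison are
  potential candidates; candidates are additionally expressed, have a
  region > 3 kb, and show no potential candidate within 100 kb upstream on
  the same strand (the initiating-locus rule). Extents come from
  deterministic change-point segmentation of the 1 Mb downstream density,
  merging contiguous segments with mean density > 0.01 from the PAS.

- **Supporting statistics.** Exon-overlap read counting (≥ half the
  alignment exonic), RPKM and the expressed rule (mean control RPKM > 5),
  TMM / median-of-ratios / total-count normalization, per-ASO negative
  binomial GLM testing with batch covariate and intersection across ASOs
  (q < 0.05, fold change ≥ 1.5), Benjamini–Hochberg correction, Fisher's
  exact feature-overlap tests, a geometric-mean randomization test, and
  local gene density.

- **A synthetic-data generator** (`simulate_dataset()`) that plants every
  effect class — direct 4× targets, udRNAs, readthrough loci with known
  extents, passengers inside readthrough regions, and
  readthrough-across-promoter confounders — over a toy genome with
  negative binomial replicate noise, so the whole pipeline is testable
  offline with a known truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
reference synthetic dataset (`Rscript analysis/01_simulate.R` through
`06_enrichment.R`; tables land in `results/`). Step 4, udRNA detection,
prints:

```
Screened 180 eligible protein-coding genes; 50 udRNA calls
Planted udRNAs recovered: 50 of 50
Readthrough-across-promoter confounders rejected: 10 of 10
Knockdown response: 100.0% positive fold change, 44.0% above two-fold
```

All 50 planted udRNAs are recovered with no false positives, and all 10
promoters swept by antisense readthrough from a downstream gene are
rejected by the two-fold-over-background rule. Step 3 shows what the
background adjustment is for:

```
Raw analysis: 24 genes up in both ASOs; 16 of 30 planted direct targets, 8 of 20 passengers
Background-adjusted: 17 genes up; 17 direct targets retained, 0 passengers remaining
```

The raw consensus calls include 8 passenger genes that merely sit inside a
readthrough region; the adjustment removes every passenger while keeping
the direct targets. Step 5 recovers all 50 planted readthrough loci as
candidates, demotes all 20 passengers to non-head chain members, and
estimates extents with a median error of 0% (96% within 10% of the planted
truth).

The same machinery is available programmatically:

```r
library(readthroughr)
sim <- simulate_dataset(sim_config(seed = 1))
res <- run_pipeline(sim$genes, sim$read_sets, sim$design, outdir = "out")
head(res$termination$regions)
```

## Scope

The package operates on annotation (GTF), uniquely mapped stranded reads
(BED6 or BAM, multi-mappers dropped via the `NH` tag), a sample design
table, and optional feature BED files. Read trimming, alignment, rRNA
filtering, coordinate liftover and GO enrichment are out of scope.
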