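---
title: "Models and methods behind readthroughr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind readthroughr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`readthroughr` analyses strand-specific RNA-seq from perturbation
experiments in which transcription escapes annotated gene boundaries. The
motivating biology is knockdown of the 7SK snRNA — the scaffold that
sequesters P-TEFb — which releases paused RNA polymerase II and produces
three distinct genomic signatures: upregulation of direct target genes,
divergent antisense transcription upstream of promoters (udRNAs), and
failed transcriptional termination (readthrough) extending downstream of
polyadenylation sites. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic validation does
and does not establish.

## Data model and coordinates

Internally everything is 1-based, closed-interval coordinates on
`GenomicRanges` objects — the native R/Bioconductor convention — with GTF
read natively and BED converted at the boundary. A `GeneSet` holds one
model per gene: merged exons, the TSS (5'-most transcript start across
isoforms), the *final TSS* (3'-most transcript start), the PAS (3'-most
transcript end) and the exonic length (size of the exon union). Genes
whose exons span several chromosomes or strands are dropped with a
warning, because every detection below assumes a single stranded locus.
Reads are uniquely mapped stranded alignments; BAM input drops secondary
alignments and records with `NH > 1`.

## Counting, RPKM and normalization

A read counts toward a gene when at least half of its aligned length
overlaps the merged exons on the gene's strand — lenient enough to keep
reads at imperfectly annotated exon boundaries. RPKM uses the exonic
length and the total reads counted to genes; a gene is *expressed* when
its mean control RPKM exceeds 5 (strict).

Three between-sample scalings are provided behind one interface
(`NormalizationFactors`, with a per-sample multiplier taking raw to
normalized counts):

* **TMM** (`tmm_factors()`, the default), delegated to edgeR's
  `calcNormFactors` with the published double trimming (30% on M, 5% on
  A) and precision weighting; the test suite pins it to an independent
  brute-force implementation of the trimmed mean.
* **Median of ratios** (`median_of_ratios_factors()`), the
  Anders–Huber-style size factors, rescaled to geometric mean 1.
* **Total count** (`total_count_factors()`), which divides by the mapped
  total and multiplies by the mean mapped total — the annotation-free
  control analysis.

Scaling factors are always fitted on annotated gene counts and then
*applied* to region counts (upstream windows, flank bins); region counts
never influence the fit.

One property of the synthetic conditions deserves emphasis: with 30
direct targets plus 20 passengers planted among only 200 genes, a quarter
of all genes shift upward in the knockdown samples. A trimmed mean is not
fully robust to a 25% one-sided contamination, so TMM under-corrects the
composition shift and unchanged genes normalize to roughly 0.8 rather
than 1.0. This is a property of the small simulated universe, not of the
implementation — at genome scale, where a few hundred genes change out of
~18,000, the trim removes all of them.

## Local background and adjusted counts

For each gene and sample, background transcription is the median read
coverage over five 2 kb windows at 1–3, 3–5, 5–7, 7–9 and 9–11 kb
upstream of the gene start, on the gene's strand, after masking exon
bases of other genes annotated on that strand — leaving intronic and
intergenic signal only. With normalized count $g_i$, exonic length
$l_i$, window counts $a_{ij}$ and unmasked sizes $b_{ij}$:

$$\mathrm{adj}_i = \max\!\left(0,\; g_i - l_i \cdot
  \mathrm{median}_j \frac{a_{ij}}{b_{ij}}\right)$$

Values below background are set to zero. Windows truncated at a
chromosome end keep their remaining bases; fully masked or fully
truncated windows are dropped before the median (an even number of
retained windows uses the midpoint of the central two). If nothing is
retained the adjustment is a conservative no-op, with a warning. The
median over five windows makes the estimate robust to a single
neighbouring feature; the mask keeps genuinely exonic transcription of
neighbours out of the estimate.

## Differential expression

Each knockdown ASO is tested separately against the scrambled controls —
a deliberate guard against oligo off-target effects — with a
negative-binomial log-linear model containing intercept, experiment batch
and ASO terms, and a likelihood-ratio test of the ASO coefficient. Genes
first pass a minimal-expression filter (CPM > 1 in at least two samples).
Dispersion estimation and the GLM itself are delegated to edgeR
(`estimateDisp`, `glmFit`, `glmLRT`); the contract, enforced by
simulation tests, is calibration — the null type-I error at nominal 0.05
stays within [0.03, 0.08] — rather than bit-level reproduction of any
particular shrinkage recipe. Fold changes are reported from normalized
means with a pseudocount of 1; the pseudocount never enters the
likelihood. The consensus call requires, in *both* ASO tests, a BH
q-value strictly below 0.05 and a same-direction fold change of at least
1.5.

The adjusted analysis reruns the same machinery on background-adjusted
counts (rounded, with unit factors, since the adjustment is applied to
already-normalized values). Its deliverable is the *up-called* set — the
direct-target catalogue. Over-subtraction can push a passenger below its
control level and produce a nominal down-call; for the purpose of
separating direct from indirect targets that is still a removal, and the
synthetic tests score it as such.

A power note the tests make explicit: with two replicates per group and a
biological CV of $\sqrt{0.1} \approx 0.32$, a single 2v2 comparison of a
4× effect reaches roughly 85–95% sensitivity at q < 0.05, and the
intersection of two such tests therefore cannot exceed roughly 80–85%.
The recovery tests report this honestly; it is a property of the design
(2+2+2 with intersection), not of the implementation — plugging the true
dispersion into the GLM does not change it.

## udRNA detection

Only protein-coding genes enter the search, and members of closely spaced
divergent pairs (head-to-head TSSs on opposite strands within 10 kb) are
excluded, since their upstream windows contain the partner's promoter
signal. For each remaining gene the 5 kb window immediately upstream of
the TSS is screened, per sample, for reads on the opposite strand, in a
*balanced* set of control and knockdown samples (two of each; the second
ASO is held out of detection and returns for quantification).

The per-sample threshold is
$\max(10,\; 2 \cdot 5000 \cdot \max_j c_{ij}/d_{ij})$, where $c, d$
describe five 2 kb antisense background windows at 1–11 kb downstream of
the final TSS with opposite-strand exons masked. The floor of 10
normalized reads suppresses noise calls; the two-fold-over-background
clause is the key discriminator against the confounder this pipeline
cares about: a readthrough region of a downstream gene on the opposite
strand sweeping leftward across the promoter produces antisense reads in
the upstream window *and* (at higher density, being closer to its source
PAS) in the background windows, so its threshold rises above its own
signal and the call is rejected. When a truncated window is smaller than
5 kb, the actual window size replaces the constant. Detected regions are
quantified across all knockdown samples with pseudocounted fold changes;
a udRNA counts as repressed by the perturbation when its fold change
exceeds 2.

## Readthrough detection and extent estimation

Each gene body is divided into 100 equal bins and each 100 kb flank into
500 bins of 200 bp, with normalized read density (reads per base)
computed per bin, per sample, reads apportioned to bins fractionally by
overlap so that density × bin size integrates exactly to the regional
read mass. Bin grids are anchored at the gene edge; flanks truncated at a
chromosome end keep whole bins only.

Downstream regions of enrichment are found on the pooled (mean across
samples) density: a bin qualifies when *any* 10-bin window containing it
has mean density ≥ 0.005 (one normalized read per 200 bp bin), and
maximal runs of qualifying bins form regions. This is one concrete
reading of a sliding-window rule; it is pinned to a brute-force oracle in
the tests, and a single hot bin that qualifies only through its covering
windows is flagged low-support. The gene's downstream region is the one
containing the first bin after the PAS. Its per-sample normalized counts
are floored at 1 and converted into one log2 fold change per knockdown
pair (5' ASO pair and 3' ASO pair) against the control pair.

Candidate logic: a *potential* candidate has a downstream region larger
than 1 kb with a fold change above 1.5 in at least one pair (a
`require_both` switch gives the stricter reading); a *candidate* is
additionally expressed, has a region larger than 3 kb, and has no
potential candidate on the same strand whose PAS falls within 100 kb
upstream of its TSS. The last clause is the initiating-locus rule: when
readthrough from one locus blankets its downstream neighbours, only the
chain head survives, and adding an upstream potential can only ever
demote a gene (an anti-monotonicity the tests check).

Extent estimation segments the mean knockdown density in 200 bp bins over
1 Mb downstream of the PAS — knockdown samples only, because the
phenomenon being measured exists only there — with a deterministic
penalized change-point method: binary segmentation under a piecewise-
constant-mean model with a BIC-style penalty
($3\hat\sigma^2\log n$, $\hat\sigma$ from the median absolute deviation
of first differences), a minimum segment length of 5 bins so isolated
empty bins cannot fragment a contiguous signal, and a final single-bin
refinement of the merged boundary by a local two-segment fit. Contiguous
segments from the PAS with mean density above 0.01 are merged; the extent
is the distance from the PAS to the merged end. A deterministic segmenter
replaces the stochastic Bayesian change-point sampler used historically
for this task: the merge rule, not the sampler, carries the biology, the
segmenter is pluggable, and determinism buys exact reproducibility. On
noiseless step signals the estimate is exact to one bin; under replicate
noise the tests require 90% of planted extents within 10%.

## The synthetic-data generator

`sim_config()` defaults define the reference dataset: 200 non-overlapping
multi-exon genes (2–8 exons, 2–8 kb) on two chromosomes; six samples in a
2+2+2 design (scrambled, 5' ASO, 3' ASO; one replicate of each in each of
two batches, with per-sample depth factors between 0.92 and 1.12);
negative binomial replicate noise at dispersion 0.1, implemented as a
shared per-(gene, sample) gamma multiplier over per-region Poisson draws
so that gene-level counts are exactly NB at the configured dispersion;
uniform background at 5×10⁻⁴ reads per base per strand on both strands.

Planted effects, on disjoint gene sets: 30 direct targets at 4× (exonic
and intronic signal, knockdown samples only); 50 udRNAs (antisense
density 0.004 reads/bp in control — several-fold over background — times
3 in knockdown); 20 isolated readthrough loci with extents drawn from
4–40 kb, density decaying geometrically per 2 kb block from 0.05 to
0.015 (always above the 0.01 merge threshold, so the planted extent is
the truth), present in knockdown only; 20 passenger genes, each 12 kb
downstream of a dedicated host readthrough locus whose region covers the
passenger's body *and* its full 1–11 kb background window; 10
readthrough-across-promoter confounders (an opposite-strand source gene
whose readthrough sweeps the victim's upstream window and its antisense
background windows); and 5 divergent close pairs that the eligibility
rule must exclude. Unrelated readthrough-bearing loci are kept more than
100 kb apart so that the only candidate chains are the planted ones.
Passengers are drawn from the lower half of the expression range so the
readthrough contribution dominates their apparent change — the situation
the background filter exists for.

What the generator does *not* emulate: splicing (reads are ungapped 50 nt
intervals; the half-overlap rule is still exercised at exon borders),
multi-isoform genes (the loader handles them; the simulation keeps TSS =
final TSS), mappability artefacts, rRNA contamination, and realistic
sequencing depth — at toy library sizes (~50k–125k reads) the RPKM > 5
and CPM > 1 filters pass essentially everything, so passing tests say
nothing about those filters' selectivity on real data. Recovery rates on
this generator demonstrate that the implemented rules discriminate the
planted geometries; they do not certify sensitivity on real libraries.

## Problem sizes and determinism

The test suite runs the full pipeline once on the 200-gene reference
dataset (about 500k reads across six samples), uses a scaled-down 18-gene
configuration for integration and determinism checks, 2,000-gene count
matrices for GLM calibration, and 10,000-case fuzz batches for each
formula-level oracle. Every dataset is a pure function of its
configuration and seed; identical runs produce byte-identical files, and
the pipeline records every threshold it applied in its JSON run log.

## Known limitations

* The consensus sensitivity ceiling at two replicates per group discussed
  above.
* TMM under-correction when a large fraction of a small gene universe
  shifts in one direction (synthetic-scale effect).
* The upstream-candidate search is same-strand only; convergent
  readthrough into a gene from the opposite strand is visible to the
  udRNA confounder rule but not treated as a readthrough chain.
* "Actively transcribed" is operationalized as the expressed rule (mean
  control RPKM > 5), the only expression criterion the pipeline defines.
* Extent estimation reports the merged-segment boundary; readthrough
  density below 0.01 beyond that point is deliberately not counted.
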