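# rtquant

Quantifying failure of RNA polymerase II transcription termination from
stranded coverage data.

When a termination or RNA-surveillance factor is depleted, three things
happen to the transcriptome that ordinary differential expression does not
capture well: polymerase runs past the transcription end site (TES) of
protein-coding genes, normally unstable promoter upstream transcripts
(PROMPTs) become longer and more abundant, and enhancer RNAs accumulate
over (super-)enhancer clusters. `rtquant` implements the quantification
toolkit for exactly this situation, for analysts working with two-condition
(control vs. factor-depleted) stranded RNA-seq or ChIP-seq coverage:

- **Read-through index.** For gene *g* with body mean coverage *b* and mean
  coverage *t* over the first 1 kb downstream of the TES (sense strand,
  transcription orientation),

  `rt(g) = (t + p) / (b + p)`

  with pseudocount *p* (default 0.01). The condition contrast is
  `Δ(g) = log2( rt_dep(g) / rt_ctrl(g) )`; positive values mean increased
  read-through on depletion. The 500 bp pre-TES window is computed
  alongside and can serve as the denominator instead of the body.
- **Cohort filters.** Genes with another gene's span within 5 kb of their
  promoter are excluded (this removes divergent pairs), genes with control
  TPM < 5 are excluded, and genes whose sense coverage over the 1 kb
  upstream of the TSS rises ≥ 2-fold on depletion are flagged as
  contaminated by read-through from an upstream unit.
- **PROMPT quantification.** Antisense windows upstream of each cohort TSS
  (default 3 kb) are scored per condition; log2FC ≥ 1 (inclusive) classes a
  PROMPT as upregulated. A half-maximum walker estimates how far the
  antisense signal extends upstream. The polyadenylation-signal hexamer
  AWTAAA (AATAAA or ATTAAA) is scanned over each PROMPT sequence in
  transcript orientation and reported as sites per kb, split by
  upregulation class.
- **Metagene machinery.** Scale-regions matrices (fixed flank bins, body
  rescaled to equal-width genomic slices), strand-split profiles (antisense
  scaled to −1 for plotting), and super-enhancer metaplots: per-region
  log2((depleted + p)/(control + p)) on both strands summed, averaged over
  regions, with a 95% percentile-bootstrap halo.
- **Proximity-labelling screen.** The candidate filter that selects
  depleted polymerase interactors from a TMT table: drop contaminants,
  require ≥ 5 peptides, keep mean abundance ratio < 0.70 (strict), rank
  most-depleted first.
- **Supporting layers.** BED/GTF/BED12 parsing, base-resolution stranded
  coverage with RPKM/CPM normalisation, bedGraph I/O, interval
  intersection/subtraction for replicate peak sets, exonic counting, TPM,
  and a simple two-condition upregulation caller (a documented stand-in for
  a full negative-binomial model).

Because the deposited data behind the original study are far beyond desk
scale, the package ships a first-class synthetic-data generator
(`synthetic_spec()`, `simulate_dataset()`) that plants every effect with
machine-readable truth: read-through fractions per condition, hard-stop
PROMPT extents, eRNA amplitudes, AWTAAA counts in motif-free backgrounds,
silent genes, divergent pairs and depleted proteins. Every statistic above
is validated by recovering the planted parameters.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Stage 1
writes a complete synthetic study to `scratch/synthetic/` (FASTA, GTF,
stranded bedGraphs, proteomics TSV, truth tables); stages 2–6 analyse it
and write result tables under `results/`:

```sh
Rscript analysis/01_simulate_dataset.R
Rscript analysis/02_readthrough.R
```

prints

```
read-through table: 140 genes after filters
  mean delta (planted): 2.995; (background): 0.001
  planted genes in top 10 by delta: 10
```

140 of 200 genes survive the neighbour and TPM filters; genes planted with
termination failure (post-TES fraction rising from 0.05 to 0.40 of the body
rate) show Δ ≈ log2(0.40/0.05) = 3 and occupy the top of the ranking, while
background genes sit at Δ ≈ 0. Stage 3 recovers the planted PROMPT
extension (8000 bp vs. 1500 bp) and the planted PAS-density contrast
(median 0.33 sites/kb in upregulated PROMPTs vs. 1.67 in stable ones);
stage 4 shows the super-enhancer body plateau at log2 ratio ≈ 1.585 =
log2(3) with a tight bootstrap halo; stage 5 recovers 8/8 planted 6-fold
genes with 0 false calls; stage 6 returns exactly the planted depleted
proteins that pass the peptide gate.

An end-to-end driver with file I/O round-trips is also available as a
single call:

```r
library(rtquant)
res <- run_demo(seed = 7, out_dir = "scratch/demo")
```

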