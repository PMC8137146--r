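---
title: "Quantifying transcription-termination defects with rtquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription-termination defects with rtquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtquant)
```

## The measurement problem

Depleting a transcription-termination or RNA-surveillance factor changes
the transcriptome in ways that are spatial rather than gene-level:
polymerase continues past the annotated transcription end site (TES),
normally short-lived antisense transcripts upstream of promoters (PROMPTs)
extend and accumulate, and bidirectional enhancer RNA rises over
super-enhancer clusters. The signal of interest therefore lives in *where*
coverage appears relative to gene anatomy, on *which strand*, and how that
changes between a control and a depleted condition. `rtquant` implements
the corresponding window statistics over stranded, base-resolution
coverage, together with the cohort filters that make them interpretable,
and validates all of them by parameter recovery on synthetic data with
planted ground truth.

All internal coordinates are 0-based half-open (BED convention); GTF input
is converted at the boundary. The TSS of a minus-strand gene is its span
end and its TES the span start, so every window below is expressed in
transcription orientation and mirrored automatically.

## The statistics

**Read-through index.** For a gene with body mean $b$, and $t$ the sense
mean over the first 1 kb downstream of the TES,
$$rt = \frac{t + p}{b + p}, \qquad
  \Delta = \log_2 \frac{rt_{dep}}{rt_{ctrl}},$$
with pseudocount $p$ (default 0.01 coverage units, applied symmetrically in
every log-ratio the package computes). Two denominators are defensible —
the whole gene body, or the 500 bp directly preceding the TES — and the
package computes both, using the body by default with a switch
(`denominator = "pre_tes"`). Exposing the pair was a deliberate choice:
the two conventions differ for genes with strong 3′ bias, and hiding one
would bury an analysis decision inside the package. On an all-zero track
the index is exactly 1 ($p/p$), so the statistic is always finite.

**Cohort filters.** Three filters precede any metagene or PROMPT statistic:

- *Neighbour exclusion.* A gene is kept iff no other gene's span overlaps
  the symmetric window $[TSS - d, TSS + d)$ with $d = 5$ kb. "Neighbour"
  could plausibly mean another TSS, span or TES; we chose span-overlap
  against a symmetric TSS window because it subsumes the others and also
  removes divergent-promoter pairs, which contaminate antisense windows.
  The distance is configurable (`neighbour_distance`).
- *Expression.* Genes with control TPM < 5 are flagged; the inequality is
  strict, so TPM = 5.0 survives.
- *Upstream contamination.* A gene whose sense coverage over the 1 kb
  preceding its TSS rises by $\log_2 FC \ge 1$ on depletion is flagged as
  inheriting read-through from an upstream unit rather than being induced
  itself. The window is fixed by the procedure; the cut-off is our default
  and configurable (`log2fc_up_threshold`).

**PROMPT quantification.** The PROMPT window of a + gene is
$[TSS - w, TSS)$ on the − strand (mirrored for − genes), default
$w = 3$ kb — long enough to bracket the normal PROMPT extent while keeping
the window promoter-proximal; windows overlapping any other gene are
dropped. Mean windowed coverage per condition gives a log2 fold change;
$\ge 1$ (inclusive) classes the PROMPT upregulated. Separately, a
half-maximum walker estimates the antisense *extent*: scanning upstream in
50 bp bins, the extent is the far edge of the furthest bin whose mean
reaches half the promoter-proximal antisense level. This deliberately
assumes an approximate plateau; for slowly decaying profiles it returns
the half-maximum point, which is still a meaningful summary of extension.

**PAS density.** The polyadenylation-signal consensus AWTAAA is expanded
exactly (AATAAA | ATTAAA) and scanned over the PROMPT sequence in
transcript orientation only, counting overlapping occurrences; N never
matches. A probabilistic motif scanner would add nothing for a two-word
exact pattern. Density is sites per kb of the *realised* (possibly
clipped) window length. Densities are summarised separately for
upregulated and stable PROMPTs.

**Metagene machinery.** Matrices follow scale-regions semantics: fixed
flank bins (default 3 kb flanks, 10 bp bins) and a body rescaled to a fixed
number of equal-width genomic slices (default 100) aggregated by mean — no
interpolation, so a flat track yields an exactly flat matrix, which is the
property the tests pin down. Minus-strand rows are reversed so columns
always run 5′→3′. Off-chromosome flank cells are 0 and masked. Strand-split
profiles report the sense column means and the antisense column means
multiplied by −1, the plotting convention in which sense transcription is
positive and antisense negative. Super-enhancer metaplots sum the two
strands before ratioing (eRNA is bidirectional), compute per-region
per-column $\log_2((num + p)/(den + p))$, and average over regions; the
95% halo is a percentile bootstrap over regions (default 1000 resamples,
seeded). A parametric interval would be tighter but assumes column-wise
normality across regions, which heavy-tailed enhancer signal does not
grant; the bootstrap is the conservative default.

**Differential upregulation (stand-in).** The package deliberately does
not re-implement a dispersion-modelling negative-binomial framework. The
caller used for the "upregulated ≥ 2-fold, FDR ≤ 0.05" classification is a
documented stand-in: median-of-ratios size factors, then per-gene
two-sided tests — exact Poisson for single-replicate designs, a normal
approximation on log2 normalised counts (Welch-type standard error) for
replicated ones — with Benjamini–Hochberg correction. With very few
replicates the normal reference is anti-conservative in the extreme tail;
in practice the ≥ 2-fold gate absorbs this (null fold changes at
realistic depth never approach 2), and on fully null simulations the
fraction of genes at FDR ≤ 0.05 stays near 3%. For real data a
negative-binomial model should replace this component; the classification
thresholds would be unchanged.

**Proximity-labelling screen.** Candidates are proteins that are not on
the contaminant list, carry ≥ 5 peptides, have ≥ 2 observed replicate
ratios, and show a mean depleted/control abundance ratio strictly below
0.70, ranked most-depleted first with identifier ties broken
lexicographically. The ≥ 2-observed-ratios rule is our addition: the
procedure assumes triplicates and says nothing about missingness, and a
candidate resting on a single ratio is not interpretable.

## The synthetic study

`synthetic_spec()` fixes the conditions under which everything is
validated. The generator writes a gene chromosome and a super-enhancer
chromosome:

- 200 genes of 2–6 kb with 18–25 kb intergenic gaps; 20% of genes are
  placed as divergent pairs with TSSs 2 kb apart (the planted violations of
  the neighbour rule); 10% are transcriptionally silent (the planted
  low-expression set — silence rather than "low" makes the TPM truth exact
  at any cohort size, while the TPM = 5 boundary itself is tested on
  handcrafted fixtures).
- Body rates are lognormal (median 150) floored at 50× so every cohort
  gene has the coverage depth the recovery tolerances assume.
- Read-through: every gene carries a post-TES tail at fraction $r$ of its
  body rate decaying as $e^{-x/500\,\mathrm{bp}}$; $r$ = 0.05 in control,
  rising to 0.40 on depletion for a planted half of the cohort. Because
  the tail shape is shared, the planted contrast is
  $\log_2(0.40/0.05) = 3$ regardless of the decay length.
- PROMPTs: every cohort gene has an antisense plateau at 15% of its body
  rate extending 1.5 kb upstream; on depletion the plateau extends to 8 kb
  for a planted half. A hard stop (rather than decay) makes extent a crisp
  recoverable parameter. Within the 3 kb quantification window this is
  exactly a 2-fold gain, i.e. the planted effect sits exactly at the
  inclusive log2FC ≥ 1 class boundary, so sampling noise splits affected
  genes across the boundary; the PAS-density ordering between classes is
  still recovered because only low-PAS (affected) genes can cross it.
- PROMPT sequences are generated AWTAAA-free and then seeded with recorded
  motif counts: 0–2 for affected (upregulated) PROMPTs, 4–8 for stable
  ones, planting the diagnostic density contrast.
- 111 super-enhancers of 3–6 kb carry bidirectional plateaus (20 units per
  strand times a per-region multiplier) that triple on depletion.
- 5 cohort genes gain sense coverage at 50% of their body rate over the
  1 kb upstream of the TSS in the depleted condition only — the planted
  upstream-contamination set.
- The proteomics table has 200 proteins: null ratios from
  $N(1, 0.08)$ truncated at 0, 4 planted depleted proteins with ratios
  from $U(0.3, 0.6)$ (a quarter of which are planted below the peptide
  gate, to prove the gate acts), and 2 contaminants with depleted-like
  ratios so the contaminant list is load-bearing.
- Observed coverage is per-base Poisson around the expected profile
  (`noise = FALSE` gives the expectation itself, used for the closed-form
  tests). Reads are emitted only to exercise pileup and exonic counting;
  every downstream statistic consumes coverage, so read-level simulation
  would add cost without adding test value.

Seeding: one master seed; each stream (annotation +13, genome +11, reads
+31, proteomics +41, coverage +100/+200 + replicate, bootstrap +71)
derives a fixed labelled offset, so any artefact is reproducible in
isolation and the whole dataset is byte-identical under a seed.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: realistic base composition or mappability,
splicing (bodies are unspliced blocks; exon structure exists only for
counting), fragment-length and library-prep biases, biological replicate
variability beyond Poisson sampling, overlapping transcription units, and
enhancer RNA instability profiles (plateaus instead of spiky bidirectional
peaks). The suite demonstrates that the estimators recover what was
planted under the stated noise model, not that the thresholds are optimal
for any particular organism or protocol.

## Numerical choices and degenerate inputs

- Pseudocount 0.01 in coverage units, numerator and denominator alike;
  all-zero windows give ratio 1, log2 0.
- Strict inequalities exactly as printed in the procedures: TPM < 5
  removed (5.0 kept), ratio < 0.70 kept as candidate (0.70 excluded),
  peptides < 5 discarded; log2FC ≥ 1 inclusive.
- Genes shorter than the 500 bp pre-TES window are skipped with a warning;
  genes whose post-TES window overlaps another gene are flagged, not
  dropped. Metagene rows shorter than the body-bin count are masked, not
  silently rescaled.
- bedGraph records must be non-overlapping and bin-aligned; violations are
  errors naming the line, because silently summing overlapping records is
  the classic way to double-count coverage.
- Ties in the candidate ranking break on protein identifier so output
  order is deterministic.

## Problem sizes

The shipped analyses and tests run the full 200-gene / 111-enhancer study
(about 6 Mb of genome, simulated in seconds), 1000-instance oracle
comparisons for the interval, pileup and motif primitives, 20 × 2000-gene
null designs for the error-control check, and a reduced 40-gene demo for
the byte-identity check of the end-to-end driver. These sizes were chosen
so the complete validation runs comfortably on a laptop while leaving wide
margins between planted effects and their recovery tolerances.

## Limitations

The package quantifies; it does not call termination sites, assemble
read-through transcripts, or model the kinetics of polymerase release. The
differential caller is a stand-in (above). PROMPT windows use a fixed
length rather than per-gene transcript models, and the extent estimator
assumes a roughly constant antisense level. Peak calling, annotation of
peaks to genomic features, and browser-track rendering are out of scope;
interval intersection/subtraction are provided precisely so externally
called replicate peak sets can be combined.
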