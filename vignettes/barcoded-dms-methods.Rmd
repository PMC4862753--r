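---
title: "Methods: barcoded deep mutational scanning fitness landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcoded deep mutational scanning fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcfitness)
```

## The experiment being modelled

`bcfitness` analyses barcoded deep mutational scanning (DMS)
growth-competition experiments on the 76-residue yeast ubiquitin ORF. A
library of roughly 1500 single-codon variants is tagged with random 18-nt
barcodes (N18), each barcode linked to exactly one allele. Two sequencing
designs feed the pipeline:

* a **subassembly** run: paired-end reads in which read 1 carries the
  barcode (plus a constant vector region) and read 2 the full 228-nt ORF,
  used once to build the barcode-to-allele lookup table;
* **competition** runs: short single-end reads of the barcode alone,
  sampled at successive timepoints of a bulk growth competition, indexed
  per sample with TruSeq-style 6-nt indices.

Between timepoints the culture grows in log phase; a variant with
per-generation log2 selection coefficient $s$ changes its abundance
relative to wild type as $f_b(g) \propto f_b(0)\,2^{s g}$, where $g$
counts elapsed wild-type generations.

## The fitness score

For each barcode $b$ with counts $c_{bt}$ at timepoints with generations
$g_t$, and the aggregated wild-type reference $w_t$ (column sums over
WT-flagged barcodes), the default score is the ordinary least-squares
slope of

$$y_{bt} = \log_2\frac{c_{bt} + \kappa}{w_t + \kappa}$$

against $g_t$, with pseudocount $\kappa = 0.5$. This slope *is* the
per-generation log2 selection coefficient: it is scale-free (sequencing
depth cancels in the ratio), defined for every sign pattern, and equals
$s$ exactly on noiseless expected-count trajectories when $\kappa = 0$.
With the default $\kappa$ the pseudocount introduces a bias of order
$\kappa / (c \ln 2)$, negligible at realistic counts but visible at
machine precision, which is why exact-recovery checks set
`pseudocount = 0`.

An alternative reading — the slope of depth-normalised counts per barcode
and for the WT aggregate, scored as $\log_2(\text{slope}_b /
\text{slope}_{WT})$ — is available as `method = "slope-ratio"`. It is
undefined whenever either slope is non-positive (the score is then
floored), which is the main reason it is not the default.

Two reporting rules follow the study design:

* **Floor at $-0.5$**: stop-codon variants, the null class, bottom out
  near $-0.5$ per generation; all reported scores are clamped there. Raw
  (unfloored) scores are retained because the spread of stop-codon scores
  below the floor is informative about measurement error.
* **Initial-count exclusion**: barcodes observed three times or fewer in
  the initial sample are excluded (`min_initial = 4`); their trajectories
  are dominated by shot noise.

The floor is applied per barcode, before amino-acid averaging. Averaged
cells can therefore sit slightly above the floor even for null variants —
visible as stop-row means a little above $-0.5$.

## Outlier removal

Barcodes of the same codon are replicate measurements of one allele.
Within each (position, codon) group of at least `min_group = 4` barcodes,
a score is flagged dirty when it lies at least `fence = 1.5` interquartile
ranges outside the group quartiles (the Tukey fence, with
linear-interpolation quartiles). Two safeguards matter in practice:

* **Zero-IQR suppression.** When all scores in a group tie, the fence has
  zero width and would flag the whole group; flagging is suppressed.
* **Fence anchored at the quartiles, not the median.** A fence centred on
  the median at $1.5 \times$ IQR sits near $2\sigma$ for well-behaved
  scores and would discard roughly 4–5% of clean barcodes in every group;
  anchoring at the quartiles (about $2.7\sigma$) keeps the false-flag
  rate at the percent level for realistic group sizes while still
  catching gross outliers. The quartile convention is stated here because
  alternative conventions change flags in groups of 4–6.

A median-absolute-deviation criterion (`criterion = "mad"`, default
$3 \times$ MAD) is provided for comparison, and the per-group MAD is
always reported. Note that for groups of 10–25 with approximately
Gaussian score noise the IQR fence still removes about 2–3% of clean
barcodes — an intrinsic property of quantile fences at these sample
sizes; the planted-outlier checks therefore use bounded within-group
spread to isolate the filter's discrimination from this base rate.

## Aggregation and binning

Clean barcode scores are pooled across synonymous codons directly into a
masked 21 x 76 matrix (rows: 20 amino acids plus stop, alphabetical with
`*` last; columns: ORF positions). Pooling barcodes — rather than
averaging codon means — weights each cell by its evidence. The companion
error matrix holds the sample ($n-1$) standard deviation of contributing
barcode scores (masked for single-barcode cells), and a count matrix
records the evidence per cell. Cells with no barcode stay masked; no
value is ever fabricated. Replicate averaging is cellwise over unmasked
values, masking only where every replicate is masked.

Per-position averages exclude the stop row by default: stop codons are
uniformly null, so including them would depress every position mean by a
constant and blur the missense signal the position bins are meant to
capture; `include_stop = TRUE` preserves the alternative. Positions are
binned as sensitive ($\le -0.35$), tolerant ($\ge -0.075$) or
intermediate — closed interval ends on both outer bins.

## Cross-condition comparison

Difference maps are computed as perturbation minus reference, so
sensitisation is negative; every output file prints this convention in
its header, since the opposite orientation is equally common in axis
labels. Residual distributions between two landscapes ($r_m = b_m - a_m$
over cells unmasked in both) are summarised by a Lorentzian
(Cauchy-shaped) fit — the expected form for residuals of ratio-derived
quantities:

$$h(x) = A\,\frac{\Gamma^2}{\Gamma^2 + (x - X_0)^2}$$

fitted by Levenberg–Marquardt least squares to histogram bin counts,
initialised from the peak bin and the half-width at half-maximum. The
amplitude $A$ depends on the binning and is reported but never compared
across binnings. The default bin width (0.001 for fits) must resolve the
expected peak width; residual histograms for display default to 0.01 on
$[-1.5, 1.5]$. Degenerate input (no spread, e.g. a self-comparison)
returns a flagged zero-width result rather than an error, and
non-convergence returns the best iterate, flagged.

Shared and perturbation-specific calls are made in the joint
$k$-perturbation difference space: a total-least-squares line (first
principal axis through the centroid) is fitted over mutants unmasked in
all perturbations, and each mutant's Euclidean distance to that line is
computed. A mutant is **shared-sensitising** when it lies within 0.1 of
the line and its mean difference is at most $-0.2$; it is
**perturbation-specific** when its distance exceeds 0.35, the deviating
perturbation being the one with the largest residual component. Fitting
one line in the joint space (rather than per pair of perturbations) uses
all coordinates at once and makes the distance threshold a single
interpretable quantity; pairwise projections of the same cloud are what
a 2-D scatter of two perturbations shows.

Position-bin transitions (newly sensitive / intermediate / tolerant under
a perturbation) and per-position minimum-fitness maps (elementwise minima
across perturbations, minus the reference) complete the comparison; masks
propagate throughout.

## Stability comparison

Given an externally computed per-mutant stability-change table in Rosetta
Energy Units (schema: `mutant`, `reu`), mutations are classed as
destabilizing (REU $\ge 1.0$) or neutral/stabilizing, and the two classes'
unmasked fitness values are compared per condition with a two-sided
two-sample t-test. Welch's unequal-variance form is the default — the
class variances have no reason to match — with the pooled-variance form
behind `pooled = TRUE`. Computing the ddG values themselves is out of
scope; any predictor that fills the schema plugs in.

## The synthetic-data generator

The generator produces ground-truthed inputs with the statistical
structure the pipeline assumes, so every stage can be checked against
known selection coefficients:

* **Library**: amino-acid variants sampled over the 76 x 20 grid (19
  non-WT amino acids plus stop per position), one random encoding codon
  each; 2.5% of the grid is left uncovered by default (a 97.5%-complete
  library).
* **Barcodes**: per-allele barcode counts from a shifted negative
  binomial ($1 + \mathrm{NB}(\mu = 14.8, \text{size} = 10)$), giving a
  sample median of 15 barcodes per substitution at library scale;
  50 WT-flagged barcodes by default. Barcodes of one allele share its
  true coefficient (jitter configurable, default 0).
* **Truth**: stop variants sit exactly at the $-0.5$ floor; missense
  variants draw from a mixture of a tolerant mode (70%, Gaussian around 0,
  sd 0.03) and a deleterious mode (30%, uniform on $[-0.55, -0.05]$) —
  a caricature of the observed bimodality, chosen once as a plausible
  landscape shape.
* **Reads**: subassembly read 1 is barcode + 8-nt constant region
  (default `GGCGCGCC`, an AscI site as in barcode-flanking cloning) +
  filler to 30 nt; read 2 is the exact 228-nt allele ORF. Competition
  reads are barcode + constant region with the sample index carried in
  the Illumina-style header comment. Substitution errors hit every base
  independently at rate $\varepsilon$; qualities are a flat Phred value.
* **Counts**: at each timepoint, reads are a multinomial draw of the
  configured depth across all barcodes with probabilities
  $\propto f_b(0) 2^{s_b g}$. This models sequencing sampling, not
  population genetics: no drift, no PCR recombination or chimeras, no
  indels, no quality degradation. Passing tests therefore demonstrate
  correct inference under the stated model, not robustness to every
  artefact of real libraries.

Default study conditions are three timepoints at 0, 2.5 and 5 WT
generations (samplings spaced 2–3 generations apart).

## Numerical choices and problem sizes

* OLS slopes use the closed form on centred generations; $R^2$ is
  reported per barcode (undefined for zero-variance trajectories).
* Quartiles use linear interpolation (R type 7) everywhere.
* Hamming searches are exact: a hash for exact matches, then a vectorised
  full scan (chunked to bound memory) for the rest; results are
  guaranteed identical to exhaustive nearest-neighbour search with
  tie discard, and ties are discarded rather than randomly assigned to
  avoid leaking counts between alleles.
* The barcode-quality floor (mean Phred $\ge 20$ over the 18 barcode
  bases) is a conventional default, exposed as a flag.
* Validation runs use a 500-allele library (about 7,800 barcodes) for
  read-level oracles and the full ~1,500-variant library at sequencing
  depth $10^6$ per timepoint for recovery statistics; these sizes give
  stable statistics at interactive runtimes.

## Known limitations

* Consensus calling is alignment-free: ORF reads are fixed-frame and
  fixed-length, as the amplicon design guarantees; indels are out of
  scope.
* Whether the original analysis floored scores before or after averaging,
  and whether counts were depth-normalised before slope fitting, is not
  derivable from the pipeline description; both choices here (floor per
  barcode; normalisation only for the slope-ratio method) are documented
  above.
* Outlier flagging operates within one (condition, replicate); combining
  replicates before flagging is not attempted.
* The Lorentzian amplitude is histogram-normalisation-dependent by
  construction; only $X_0$ and $\Gamma$ are comparable across analyses.
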