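---
title: "Integrating destructive brain-slice readouts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating destructive brain-slice readouts: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoscape)
```

`hemoscape` analyses hemoglobin/heme toxicity experiments in organotypic
brain-slice cultures. This vignette explains the statistical models the
package implements, the assumptions behind them, the parameters that
matter, and the choices we made where the design was genuinely open. It
states no empirical result beyond what the package's tests and
acceptance script themselves compute.

## The integration problem

Each of the five readouts — tissue ⁵⁸Fe (ppb), normalized MDA
(µM g⁻¹ protein), heme-stress score, heme-metabolism score (both
arbitrary variance-stabilized units), and the apoptotic neuron fraction —
destroys the slice it is measured on. The data are therefore five
*unpaired* per-condition samples, and no per-slice multivariate vector
exists. The bootstrap pseudoslice device reconstructs a multivariate
sample whose margins are correct: for condition $c$ and replicate $b$,

$$\mathbf{x}_{cb} = (x_{cb1},\dots,x_{cb5}), \qquad
x_{cbk} \sim \widehat{F}_{ck} \; \text{i.i.d. with replacement},$$

where $\widehat{F}_{ck}$ is the empirical pool of readout $k$ under
condition $c$. Within a condition the five entries are independent by
construction — pseudoslices deliberately carry **no** within-slice
correlation, because none is observable. All cross-readout covariance in
the stacked matrix is therefore *between-condition* mean structure. This
is the central assumption to keep in mind: the PCA axes summarize how
condition means co-vary across readouts, not how readouts co-vary within
a slice.

With the five standard conditions (Ctrl, heme-albumin, heme-Hpx, Hb,
HbHp) and the default $B = 250$, the stacked matrix is $1250 \times 5$.
It is z-scaled *globally* (one mean and SD per column over all 1250
rows, divisor $n-1$), not per condition: scaling is a property of the
assembled matrix, and per-condition scaling would erase exactly the
between-condition structure the analysis is after. `run_pca()`
eigendecomposes the covariance of the scaled matrix (equivalent to
correlation PCA of the raw columns); explained fractions are
eigenvalue/trace.

Because eigenvector signs are arbitrary, `orient_components()` fixes a
biplot convention: the ⁵⁸Fe loading on PC1 and the heme-metabolism
loading on PC2 are made non-negative, so toxicity increases rightward
and adaptation upward. A zero anchor loading leaves the component
untouched and is recorded.

### Attractor states

The verbal state descriptions (Toxic, Sequestered, Adaptive, Baseline)
are made operational with an explicit interval rule. Each condition gets
a 2.5–97.5 percentile interval of its pseudoslice scores per axis;
relative to the control: the control itself is Baseline; a treated
condition whose PC1 interval clears the control's entirely is Toxic;
otherwise one whose PC2 interval clears it is Adaptive; any remaining
treated condition is Sequestered (it overlaps baseline despite a toxin
being present). The rule is deterministic and configurable through its
inputs; note two of its consequences. First, percentile intervals of the
pseudoslice *distribution* are wide, so Toxic requires a large
displacement. Second, Toxic is tested before Adaptive; under the
synthetic score presets below, HbHp's PC1 interval can clear the
control's, in which case the rule grades HbHp Toxic even though its
dominant displacement is adaptive (on the original deposited pools, the
reported state is Adaptive). We kept the priority order because a
condition that clears baseline on the damage axis has, by that
definition, measurable toxicity regardless of its adaptation.

## What the generators emulate — and what they do not

### Readout pools

Only per-condition mean ± SD and $n$ are published for each readout, so
`generate_readout_pool()` models a pool as a normal distribution
truncated to the readout's valid range (⁵⁸Fe ≥ 0, cell-death fraction in
[0, 1], MDA and scores unbounded). `default_presets()` transcribes every
published summary exactly (e.g. free Hb ⁵⁸Fe 0.202 ± 0.011 ppb, n = 6;
heme-albumin apoptotic fraction 0.543 ± 0.25, n = 15) and flags as
`assumed` the entries no publication provides:

- **Control ⁵⁸Fe.** No control iron value is published; the heme-Hpx
  level (0.056 ± 0.004 ppb), described as near-baseline, serves as
  proxy.
- **Score presets.** The transcript scores are in arbitrary units; the
  presets encode only the published ordinal ranking (heme stress:
  HemeHpx < Ctrl < HemeAlb < Hb < HbHp; heme metabolism elevated only
  for HbHp) with effect sizes of 1–1.5 pool SDs between adjacent
  conditions — chosen once as a realistic separation for gene-set scores
  averaged over ~50 genes and 8–19 samples.
- **Unpublished n.** ⁵⁸Fe n = 6 (the assay's published group size) is
  used for the groups whose n is not printed; the control cell-death n
  is set to 16, the midrange of the printed 13–18.

Pool sizes equal the printed per-assay $n$ (6–21). At these sizes a
randomly drawn pool's mean sits up to a few standard errors away from
the preset — occasionally far enough to reorder conditions on an axis.
That is faithful small-sample behavior, and the default
(`pools_from_presets()`) keeps it. For analyses that should reflect the
*printed* summaries themselves rather than one Monte-Carlo perturbation
of them — the acceptance checks of the map's qualitative structure, the
worked example in the README — `quantile_pools = TRUE` replaces each
random pool with the equally spaced quantiles of its generating
truncated normal: deterministic, in-range, and mean/SD-faithful up to
quantile discretization (the pool SD shrinks by ~5–15% at these $n$,
which global z-scaling absorbs).

The generators do **not** model inter-batch drift, assay detection
limits, ICP-MS measurement error, or any within-slice correlation
between readouts.

### Images

`generate_image()` renders disk-shaped cells with per-cell channel
intensities $\mathcal{N}(\mu, (\mathrm{cv}\,\mu)^2)$ and mild pixel and
background noise, two populations (viable: NeuN 12000/Casp3 800;
apoptotic: NeuN 800/Casp3 12000; cv 0.15 by default), non-overlapping
placement by rejection sampling (an infeasible packing is an error,
never a silent truncation), and a ground-truth table. The apoptotic
count is `round half up` of fraction × n, so exact mixing fractions are
representable. In log₁₀ space the default populations are ≈18 SD apart —
deliberately easy, because these fixtures test the *pipeline mechanics*
(segmentation accuracy, feature extraction, cluster labelling,
bookkeeping), not the hard segmentation problems of real confocal tiles:
no point-spread function, autofluorescence, overlapping somata, tissue
depth or GFAP channel. Passing tests show the pipeline recovers known
answers on clean input; they do not certify performance on real
microscopy.

Segmentation is Otsu thresholding on the nuclei channel plus connected
components and a minimum-area filter (default 20 px) — no watershed
splitting, which the non-overlapping fixtures do not need. Pixel
coordinates are 0-based (row, col). Features are log₁₀(x + 1); the
pseudocount makes zero intensity finite. k-means uses `stats::kmeans`
with 10 random restarts under a fixed seed (restarts, rather than a
specific seeding heuristic, make the two-cluster optimum reproducible on
separated data; with exactly two distinct cells the optimal partition is
assigned directly). Cluster naming is deterministic: the center with
higher mean log-Casp3 is apoptotic, ties broken by lower log-NeuN.
Clustering is per image by default; pooling across images is the
caller's choice of input.

### Count matrices

`generate_counts()` draws negative-binomial counts (dispersion 0.1 by
default) around log-normal baseline means scaled to a target library
size, with two disjoint spiked programs: heme-stress genes (default
log2FC per condition 0 / 1.5 / −0.5 / 2.0 / 2.5 for
Ctrl / HemeAlb / HemeHpx / Hb / HbHp) and heme-metabolism genes
(elevated only for HbHp, log2FC 2.0). The exact effect sizes are not
published; these defaults encode the published ordinal pattern with
magnitudes typical of strong stress responses. No length bias, GC bias,
batch effects or compositional outliers are simulated.

## Gene scoring dialect

The variance-stabilizing transform is median-of-ratios size factors
(reference: per-gene geometric mean over genes expressed in all
samples; factors are `exp(median(log ratio))`) followed by
`log2(normalized + 1)`. The DE ranker is a per-gene Welch $t$-test on
VST values with Benjamini–Hochberg adjustment and
`log2fc` = group-mean difference. This is a deliberately minimal,
fully documented stand-in for a count-based shrinkage model such as
DESeq2/apeglm: adequate to exercise score-set construction end-to-end
and calibrated under its own generator (the acceptance checks measure
type-I rate and power), but without shrinkage, count-level modelling, or
multi-factor designs — do not reuse it as a general DE tool.

The heme response set takes genes with adjusted p < 0.05 and positive
fold change, ranked by fold change descending (ties broken
lexicographically by identifier, making the set reproducible under row
shuffling), and keeps the top 50. Ranking by fold change rather than by
p-value is a recorded choice — the original construction does not state
its ranking key — and both `k` and the threshold are arguments. Scores
are unweighted per-sample means of VST values over the set; the curated
comparison sets (Nrf2, heme metabolism, iron transport) are injected as
external GMT gene lists, since the originals reference named database
collections. In the synthetic pipeline these stand-ins are halves of the
simulated programs, labelled as synthetic in the outputs.

## Numerical and degenerate-input policy

- Truncated-normal sampling is by rejection; an SD of 0 returns the
  constant pool (and errors if the constant violates the range).
- `zscale()` refuses already-scaled input and names any zero-variance
  readout; scaled columns satisfy |mean| < 1e-9, |SD − 1| < 1e-9.
- `run_pca()` requires more rows than columns; tiny negative eigenvalues
  from floating-point are clipped at zero before the explained-variance
  normalization. Loadings are orthonormal to 1e-9 and match an
  independent eigendecomposition oracle to 1e-8 in the tests.
- Empty segmentation output is a valid empty table; classification of
  < 2 cells or identical feature vectors is an error naming the
  degenerate condition.
- A negative TBARS ΔA passes through to a negative concentration:
  control-centered MDA is legitimately negative, so there is no flooring
  at zero. The homogenate dilution factor defaults to 10 (100 µL in a
  1000 µL reaction) and is overridable.
- The bootstrap consumes one seeded RNG stream in fixed condition-major
  order, so a seed pins the entire pseudoslice matrix bit-for-bit; all
  generator functions restore the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data at desk scale, chosen to exercise every code path with comfortable
statistical margins: B = 250 (5000 where a correlation bound is
asserted), 20 images of ~100 cells for fraction recovery, 2000–3000
genes with 8 samples per group for DE calibration, and 100 random
20 × 5 matrices for the PCA oracle. The full suite completes in well
under a minute of compute on a single core.

## Known limitations

- The PCA variance fractions and loadings computed from the synthetic
  presets are *not* the originally reported ones and cannot be: the
  deposited per-slice pools for the two transcript scores were never
  printed, and the score presets here are ordinal stand-ins. The package
  reproduces the structure of the map (which readouts co-load, which
  conditions separate, on which axis), not its exact numbers.
- Pseudoslices cannot recover within-slice correlations; any biology
  living in that covariance is invisible to this design.
- The attractor rule is one defensible formalization of a verbal
  description; its Toxic-before-Adaptive priority matters for borderline
  conditions (see above).
- The DE stand-in and the image generator trade realism for
  testability, as detailed in their sections.
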