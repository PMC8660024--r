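---
title: "Processing donor microarray data into regional expression matrices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing donor microarray data into regional expression matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(multigex)
```

## The problem

Brain-wide transcriptomic atlases sample gene expression from a handful of
post-mortem donors at stereotactically registered tissue sites. Before such
data can be related to imaging phenotypes they must be condensed into a
single brain-region-by-gene expression matrix, and every step of that
condensation — which microarray probe represents a gene, which tissue sample
belongs to which atlas region, how expression is normalized within and
across donors — admits several defensible choices. `multigex` implements the
full space of those choices as one configurable pipeline, the three
prototypical statistics used to summarize such matrices, and the multiverse
machinery to execute a grid of pipelines and quantify which choices move the
statistics most.

## The processing pipeline

`run_pipeline()` executes a fixed, canonical stage order:

1. **Probe reannotation** (optional): replace the release-time
   probe-to-gene annotations with an updated mapping; probes mapping to no
   gene are dropped at selection time.
2. **Intensity-based probe filtering** (optional): keep a probe only if it
   exceeds background in strictly more than a threshold fraction of all
   samples pooled across donors. Filtering always precedes probe selection;
   the reverse order could promote noisy probes into the analysis.
3. **Probe selection**: collapse redundant probes to one expression row per
   gene by one of six criteria — max intensity, highest mean correlation
   with the gene's other probes (falling back to max intensity or max
   variance for two-probe genes), differential stability (mean
   between-donor Spearman correlation of structure-averaged profiles),
   RNAseq fidelity, or averaging. Criteria that operate on samples admit
   three donor modes: pooled across donors, independent per donor, or the
   most commonly selected probe applied to all donors. Averaging,
   differential stability and RNAseq fidelity are inherently cross-donor,
   so the donor mode is redundant for them and is fixed to the pooled form;
   this collapse is also what the grid-counting machinery encodes.
   All argmax ties break to the lowest probe id, making every selection
   deterministic.
4. **Coordinate correction** (optional): replace the released MNI
   coordinates with an externally supplied corrected table.
5. **Mirroring** (optional): duplicate samples across the midsagittal
   plane (left-to-right, right-to-left, or bilaterally). Mirrored copies
   negate x, flip hemisphere, keep their expression, and receive fresh
   synthetic well ids. Samples at exactly x = 0 are excluded from
   mirroring.
6. **Inter-areal similarity filtering** (optional): drop samples whose
   mean Spearman correlation with the donor's other samples falls below a
   threshold.
7. **Assignment**: volumetric atlases map each sample through the inverse
   affine to its nearest voxel; unlabeled or incompatible hits fall back to
   the nearest labeled voxel within the tolerance (in mm). A
   hemisphere/structure-class compatibility gate prevents cross-midline and
   cross-class matches — important after mirroring. Surface atlases match
   each sample to the nearest labeled vertex of its hemisphere and then
   exclude samples farther from the surface than the donor mean plus
   `tolerance` standard deviations (n − 1 denominator, computed per donor).
   Nearest-voxel ties resolve to the most frequent label among the tied
   voxels, then the lowest region id.
8. **Sample normalization**: each sample's gene vector through z-score or
   scaled robust sigmoid (SRS).
9. **Gene normalization**: each gene across a donor's samples, optionally
   restricted to region-matched samples and/or applied separately within
   structural classes (cortex, subcortex/brainstem, cerebellum, white
   matter). Normalization is always per donor — its purpose is the removal
   of donor-specific differences, which pooling would defeat. Sample
   normalization precedes gene normalization; the package deliberately
   exposes no reordering, trading flexibility for a single reproducible
   contract.
10. **Aggregation**: the mean or median over a region's samples, either
    per donor and then across donors (`donors_first`) or pooled across all
    donors at once (so donors with more samples weigh more).
11. **Missing regions**: either left as flagged all-NA rows (the analyses
    drop them) or filled from the tissue sample nearest each donor's
    centroid, aggregated with the pipeline metric. Filling from the nearest
    *sample* (not the nearest filled region) follows the nearest-neighbour
    interpolation convention of the toolbox lineage this design follows.

The scaled robust sigmoid is
$y = \left[1 + \exp\left(-\frac{x - \mathrm{med}(x)}{\mathrm{IQR}(x)/1.35}\right)\right]^{-1}$,
rescaled to the unit interval. The 1.35 factor converts the IQR into a
normal-consistent scale estimate; when the IQR is zero the standard
deviation replaces it, and fully constant input maps to 0.5. All standard
deviations in the package use the n − 1 denominator. A constant vector
z-scores to zeros.

## The three analysis statistics

- **Correlated gene expression (CGE)**: Pearson correlation between region
  rows across genes, then the Spearman correlation between the strict upper
  triangles of the inter-centroid Euclidean distance matrix and the CGE
  matrix. Pearson builds the CGE matrix (continuous expression values);
  Spearman is reserved for the distance relationship, which is
  monotone-but-nonlinear. The relationship is plausibly exponential, but a
  rank correlation captures its direction and strength at a fraction of the
  cost of a nonlinear fit.
- **Gene co-expression (GCE) silhouette**: Euclidean distances between gene
  columns over non-missing regions; for externally supplied gene modules,
  $s_i = (b_i - a_i)/\max(a_i, b_i)$ averaged over genes, with singleton
  modules (and the degenerate $a_i = b_i = 0$ case) contributing 0.
- **Regional gene expression (RGE)**: gene columns are mean-centered, the
  first principal component's region scores extracted by SVD, and the
  absolute Spearman correlation with a regional phenotype reported —
  absolute because a principal component's sign is arbitrary.

All three drop missing regions and require at least three usable regions
(two modules for the silhouette); degenerate inputs (zero-variance
matrices, >10% undefined CGE pairs) raise classed errors rather than
returning quiet NAs.

## The multiverse machinery

A `parameter_grid()` is a declared list of options with ordered choices, a
measurement scale (binary / ordinal / categorical), and optional redundancy
rules. The rule used by the default grid declares the donor mode collapsed
to `aggregate` whenever the probe method is donor-independent, so the
17-option grid enumerates 746,496 distinct pipelines rather than the naive
1,119,744 — the count is computed in closed form (free options contribute a
product; the small rule-involved sub-grid is enumerated explicitly) and is
checked against the streamed enumeration.

Impact scoring groups pipelines into matched tuples that differ in exactly
one option, matching on *effective* (redundancy-collapsed) configurations:
tuples in which the varied option has no effective variation are skipped,
and duplicate effective tuples are counted once, so collapsed cells are
never double counted. Each tuple contributes the absolute estimate
difference (binary), the mean over adjacent choice pairs (ordinal), or the
mean over all unordered pairs (categorical); the impact score is the mean
over tuples, and ranks (1 = most impactful) are assigned per analysis with
ties broken by option declaration order. Impact scores are invariant to
shifting all estimates and scale with their magnitude, which the test suite
asserts. `pca_estimates()` mean-centers the pipeline-by-estimate table and
reports the first two principal components with their variance fractions.

## The synthetic-data generator

Testing any of this requires data whose correct answer is known.
`simulate_dataset()` plants, in order of importance:

- **A smooth spatial expression field.** Regional signals are Gaussian
  fields whose covariance is a mixture of two exponential kernels,
  `0.9 · exp(−d_folded/λ) + 0.1 · exp(−d/λ)` with λ = 40 mm by default:
  one kernel decays with distance between midline-folded coordinates
  (|x|, y, z), making homologous left/right regions strongly correlated —
  cortical expression shows minimal lateralization, which is precisely what
  justifies the mirroring step — and the other with true 3-D distance. A
  small iid asymmetry (sd 0.05) keeps hemispheres from being identical.
  The 40 mm default places most sampled inter-region distances on the
  informative part of the decay rather than its flat tail.
- **A dominant expression gradient.** One shared spatial field enters every
  gene with a Normal(0, 0.8) loading, giving the truth matrix a dominant,
  well-separated first principal component, as observed in cortical
  transcriptomes. The regional phenotype is this standardized-expression
  PC1 plus 5% noise — standardized, because the phenotype should track the
  dominant spatial gradient rather than the units of high-amplitude genes,
  matching how imaging phenotypes are compared against normalized
  expression.
- **Gene modules.** Genes are assigned round-robin to modules; 60% of each
  gene's spatial variance is the module's shared pattern.
- **Amplitude heterogeneity.** Per-gene signal amplitudes are lognormal
  (sdlog 1) and scale the module/idiosyncratic signal but *not* the
  gradient: genes with a large raw dynamic range are not more
  gradient-rich. Without gene normalization, analyses therefore become
  driven by a small subset of high-amplitude genes with idiosyncratic
  patterns — the textbook argument for normalizing genes, and the planted
  mechanism behind the impact-ranking checks.
- **Donor batch effects.** Each donor carries a per-gene offset built from
  a shared batch axis (heavy-tailed gene loadings, donor-specific
  severity — emulating global post-mortem batch differences) plus iid
  residuals, and a multiplicative scale jitter. Donors after the first
  sample only ~60% of their admissible regions, with lognormal weights, so
  regional donor composition varies across the brain; only the first two
  donors are sampled bilaterally (and carry gene-level RNAseq), the rest
  are left-hemisphere only.
- **Probe redundancy and failure.** Genes carry 1–4 probes with additive
  biases; a `background_fail_rate` fraction of probes is unreliable,
  failing the above-background call in 50–95% of samples (so the 25%/50%
  intensity filters actually discriminate), and failing probes are
  noisier.
- **Plumbing hazards.** One donor contains a sample placed far outside the
  atlas (exercising unassigned-sample paths), recorded MNI coordinates
  carry 0.5 mm error relative to the corrected table, and the emitted
  reannotation table drops every 50th probe's gene.

The volumetric atlas labels voxels (4 mm grid) by nearest same-hemisphere
centroid within 8 mm; the surface atlas scatters eight jittered vertices
per region, mirrored exactly. Samples jitter 1.5 mm around their region's
centroid, so matching tolerances of 1–2 mm behave realistically.

What the generator does *not* emulate: microarray physics (dilution,
probe-sequence affinity), ontology structure beyond the four structural
classes, realistic gene identities, or donor-specific anatomy. Passing
tests therefore demonstrate that the pipeline's bookkeeping and statistics
behave correctly under a faithful statistical caricature of such data —
not that any particular processing choice is optimal for real data.

## Problem sizes and determinism

The default simulation (6 donors × 100 samples, 150 genes × 1–4 probes, 30
regions) keeps a full pipeline run under a second and the 96-pipeline
reduced multiverse under two minutes on one core, which is the scale the
package's own test suite and acceptance script use. The reduced impact
grid varies gene normalization (3 choices), sample normalization (2),
aggregation metric (2), mirroring (2) and tolerance (4 ordinal values);
the recovery grid is the 2⁴ grid over gene/sample normalization, metric
and mirroring. Everything downstream of a seed is deterministic: same
seed, byte-identical donor directories, expression TSVs, estimate tables
and reports. Numeric output uses fixed significant-digit rendering (15 for
donor dialect files, 6 for expression matrices), so round-trips are exact
to the documented precision.

## Known limitations

- The volumetric assignment searches all labeled voxels per unassigned
  sample; fine (1 mm) whole-brain grids would want a spatial index.
- Impact scoring materializes the factorial of "all other options" per
  option; it is intended for reduced grids (the full 746,496-pipeline
  grid is counted and enumerated, not executed).
- `right_to_left` mirroring is implemented for completeness but excluded
  from the default grids, as it serves left-hemisphere-only analyses.
- The inter-areal similarity filter requires at least three samples per
  donor and is disabled in the default configuration.
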