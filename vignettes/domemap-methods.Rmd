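---
title: "Methods: models, generators and design choices in domemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators and design choices in domemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domemap)
```

# Scope

`domemap` re-implements, as tested and reusable code, a multi-platform
spatial analysis of gut-associated lymphoid tissue (GALT): suspension mass
cytometry of paired tissue/blood B cells, imaging mass cytometry (IMC)
phenotyping of segmented cells, distance-to-epithelium statistics, spot-level
spatial transcriptomics with spatially regularised clustering and region
differential expression, and pixel colocalization of in-situ transcripts.
Every stage can be driven by a synthetic tissue generator with known ground
truth, so each scientific claim of the pipeline is verifiable without any
external data. This vignette records the models, the generator's
assumptions, the numerical conventions, and the design decisions that were
genuinely open.

# The synthetic tissue generator

## Follicle geometry

`default_zone_map()` builds a concentric follicle: a lumen strip above a
flat follicle-associated epithelium (FAE) strip (thickness about 36 µm), a
subepithelial dome (SED) trapezoid below it, a germinal-centre (GC) disc
nested in a mantle (follicle) disc, a T-cell zone beside the follicle, and
lamina propria filling the remainder. Zones are simple polygons in
micrometres (origin top-left, y downward); nested polygons resolve by the
smallest-area-containing rule, so the same map drives cell placement, spot
zoning and annotation without special cases.

## Marker model

Marker intensities follow a two-component lognormal on the raw scale, with
levels *negative*, *dim*, *positive* and *high* (meanlog 0.3, 1.6, 3.2 and
4.2; sdlog 0.45–0.6). All cytometry statistics operate on
`asinh(x / 5)`-transformed values; cofactor 5 is the mass-cytometry
convention and is configurable per panel. A `separation` multiplier scales
the positive/negative gap so tests can dial difficulty.

## Suspension pairs

`simulate_suspension_pair()` draws, per donor, one GALT and one PBMC event
table. Subset compositions are the study conditions: DN2/3 at 12 % of GALT
B cells versus 6 % in blood (the configured two-fold tissue enrichment),
DN1 at 5 % in both compartments (the designed null), GC and plasmablast
fractions elevated in GALT. Donor-level composition noise is lognormal with
sd 0.10 on the proportion scale — modest inter-donor variability, which
gives a paired design with five donors realistic power without making the
comparison trivial.

## IMC regions of interest

`simulate_imc_roi()` places about 2,500 segmented cells per ROI by
zone-weighted point processes. Conventions worth stating:

* Epithelial cells fill the FAE strip. Intraepithelial DN B cells (IEDN) are
  placed first and locally displace the epithelium (a 9 µm exclusion
  radius); DN2 cells sit 60 % inside the FAE and 40 % in a 15 µm
  subepithelial band. These two conventions reproduce the ordering observed
  in the source tissue — DN2 consistently closest to the epithelium among B
  subsets — *by construction*; they are simulator conventions, not
  measurements.
* Myeloid (CD11c/CD11b/CD68) cells are DNASE1L3-positive with probability
  0.8 inside the SED and 0.15 elsewhere; among positive cells, lysozyme and
  NOX2 positivity is likewise SED-enriched. This encodes the subepithelial
  DNASE1L3/microbicide co-expression the spatial contrasts are meant to
  recover.
* Observed raw intensity = inverse-arcsinh of (true transformed value +
  per-ROI batch shift, sd 0.15) mixed through the spillover matrix
  (default: unit diagonal with 4 % nearest-channel leakage). Cell areas are
  lognormal with about 5 % below the 11-pixel QC limit; 2 % of cells are
  low-DNA debris and 2 % are CD20+CD3+ doublets, so the QC and
  mutual-exclusion rules have something to do.

## Spot transcriptomes

`simulate_spot_sample()` lays spots on a Visium-like hex grid (100 µm
pitch, 6-neighbour adjacency; square/4-neighbour supported) over the same
follicle geometry. Counts are negative binomial (gene dispersion 0.2) with
lognormal library sizes and a halved lumen library. Gene programmes encode
the tissue's published expression structure:

* The SED programme (DNASE1L3 at fold change 4 — deliberately the largest —
  C1QB/C1QA at 3, C3/C1R at 2.5, C1S at 2, ITGAX at 2.5, CCL20 at 2) with
  three structural features: FAE spots carry the SED programme at ~0.7
  strength (55 µm spots straddle the epithelium and the dome, which is also
  why the analysis merges FAE spots into the SED class); the programme
  decays exponentially into the follicle (length scale 250 µm, matching
  complement expression at the follicle periphery); and all its genes share
  one per-spot lognormal abundance factor (sdlog 0.9 in the dome, 0.7
  elsewhere) representing the fluctuating density of the dendritic cells
  that co-express them. The shared factor is what makes DNASE1L3–C1Q
  Spearman correlations strong, as in the source tissue.
* Structural programmes — follicle (MS4A1, IGHD, IGHM, TCL1A…), GC (BCL6,
  AICDA, MKI67…), T zone (CD3D/E, TRAC, CCL19/21), epithelium (EPCAM,
  KRT8, OLFM4, CCL20/23), lamina propria and lumen — are stable (no shared
  abundance factor), so spatial clustering has clean zone signals. Each
  zone also carries six synthetic filler marker genes (`PRG.<zone>.<i>`).
* Programme genes share a fixed moderate baseline (mean 8 counts at unit
  library) so that differential-expression strength is ordered by the
  configured fold changes; 600 null genes with lognormal baselines form a
  stable background so that library-size normalisation does not couple
  unrelated genes through the divisor.
* Sample `"STB"` carries a gene-wise lognormal batch factor (sdlog 0.15)
  for integration tests.

`simulate_program_lattice()` is a separate calibration generator: a lattice
split into a configurable number of contiguous, equally prominent
programmes. Cluster-number tuning is evaluated on it, because recovering a
programme count by an elbow criterion presupposes programmes of comparable
prominence — the tissue generator's zones (21-spot FAE versus 400-spot
lamina propria) are deliberately not that.

## What passing tests do and do not show

The generator emulates zone structure, marker bimodality, spillover, batch
shifts, count overdispersion and programme co-expression. It does not
emulate segmentation errors, ablation artefacts, cell-shape effects,
spatial gradients within the epithelium, or the full transcriptome. Tests
passing on this ground truth therefore validate the pipeline's logic and
statistics, not its robustness to every artefact of real acquisitions.

# Stage models and conventions

## Statistical primitives

Paired/unpaired two-tailed t tests delegate to `stats::t.test` (Welch by
default for unpaired data — figure-style legends rarely state a variance
convention, and Welch is the robust default; pooled Student is a flag).
Zero-variance inputs return an explicit degenerate flag with p = 1 for
identical groups instead of raising, so batch reports can proceed. The
Wilcoxon rank-sum test uses midranks with exhaustive enumeration up to 16
total observations (valid under ties) and a tie-corrected,
continuity-corrected normal approximation above; `stats::wilcox.test` is
used as an independent oracle in the tests. Holm and Bonferroni adjustments
delegate to `stats::p.adjust`. Spearman's rho is the Pearson correlation of
midranks with the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`, exact
permutation for n ≤ 7 without ties.

## Suspension stage

Equal-event subsampling (default 9,214 events per sample) precedes
density-dependent downsampling: local density is the number of neighbours
inside a kernel radius calibrated as the median distance to the 15th
nearest neighbour, and points are kept with probability
`min(1, target / density)` (target: the 3rd density percentile). The
density estimate is a neighbour count rather than an inverse mean distance
because only a count scales linearly with true density in any dimension —
with an inverse-distance estimate, a four-fold denser blob would be thinned
only two-fold in 2-D. The tree is built by k-means (default 100 nodes) on
the 12 dimension-reduction markers, with a minimum spanning tree over node
medians and nearest-node upsampling of all events. Any 2-D embedding can be
attached for display; the tree is built directly in transformed marker
space because clustering quality, not the embedding, is what the stage's
claims rest on.

Bubble assignment replaces manual gating with an ordered rule table of
required-high/required-low markers (the canonical subset phenotypes,
including DN2/3 = CD27-/IgD-/CD21-low/CD11c-high), evaluated on node
medians against per-marker thresholds from pooled two-component Gaussian
mixture fits (in-package EM, quantile-initialised; threshold = midpoint of
the component means; degenerate fits fall back to a quantile rule with a
warning). Events whose nearest and second-nearest nodes carry different
bubbles are re-assigned by full-panel profile distance — the same use of
key markers (CD11c, CD21) an analyst makes when adjudicating nodes at
bubble boundaries; without it, DN1/DN2-3 boundary mixing produces a small
composition-dependent bias in the null subset's paired test.

## Imaging stage

QC removes cells below 11 px or with mean DNA below the 1st per-ROI
percentile (floor: 1 count). Spillover compensation solves
`observed = true %*% S` per cell by non-negative least squares; cells whose
unconstrained solve is already non-negative take the exact linear solution
and only the remainder go through the active-set solver, so compensated
intensities are never negative and the noise-free round trip is exact to
numerical precision. Gating evaluates every gate independently per image
(two-component mixture thresholds per channel per image): exactly one match
labels the cell, zero or several matches — including the CD20+CD3+
neighbour combination — leave it unassigned; independence of gate
evaluation makes the labelling order-invariant by construction. A
500-tree random forest trained on the gated cells (70 %/30 % split)
propagates labels to unassigned cells; gated labels are never overwritten
and accuracy is reported on the held-out gated cells only.

Batch integration is a Harmony-style simplification: PCA, then alternating
entropy-penalised soft k-means and per-cluster per-batch linear centroid
shifts, with batch centroids pinned to the global mean before and during
iteration so a constant offset is removed exactly. Contract-level
behaviour — batch mixing improves, biologically distinct subsets stay
separate — is what the tests assert; algorithmic identity to the reference
implementation is not claimed. B cells are then clustered by k-means
(k = 12 by default; the source analysis merged an unreported number of
clusters) on the corrected embedding, and clusters are named by the same
rule machinery, including IEDN (DN + E-cadherin-high, the epithelial
marker carried over from neighbouring cells) and DN2 (DN + CD11c-high,
CD21-low).

## Spatial statistics

Distances to the epithelium are Euclidean centroid-to-centroid per ROI
(never across ROIs), exactly equal to the brute-force minimum — the blocked
computation uses explicit coordinate differences so it is bitwise identical
to the naive formula. Whether the source measurements used centroids or
boundaries is unknowable from the text; a `self_exclude` flag covers the
epithelial-cell convention. Group contrasts default to ROI-level paired
summaries (legends report n as ROIs); pooled per-cell Welch tests are the
`unit = "cell"` option. Positivity thresholds default to mixture fits on
cell tables and Otsu on rasters; every report records the method. Object
segmentation is Otsu + connected components (4- or 8-connectivity) with a
minimum-diameter filter; colocalization is the fraction of signal-positive
pixels inside the reference mask, `NaN` with a warning when no pixel is
signal-positive.

## Spot stage

One normalisation — `log1p(count / total * 1e4)` — serves both clustering
and differential expression (the source analysis used a variance-stabilised
transform for the manual-region DE; the DE here is rank-based and therefore
insensitive to monotone per-gene transforms, which is why a single code
path is acceptable). Variable genes are ranked by variance standardised
within 20 mean-expression bins; PCA runs on the scaled HVG submatrix
(defaults: 2,000 genes, 15 components).

The spatial clustering model is a Gaussian mixture over the PCs with a
Potts prior: the full conditional for spot i is proportional to
`N(pc_i; mu_k, Sigma) * exp(2 * gamma * n_ik / deg_i)`. Two conventions
matter. First, the neighbour term carries the factor 2 of the reference
spatial-clustering model (each edge counted from both ends); with the
halved exponent, gamma = 2 under-smooths and cannot reach the intended
accuracy at moderate separation. Second, the component covariance is a
shared *full* (pooled within-cluster) matrix rather than spherical:
principal components carry correlated technical structure (library-size
gradients), and under a spherical model each extra cluster keeps absorbing
that structure so the likelihood improves linearly in q and no elbow ever
forms. Spherical remains available (`covariance = "spherical"`). Updates
are chromatic Gibbs sweeps (colour classes updated jointly — exact, since
a colour class is conditionally independent given the rest), moment
updates for the parameters, and the final label is the per-spot marginal
mode over post-burn-in samples; defaults are 1,000 sweeps with 200
burn-in, initialised by k-means under the chain's seed.

`tune_q()` runs short chains over a q range and records the negative
profile data log-likelihood (mean of the final quarter of the trace). The
suggested q is the maximum-discrete-curvature point of the normalised
curve, declared only when that curvature exceeds twice the median absolute
deviation of the curvature sequence — structureless data improves at a
near-constant, jittery rate and then no elbow is credible, so the smallest
candidate is returned. The suggestion is advisory, exactly as a tuning plot
is: per-sample overrides (q = 7 and q = 8 for the two reference samples)
are respected downstream.

Lymphoid-cluster selection scores clusters by mean B-lineage marker
expression (MS4A1, IGHD, IGHM) and flags ties instead of guessing.
Sub-clustering merges samples over common genes, selects variable genes,
standardises, applies the batch integration with sample as batch, k-means
with 5 subclusters (the number of regional clusters reported for the
reference samples), and names subclusters by marker-set scores (GC;
SED/epithelium — including the epithelial markers, since dome and
epithelium merge at spot resolution; T zone; follicle). Clusters sharing a
name merge into one region, mirroring the merge-and-classify workflow of
the source analysis. Because the dome programme decays smoothly into the
follicle, upper-follicle spots are genuinely intermediate and region
alignment with the hard zone labels plateaus around ARI 0.7 — a property
of the generator's (realistic) graded boundaries, not of the clustering.

Region DE applies the 0.25 log-fold-change (difference of mean
log-normalised expression, natural log) and 10 % minimum-detection filters,
tests passing genes by the Wilcoxon rank-sum test, adjusts by Bonferroni
over the tested set, and sorts by adjusted p then absolute log-fold change;
filtered genes are flagged, never dropped. FAE spots are merged into the
SED class before this contrast. The gene-gene correlation matrix is
pairwise Spearman over the selected spots with Holm across the unique
pairs.

# Orchestration

`run_pipeline()` executes the stages in dependency order on synthetic
inputs from a single validated configuration (`pipeline_config()`, YAML
round-trip, unknown keys rejected), collects warnings, and writes a
reproducible report bundle (CSV/JSON). All randomness flows from the
configuration seed through per-object hashed RNG streams, so adding an
output never perturbs another and reruns are identical. The demonstration
configuration (3 donors, 4 ROIs, a 24 x 24 spot sample) completes in a few
minutes on one CPU; the test suite and the acceptance script use reduced
problem sizes (400–600 events per sample, 2–16 ROIs, 16 x 16 to 40 x 40
lattices), chosen as the smallest sizes at which each property is
statistically decidable.

# Known limitations

* The generator's zone boundaries are polygonal and its programme
  gradients smooth; real follicles are irregular and their gradients
  anisotropic.
* Bubble/gate thresholds assume marker bimodality; unimodal channels fall
  back to quantile rules with warnings rather than failing.
* The Potts sampler asserts contract-level behaviour (spatial coherence,
  gamma = 0 reduction, elbow recovery on balanced programmes), not
  numerical identity to any reference implementation.
* Batch integration is a linear-shift model; nonlinear batch distortions
  are out of scope.
* Colocalization and segmentation operate on single 2-D channels;
  z-stacks and intensity-watershed declumping are out of scope.
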