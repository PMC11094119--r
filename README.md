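# domemap

Spatial multi-omic mapping of gut-associated lymphoid tissue (GALT).

GALT follicles sit at the boundary between the gut microbiota and the host:
luminal antigen crosses the follicle-associated epithelium (FAE) into the
subepithelial dome (SED), where it first meets immune cells. Recent work has
placed two unexpected players in that niche — DN2 B cells
(CD27⁻IgD⁻CD21^lo CD11c^hi, a subset otherwise associated with lupus) and
dendritic cells co-expressing the lupus autoantigens DNASE1L3 and C1q.
Characterising this microenvironment takes four platforms at once:
suspension mass cytometry of paired tissue/blood B cells, imaging mass
cytometry (IMC) of segmented cells, spot-level spatial transcriptomics, and
in-situ transcript colocalization.

`domemap` implements that analysis as one tested R package, driven end to
end by a synthetic GALT generator with known ground truth, so every stage's
claim is verifiable without external data:

* **`stats_core`** — arcsinh transforms, paired/Welch t tests with explicit
  degenerate handling, Wilcoxon rank-sum with exact enumeration (midranks,
  n ≤ 16) or tie-corrected normal approximation, Holm/Bonferroni, Spearman
  correlation.
* **Synthetic tissue** — `sim_config()`, `simulate_suspension_pair()`,
  `simulate_imc_roi()`, `simulate_spot_sample()`, `simulate_coloc_raster()`,
  `simulate_program_lattice()`: zoned follicle geometry, two-component
  lognormal marker models, spillover, per-ROI batch shifts, negative-binomial
  spot counts with zone programmes (DNASE1L3 carrying the largest SED fold
  change), rasters with requested overlap fractions — plus complete ground
  truth.
* **Suspension stage** — equal-event subsampling (9,214 per sample),
  density-normalised downsampling, SPADE-style k-means tree with a minimum
  spanning tree and full upsampling, declarative subset "bubbles"
  (`default_b_subset_rules()`), paired GALT-vs-PBMC proportion tests.
* **Imaging stage** — QC (< 11 px, low DNA), non-negative least-squares
  spillover compensation, mutually exclusive per-image gating (B, T,
  Macrophage/DC, endothelium, epithelium; CD20⁺CD3⁺ never assigned),
  random-forest label propagation (70/30 split), Harmony-style batch
  integration, B-subset clustering and rule-based naming (incl. IEDN and
  DN2).
* **Spatial statistics** — exact nearest-epithelium distances per ROI,
  polygon zone assignment, positivity calling, ROI-level paired contrasts,
  blob segmentation, pixel colocalization fractions.
* **Spot stage** — log-normalisation, binned-variance HVGs, PCA, hex/square
  spot graphs, Potts-prior Gibbs clustering
  (`potts_cluster()`; full conditional ∝ N(pcᵢ; μ_k, Σ)·exp(2γ·n_ik/degᵢ)),
  cluster-number tuning (`tune_q()`), lymphoid-cluster selection and
  subclustering, SED-vs-follicle differential expression (0.25 logFC, 10 %
  detection, Wilcoxon + Bonferroni), Spearman/Holm gene–gene correlation
  matrices.
* **Orchestration** — `pipeline_config()` / `run_pipeline()` with one seed,
  per-object RNG streams and a reproducible report bundle.

## Worked example

Simulate five donor pairs with the configured two-fold DN2/3 enrichment in
GALT and run the suspension stage:

```r
library(domemap)

cfg  <- sim_config(seed = 11)
pair <- simulate_suspension_pair(cfg, n_donors = 5, n_events = 500)
st   <- run_cytof_stage(pair, n_per_sample = 400, k_nodes = 100, seed = 11)
subset(st$report$report, group %in% c("DN1", "DN23"),
       select = c(group, statistic, p_raw))
#>      group statistic       p_raw
#> DN1    DN1 -1.299688 0.263548537
#> DN23  DN23  4.839482 0.008403239
```

The enriched DN2/3 subset is detected (paired p ≈ 0.008, GALT mean higher),
while the no-effect DN1 subset stays null (p ≈ 0.26) — the Fig-1-style
readout the stage exists for.

Distances to the epithelium on a simulated IMC region:

```r
roi  <- simulate_imc_roi(cfg)
meta <- roi$cells$meta
meta$lineage_full <- roi$ground_truth$lineage
d <- nearest_epithelial_distance(meta)
b <- roi$ground_truth$lineage == "B"
sort(round(tapply(d[b], roi$ground_truth$subset[b], median), 1))[1:3]
#>   DN2  IEDN PB/PC
#>   7.4  10.4 120.9
```

DN2 B cells sit closest to the epithelium, ahead of intraepithelial DN and
every other subset. Spot-level clustering and differential expression:

```r
sa <- simulate_spot_sample(cfg, "STA")
pp <- preprocess_spots(sa$counts)          # 2000 HVGs, 15 PCs
g  <- build_spot_graph(sa$spots)           # hex, 6 neighbours
z  <- sa$ground_truth$zone
region <- ifelse(z %in% c("SED", "FAE"), "SED",
                 ifelse(z %in% c("mantle", "GC"), "Follicle", "none"))
de <- region_de(sa$counts, pp$norm, region)
head(subset(de, tested & logFC > 0, select = c(gene, logFC, p_adj)), 3)
#>       gene    logFC        p_adj
#>   DNASE1L3 1.332054 2.719407e-26
#>       C1QA 1.026124 2.112186e-18
#>       C1QB 1.006643 5.275479e-18
```

DNASE1L3 tops the SED-enriched table, mirroring the headline finding the
generator encodes.

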