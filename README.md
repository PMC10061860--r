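# cottontraits

Architectural trait extraction from labeled 3D point clouds of single cotton
plants.

Plant architecture — node and branch counts, boll number, stem size, branch
angles — drives yield and informs breeding, but measuring it by hand is slow
and error-prone. Terrestrial LiDAR of defoliated plants plus semantic
segmentation of the cloud into **main stem / branch / boll** makes the
measurement automatic. This package implements everything around the
segmentation model: preprocessing of raw clouds, correction of the
stem/branch confusion segmentation leaves behind, extraction of seven
architectural traits from the labeled cloud, segmentation quality metrics,
and a procedural simulator of labeled cotton plants with known ground truth
for validating the whole chain.

It is aimed at plant-phenotyping researchers who have (or plan to produce)
per-point part labels for single-plant clouds and want reproducible,
scriptable trait measurements.

## The method in brief

For a labeled cloud with points \(p_i \in \mathbb{R}^3\) (meters, z up):

* **Preprocessing** — statistical outlier removal (mean distance to k = 6
  nearest neighbors, threshold \(\mu + \sigma\)); unit-sphere normalization
  \(p_i' = (p_i - \hat p)/\max_k \lVert p_k - \hat p \rVert\) with exact
  inversion; uniform random down-sampling to 100k points.
* **Label correction** — 1 cm slices walked up the stem; per slice, branch
  points inside the previous slice's x/y bounds (+1 cm margin, second round
  +1.2 cm) become stem, stem points outside become branch. Corridor drift is
  damped to half a margin per slice so attachments cannot drag the corridor
  into a branch.
* **Traits** — stem height (z-span of stem points); stem diameter (Pratt
  circle fit on the bottom 1 cm projected to xy); branches (two-stage
  DBSCAN: size filter at eps 2 cm / minPts 100, then per-branch clustering of
  points within 2 cm of the stem); nodes (clusters whose minima lie within
  1 cm share a node); branch inclination (angle of the first principal
  component above the horizontal); branch diameter (Rodrigues rotation of the
  branch onto \(\hat z\), then a base-slice circle fit); boll count (DBSCAN at
  eps 5 mm / minPts 100, 3 cm height filter, connected bolls resolved by the
  Q3 + 1.5 IQR cluster-size rule).
* **Metrics** — per-class precision/recall/IoU/F1 from exact confusion
  counts, pooled accuracy, and per-cloud-averaged mean IoU.

## Worked example

```r
library(cottontraits)

# simulate a labeled plant with known ground truth
pl <- generate_plant(plant_spec(stem_height = 1.0, stem_diameter = 0.016,
                                n_branches = 6L, n_bolls = 10L, seed = 42))
pl$truth
#> <ground_truth> stem 1.002 m x 16.0 mm | 6 branches, 6 nodes | 10 bolls
#>   branch angles 20.7-36.7 deg, diameters 7.4-9.9 mm

# inject segmentation-like errors, correct them, extract traits
noisy <- perturb_labels(pl$cloud, "boundary_swap", fraction = 0.02,
                        region_size = 0.01, seed = 1)
noisy <- perturb_labels(noisy, "region_flip", region_size = 0.02,
                        from = "main_stem", seed = 2)
fixed <- correct_stem_branch(noisy)
extract_all(fixed)
#> <plant_traits>
#>   main stem:  height 1.005 m, diameter 16.1 mm
#>   branches:   6 (nodes: 6)
#>     inclination 21.5-37.2 deg, diameter 7.6-10.1 mm
#>   bolls:      10
```

Every count is recovered exactly and the continuous traits land within a few
percent of truth despite ~3,000 corrupted labels. On a real cloud you would
start from `read_cloud("plant.ply")` (labels from the `label` vertex
property, or inferred from the red/green/blue annotation colors) and run
`run_pipeline()`, or use the shell interface:

```sh
cottontraits traits plant.ply --out traits.json
cottontraits evaluate --pred pred.ply --truth truth.ply --out report.json
```

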