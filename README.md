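# gliaclust

Morphometric profiling and unsupervised clustering of microglia from
binary segmented photomicrographs.

Microglia shift along a continuous morphological spectrum — from compact
amoeboid cells through reactive intermediates to highly ramified
homeostatic cells — and that spectrum is a sensitive readout of
neuroinflammation. Predefined categories miss subtle transitions, so
`gliaclust` instead quantifies every segmented Iba-1+ cell with a rich
feature set and lets the structure emerge from unsupervised clustering,
then maps the clusters back onto the tissue to localize where each
morphology concentrates. It is aimed at neuroscience labs that already
produce binary masks of immunostained microglia (e.g. thresholded and
manually reconstructed in ImageJ/Fiji) and want a reproducible,
scriptable analysis of those masks.

## The pipeline

Five stages, each exposed as plain R functions and orchestrated by
`run_pipeline()`:

1. **Morphometry** — each connected component becomes a cell and yields
   32 features across five families:
   * *Skeleton* (`Sk_`): total branch length, initial points (processes
     leaving the soma), junctions, endpoints, from a topology-preserving
     Zhang–Suen skeleton;
   * *Soma* (`So_`) and *whole cell* (`C_`): area *A*, perimeter *P*
     (4-direction Crofton estimate), circularity 4πA/P² (1 = perfect
     disk), Feret diameter, compactness √(4A/π)/Feret, aspect ratio,
     orientation, eccentricity (major/minor axis); the soma is the
     largest component surviving a disk opening;
   * *Fractal / convex hull* (`F_`): the same eight shape descriptors on
     the filled convex hull, plus the box-counting fractal dimension
     (−slope of log N(s) vs log s over dyadic box sizes);
   * *Sholl* (`Sh_`): number of concentric circles around the soma
     centroid that reach the skeleton, total crossings (connected runs
     per one-pixel annulus), and maximum centroid-to-image-corner
     distance.
2. **Feature selection** — recursive feature elimination with a
   random-forest engine drops the least important feature per iteration
   until half remain (32 → 16 by default), supervised by the study-group
   labels.
3. **Dimensionality reduction** — UMAP on the z-scored selected
   features (`n_neighbors = 10`, `min_dist = 0.1`, `n_components = 2`),
   single-threaded for bit-reproducibility.
4. **Clustering** — HDBSCAN (implemented in the package: mutual
   reachability, MST, condensed tree, excess-of-mass extraction) with
   `min_cluster_size = 20`, `min_samples = 10`; low-density cells are
   labelled noise (−1) and excluded from all downstream statistics.
5. **Spatial analysis & statistics** — cluster-coloured cells are
   painted back onto the image; counts per anatomical layer polygon
   (e.g. CA1 strata SO/SPyr/SR) and per lateral-distance bin
   (0.24 mm bins from 0.48 mm); chi-square independence test on the
   cluster × group table with Pearson and adjusted standardized
   residuals; z-scored feature heatmaps; Mann–Whitney U tests on
   per-image counts.

A synthetic generator (`make_cell()`, `make_scene()`,
`generate_dataset()`) produces mask images from parametric morphology
archetypes with known ground truth, so the whole pipeline is testable
without tissue data.

## Worked example

```r
library(gliaclust)

# synthetic two-group dataset: masks + metadata sidecar
paths <- generate_dataset(file.path(tempdir(), "demo"), seed = 7)

res <- run_pipeline(list(
  input  = list(mask_dir = paths$mask_dir, metadata_csv = paths$metadata),
  hdbscan = list(min_cluster_size = 8, min_samples = 4),
  output = list(dir = file.path(tempdir(), "demo_run"))
))

print(res$clusters)
#> <glia_clusters> 80 points, 3 cluster(s), 0 noise (min_cluster_size=8, min_samples=4)
#>  0  1  2
#> 36 24 20

res$contingency
#>        group
#> cluster SCOP SS
#>       0    8 28
#>       1   17  7
#>       2   15  5
round(res$chisq$statistic, 2)
#> [1] 20.28
```

Reading: 80 synthetic cells were segmented from 8 images; HDBSCAN found
three morphology clusters and no noise at this small scale. The
contingency table shows cluster 0 (ramified cells) concentrated in the
SS-like group while clusters 1 and 2 (compact and reactive-like cells)
sit mostly in the SCOP-like group; the chi-square statistic of 20.28 on
2 df confirms the cluster-group association. The run directory contains `features.csv`,
`selection.csv`, `embedding.csv`, `clusters.csv`, painted PNG overlays,
heatmap matrices and the chi-square report.

A command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "gliaclust", package = "gliaclust"))') \
    run --config analysis.yaml
```

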