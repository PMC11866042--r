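# hecif

Continuous fibrosis scoring of bone-marrow trephines from H&E images.

## The problem

Bone-marrow fibrosis in myeloproliferative neoplasms is conventionally
graded on reticulin-stained trephine sections with the semiquantitative
WHO MF scale (0–3). Reticulin silver stains are fragile: their intensity
varies between laboratories, decalcified bone detaches during
restaining, and the analysable intertrabecular area shrinks accordingly.
`hecif` quantifies fibrosis directly from the routine H&E stain as a
**continuous score** — CIF, Continuous Indexing of Fibrosis, in [0, 1] —
so that the slide that already carries the core diagnostic information
also yields the fibrosis estimate.

The score comes from a **ranking model** trained with ordinal
supervision only: for pairs of tiles whose teacher labels differ by at
least a gap δ, a shared scorer *f* is fitted by minimising the pairwise
logistic (RankNet) loss

    L = Σ log(1 + exp(−(f(x_i) − f(x_j)))),   y_i − y_j ≥ δ,

and raw scores are mapped to [0, 1] by min–max calibration over the
training scores. The slide score is the mean CIF of its analysable
tiles (fat < 50%, bone < 1%, both strict).

Around the model the package provides the full pipeline:

* **`phantom`** — synthetic paired-stain slides (pseudo-H&E +
  pseudo-reticulin) with a known latent fibrosis field, bone/fat
  compartments, a known affine misalignment, per-slide stain drift and
  bone-loss artefacts, so every stage is testable without clinical data;
* **`tiling`** — tissue masking, fixed-grid 512 px/113 µm tile
  extraction, exact composition fractions, analysability filter;
* **`register`** — affine estimation between co-sectioned stain pairs
  from their tissue masks (moments + IoU refinement), tile pairing;
* **`preprocess`** — channel-wise histogram equalisation;
* **`cifmodel`** — pair construction, ranking-network training,
  calibration, CIF maps, pairwise prediction accuracy, false-colour
  heatmaps;
* **`qc`** — dominant stain colour in RGB/CIELAB, cohort colour
  variation, bone area (mm²), analysable tile counts;
* **`subsample`** — biopsy-adequacy curves by spatial subsampling at
  2/15 … 10/15 of the analysable area and the heterogeneous/homogeneous
  call (deviation > 0.1 at the smallest fraction).

## Worked example

Simulate a two-slide paired-stain cohort with known severities (0.15 and
0.85), register one pair from its masks, and run the pipeline end to
end:

```r
library(hecif)

specs <- list(
  mild   = phantom_spec(width_px = 384, height_px = 384, mpp = 1.18,
                        fibrosis_field = list(type = "constant", value = 0.15),
                        misalignment = list(rotation_deg = 3,
                                            translation_px = c(12, -7), scale = 1),
                        n_bone_blobs = 1, fat_fraction = 0.08, seed = 1),
  severe = phantom_spec(width_px = 384, height_px = 384, mpp = 1.18,
                        fibrosis_field = list(type = "constant", value = 0.85),
                        misalignment = list(rotation_deg = -2,
                                            translation_px = c(-6, 4), scale = 1),
                        n_bone_blobs = 1, fat_fraction = 0.08, seed = 2))
manifest <- simulate_cohort(specs, "cohort")

pair <- generate_phantom(specs$mild)
estimate_affine(pair$reticulin_tissue_mask, pair$tissue_mask)
#> <affine_transform>
#>          [,1]      [,2]      [,3]
#> [1,] 0.998637 -0.052255  22.26516
#> [2,] 0.052255  0.998637 -16.74000
#> rotation 2.995 deg, scale 1.0000, translation (22.27, -16.74)

res <- run_end_to_end(manifest, "run",
                      pipeline_config(tile_size = 64L,
                                      ranking = ranking_config(epochs = 40, seed = 3),
                                      draws = 10L, seed = 9L))
res$model
#> <cif_ranker> 96 features -> 16 hidden -> score; logistic loss
#> trained on 27 tiles / 108 pairs, 40 epochs; final loss 0.0006

round(res$validation_accuracy, 3)
#> [1] 1

sapply(res$samples, function(s) round(cif_aggregate(s$cif_map), 3))
#>   mild severe
#>  0.009  0.956

sapply(res$samples, function(s) classify_heterogeneity(s$subsample))
#>          mild        severe
#> "homogeneous" "homogeneous"
```

The registration recovers the planted 3° rotation to 0.005°. The
held-out pairwise accuracy is 1 (every validation pair with a ≥ 0.1
label gap is ordered correctly). The slide aggregates — 0.009 for the
mild phantom, 0.956 for the severe one — track the planted severities;
CIF is calibrated to the training cohort's own score range, so the
least fibrotic material anchors 0 and the most fibrotic anchors 1.
Both constant-severity slides are called homogeneous: no 2/15-area
subsample strays more than 0.1 from its whole-slide score. The run
directory contains, per slide, the CIF table (`cif_<id>.csv`), a
viridis heatmap PNG, the fitted affine JSON, the subsampling JSON, plus
cohort QC (`qc.csv`) and a provenance record.

A command-line wrapper over the same functions is installed at
`inst/cli/hecif.R` (verbs `simulate`, `tile`, `register`, `preprocess`,
`qc`, `subsample`, `run`).

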