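# coccimorph

Quantitative morphometry of coccoid bacteria in high-resolution scanning
electron micrographs (HR-SEM), for microbiologists who already have instance
segmentations (e.g. from Cellpose) and need reproducible per-cell
measurements and group statistics: how much do cells swell, and how much
rougher do their surfaces get, under an antimicrobial treatment such as ZnO
nanoparticles?

The package owns everything downstream of segmentation:

1. **Regions** — each nonzero label of an instance mask becomes a region with
   area (pixel count), centroid and ordered outer contour; border-touching
   regions are flagged.
2. **Ellipse morphometry** — a direct least-squares conic fit constrained to
   an ellipse (Halir–Flusser) gives center, axis lengths and orientation;
   regions with fewer than 5 contour points or area < 1000 px²
   (0.183 µm²) are excluded as segmentation artifacts.
3. **Background filtering** — cells are neighbors when the minimum
   perimeter-to-perimeter distance between their fitted ellipses (100 sampled
   points each) is < 5 px (0.068 µm); a cell is removed when its area is
   < 0.7 × the mean area of its neighbors. This strips cells partially hidden
   behind others, whose visible footprint is artificially small.
4. **Surface texture** — each mask is eroded (7×7 kernel, 2 iterations), the
   [0,1]-normalized intensities inside are detrended with a full second-order
   polynomial surface *z = a₀ + a₁x + a₂y + a₃x² + a₄y² + a₅xy* (ordinary
   least squares), and the per-cell texture value is the rms residual. The
   polynomial absorbs illumination tilt and the smooth dome of an intact
   cell; the residual isolates high-frequency roughness of a damaged surface.
5. **Group statistics** — per-condition summaries of projected area (µm²) and
   texture, percent change of means versus the control, and Cliff's delta

   δ = (#{xᵢ > yⱼ} − #{xᵢ < yⱼ}) / (nₓ·n_y),

   categorized as large (|δ| ≥ 0.474), medium (≥ 0.33), small (≥ 0.147) or
   ns, with violin-plot output.

A synthetic scene generator (`generate_scene()`) renders shaded, noisy
ellipse "cocci" in chains — with known areas, orientations, roughness
amplitudes and planted occlusions — so every stage is validated against
ground truth rather than against another implementation.

## Worked example

```r
library(coccimorph)
cfg <- read_run_config(system.file("extdata", "example_config.yaml",
                                   package = "coccimorph"))
run <- run_pipeline(cfg)   # 2 conditions x 6 synthetic fields, seed 1
print(run)
```

```
morphometry run: 12 images, 540 segmented cells, 407 kept
group comparison vs control 'control'

per-group summaries:
   group   n          area_um2           texture
 control 203 0.4041 +/- 0.0893 0.0219 +/- 0.0010
 zno_200 204 0.4390 +/- 0.1122 0.0291 +/- 0.0012

comparisons vs control:
   group        metric change delta effect
 zno_200      area_um2  +8.6% 0.152      *
 zno_200 texture_value +32.5% 1.000    ***
```

Reading the output: of 540 segmented objects, the artifact and background
filters keep 407; about 24% of objects per field are removed as hidden
background cells (visible in `summary(run)`), matching the config's planted
25% occlusion. The treated group's texture rises by a third with complete
group separation (δ = 1.000 — the generator gives every cell of a group the
same roughness amplitude, so between-group overlap is purely statistical and
much smaller than in real micrographs). The measured area change (+8.6%)
understates the planted +24% in *occlusion-heavy* scenes because occluders
are conditioned to be large enough for their hidden partner to pass the
artifact filter; occlusion-free configurations recover planted shifts within
sampling error (the acceptance script demonstrates exactly this). See the
methods vignette (`vignettes/sem-morphometry.Rmd`) for details.

`write_run(run, "results/")` writes `cells.csv` (one row per segmented cell,
every stage column), `groups.csv`, `comparisons.csv`, `manifest.json`
(parameters, seed, per-stage counts) and violin figures. A thin CLI wrapper
lives at `inst/scripts/run_pipeline.R`:

```sh
Rscript inst/scripts/run_pipeline.R --config config.yaml --out results/
```

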