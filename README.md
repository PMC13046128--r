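# spinalpolar

Quantitative spatial analysis of immunolabelled cell populations in
spinal-cord cross-sections, for labs counting and mapping interneurons
and motor neurons in multi-channel confocal images.

A section enters as a four-channel z-stack (ChAT, GAD-67, Parvalbumin,
Calbindin) with a gray-matter ROI and a central-canal ROI. Each channel
is maximum-projected, masked to the gray matter, background-subtracted
with a 20-px rolling ball (grayscale opening), thresholded by maximum
entropy (Kapur–Sahoo–Wong, 256-bin in-mask histogram), despeckled and
closed. Particles are 8-connected components filtered by marker-specific
size windows derived from soma diameters via *area = π(d/2)²*
(e.g. ChAT 10–40 µm → 78.5–1256.6 µm²), with ChAT cells split at 25 µm
(491 µm²) into interneurons and motor neurons. Double-positive cells are
those whose ROI overlaps the partner marker's binary mask by ≥ 20%.

Every cell is then mapped into canal-referenced polar coordinates:
distance to the canal centroid (normalised to the gray-matter extent,
0 at the canal and 1 at the boundary under the default radial-fraction
variant) and an angle in the 0°-right / 90°-dorsal convention. Because
free-floating sections have no identifiable left/right, angles strictly
between 90° and 270° are mirrored with **θ′ = 180° − θ** before
inference. Groups are compared with one-way ANOVA on per-animal counts,
nested ANOVA (animals within genotype) on normalised distances, and
circular statistics on pooled mirrored angles: the common circular-median
test (k-sample analogue of Kruskal–Wallis, statistic
`N²/(M(N−M)) Σ mᵢ²/nᵢ − NM/(N−M)` against χ²(k−1)), pairwise two-sample
Kuiper tests (`V = max(F₁−F₂) + max(F₂−F₁)`, permutation p-values), and
Benjamini–Hochberg adjustment within each cell class.

Because raw imaging data for studies of this kind are rarely deposited,
the package ships a synthetic-section generator with complete ground
truth — butterfly-shaped gray matter, per-population angular (von Mises
mixture) and radial laws, exact co-expression bookkeeping, uniform-disk
rendering into 16-bit z-stacks — so the whole pipeline is verifiable.
See the methods vignette (`vignettes/spinalpolar-methods.Rmd`) for the
model, parameter choices and limitations.

## Worked example

```r
library(spinalpolar)

cfg <- section_config(min_separation = TRUE, noise_sd = 1200, seed = 42)
sec <- simulate_section(cfg)                      # 4 channels + ground truth
cells <- process_section(sec$stacks, sec$geometry)

head(cells[, c("marker", "area_um2", "size_class",
               "angle_deg", "angle_mirrored_deg", "norm_distance")], 3)
#>   marker  area_um2   size_class angle_deg angle_mirrored_deg norm_distance
#> 1   ChAT  775.8612 motor_neuron  221.4888          318.51123     0.7814574
#> 2   ChAT  805.7520 motor_neuron  231.7658          308.23418     0.8861994
#> 3   ChAT 1026.6840 motor_neuron  194.4124          345.58764     0.5384006

table(cells$marker)
#>   Calbindin        ChAT       GAD67 Parvalbumin
#>          38          37          97          38
```

The ChAT channel recovers 25 motor neurons and 12 interneurons — exactly
the generated ground truth at this noise level (SNR ≈ 5). The first cell
sits in the left ventral horn (221° raw); mirroring maps it to 318°, and
its normalised distance 0.78 places it in the outer gray matter. Motor
neurons concentrate ventrally:

```r
mn <- cells$angle_mirrored_deg[cells$marker == "ChAT" &
                               cells$size_class == "motor_neuron"]
round(circular_mean(mn), 1); round(circular_variance(mn), 3)
#> [1] 320.3
#> [1] 0.197

set.seed(9)
common_median_test(list(wt = rvonmises(200, 315, 3),
                        mut = rvonmises(200, 322, 3)))
#> common circular median test
#>   statistic = 2.25 df = 1  p = 0.1336
```

A full study — `run_study()` — simulates (or processes) 4 genotypes ×
3 animals × 8 sections, pools cells per class and genotype, and returns
count, distance and circular test tables plus rose-diagram bins; see
`?run_study` and `?analyze_cells`.

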