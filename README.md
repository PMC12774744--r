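# isletmito

Quantification of mitochondrial dynamics in pancreatic islet cells from
light- and electron-microscopy data.

Pancreatic alpha and beta cells regulate glucagon and insulin secretion
in part through the positioning and movement of their mitochondria.
Measuring that movement in whole isolated islets is hard: cells are
packed in a three-dimensional tissue, and individual mitochondria drift
in and out of a ~1 µm confocal section, which defeats conventional
tracking algorithms. `isletmito` implements a tracking-free alternative
for analysts working with whole-islet recordings, together with the
surrounding morphometric and biosensor analyses, and a synthetic-data
generator that makes the whole pipeline testable with known ground
truth.

## What it computes

**Motility (time-lapse confocal).** A recording of `T` frames is
collapsed into a per-pixel temporal standard deviation,

    SD(p) = sqrt( sum_t (I_t(p) - mean(I(p)))^2 / (T - 1) ),

used as the motility proxy: pixels whose intensity fluctuates because
mitochondria move through them score high. Per cell, the SD image is
normalized to its maximum ("maximal motility" is reported separately),
the nucleus is segmented by thresholding, and `360/θ` radial line
profiles (θ = 10° ⇒ 36 lines; θ = 1° ⇒ 360) are cast from the nucleus
centroid. Profiles start at the nucleus periphery and are averaged over
a fixed 7 µm cytosolic fraction; rays whose nucleus-to-membrane span is
shorter than 7 µm are excluded. A QC correlation between the SD and
temporal-mean images flags cells whose "motility" is likely an intensity
artifact (dye quenching, membrane-potential sensitivity).

**Morphometry (TEM polygon annotations).** Per mitochondrion: area,
perimeter, fitted-ellipse length/width, aspect ratio AR = length/width,
form factor FF = perimeter²/(4π·area), circularity = 4π·area/perimeter²
(FF and circularity are exact reciprocals), shortest distance to the
nucleus and to a possibly multi-component Golgi apparatus (component
minimum; "absent", not zero, when no Golgi is annotated), plus cell-level
mitochondrial density (total mitochondrial area / cell area).

**Ratiometric biosensor imaging.** Dual-excitation ATP/ADP sensor stacks
are converted to per-pixel R476/405 ratio images (denominator-floored,
gain-invariant), averaged in a sub-plasma-membrane shell (pixels within
4 µm of the cell boundary, via distance transform), and screened for
high-ratio microdomains (connected components above mean + 2 SD of the
shell, ≥ 0.5 µm²). Rolling-ball background subtraction (Sternberg ball,
default radius 300 px) and immunofluorescence knockdown-efficiency
quantification (infected/control × 100%) round out the module.

**Synthetic data.** `simulate_movie()`, `simulate_ratio_movie()` and
`simulate_tem_annotations()` generate two-channel movies of cells with
elongated, optionally motile mitochondria (reflected 3-D random walk,
optical-section attenuation), ratio movies with planted sub-membrane
microdomains, and TEM-style polygon annotations — all bit-reproducible
from a seed and returned with full ground truth.

## Worked example

```r
library(isletmito)

cfg <- movie_config(n_cells = 2, alpha_fraction = 1, seed = 42)
sim <- simulate_movie(cfg)
res <- analyze_motility(sim$stack, sim$annotations, classify = FALSE)
print(as.data.frame(res$table)[, 1:6], digits = 3, row.names = FALSE)
#>  cell_id class n_lines max_raw_sd mean_norm_motility  qc_r
#>  cell_01 alpha      36        110              0.135 0.912
#>  cell_02 alpha      36        100              0.136 0.927
```

`n_lines = 36` confirms the θ = 10° geometry (all rays span ≥ 7 µm in
these round cells); `max_raw_sd` is the cell's maximal motility in
intensity units; `mean_norm_motility` is the average normalized SD over
the 7 µm cytosolic fraction — the headline per-cell motility statistic,
which rises with the mitochondrial step size of the simulation.

```r
tem <- simulate_tem_annotations(n_cells = 1, mitos_per_cell = 3,
                                golgi_components = 2, seed = 7)
morpho <- cell_morphometry(tem$cells[[1]])
print(as.data.frame(morpho)[, c("mito_index", "area_um2", "aspect_ratio",
                                "form_factor", "circularity",
                                "d_nucleus_um", "d_golgi_um")],
      digits = 3, row.names = FALSE)
#>  mito_index area_um2 aspect_ratio form_factor circularity d_nucleus_um
#>           1    0.433         3.46        1.68       0.596         3.34
#>           2    0.648         2.22        1.26       0.792         3.05
#>           3    0.481         1.21        1.02       0.981         2.67
#>           0       NA           NA          NA          NA           NA
#>  d_golgi_um
#>        2.52
#>        1.81
#>        0.00
#>          NA
```

Row `mito_index = 0` is the cell-level summary (area, count, density);
a `d_golgi_um` of 0 means that mitochondrion touches a Golgi component.

A thin command-line wrapper lives at `inst/cli/mitodyn.R`
(`Rscript mitodyn.R motility --stack s.tif --annotations a.geojson
--pixel-size 0.25 --out results.csv`, plus `simulate`, `tem`, `atp`,
`run`, `summarize` subcommands); `run_pipeline()` drives the same stages
from a YAML config with deterministic, metadata-stamped outputs.

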