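# axmwi — simulated radar microwave imaging of axillary lymph nodes

Axillary lymph nodes (ALNs) are the first site of breast-cancer metastasis,
and current preoperative imaging often cannot tell whether they are
involved. Radar microwave imaging (MWI) exploits the dielectric contrast
between metastasized and healthy tissue: an ultra-wide-band pulse is emitted
from an on-skin antenna array, the backscatter is recorded monostatically,
the dominant skin response is removed, and a beamformer focuses the residual
echoes into a backscattered-energy image in which bright spots mark nodes.

`axmwi` implements that pipeline end to end, for researchers comparing
artifact-removal and beamforming algorithms under controlled 2D anatomy:

* **Phantoms** — layered skin (uniform or sinusoidal) / adipose / muscle
  anatomy with bean-shaped ALNs (single-pole Debye media,
  `tissue_library()`), 5 % tiled dielectric heterogeneity, 16-antenna
  80-mm array (`phantom_config()`, `build_phantom()`).
* **Forward solver** — 2D TMz FDTD with auxiliary-differential-equation
  Debye dispersion and convolutional-PML boundaries, driven by a 150-ps
  differentiated Gaussian centered at 7.5 GHz (`run_monostatic()`).
* **Skin-artifact removal** — average subtraction, and adaptive
  multichannel FIR prediction fit on the early-time window
  (`remove_artifact()`).
* **Beamformers** — DAS, DMAS, and their channel-ranked variants CR-DAS and
  CR-DMAS (`reconstruct()`). DAS focuses with round-trip delays,

  $$I(p) = \sum_{t\in W}\Big[\sum_{m=1}^{M} w_m\, s_m(t+\tau_{p,m})\Big]^2,$$

  DMAS multiplies delayed channel pairs before summation,
  $I(p) = \sum_{t\in W}\big[\sum_{i<j}\hat s_i \hat s_j\big]^2$, and the CR
  variants weight channels by the rank of their propagation distance.
* **Metrics** — signal-to-clutter (SCR), signal-to-mean (SMR), max-to-max
  (MMR), full width at half maximum (FWHM) and localization error (LE)
  against the phantom ground truth (`detection_report()`), plus a
  two-target resolution sweep (`run_resolution_sweep()`).

## Worked example

```r
library(axmwi)

sc  <- built_in_scenarios()$single_uniform_skin   # 1 node at 20 mm depth
res <- run_scenario(sc)                           # ~30 s on one core
res$report[, c("artifact", "beamformer", "smr_db", "fwhm_mm", "le_mm")]
#>   artifact beamformer   smr_db   fwhm_mm le_mm
#> 1  average        DAS 13.69170 12.448081   0.5
#> 2  average       DMAS 21.86079  6.554110   0.5
#> 3  average     CR-DAS 16.32925 11.369295   0.5
#> 4  average    CR-DMAS 24.93542  6.722700   0.5
#> 5 adaptive        DAS 13.70247 12.763229   0.5
#> 6 adaptive       DMAS 22.20340  6.359303   0.5
#> 7 adaptive     CR-DAS 16.71259 11.058014   0.5
#> 8 adaptive    CR-DMAS 25.55777  6.542452   0.5

plot(res$maps[["adaptive_CR-DMAS"]], phantom = res$phantom)
```

Every combination localizes the node to 0.5 mm (one pixel). The
pair-multiplying beamformers (DMAS, CR-DMAS) reach ~8–11 dB higher
signal-to-mean ratio and roughly half the response width of the summing
ones — the pair products cancel clutter that is not coherent across the
array. On the sinusoidal-skin phantom the same call shows average
subtraction failing (LE > 20 mm, the residual skin response dominates)
while adaptive filtering still finds the node within 1 mm.

A thin CLI over the same functions is installed with the package
(`system.file("scripts", "axmwi", package = "axmwi")`), with
`simulate` / `reconstruct` / `evaluate` / `scenario` / `sweep` subcommands.

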