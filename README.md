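# tuberphen

Multi-modal, non-invasive phenotyping of potato (*Solanum tuberosum*)
under water deficit, as an R package. Drought trials monitor the same
plants at three levels, none of which requires harvesting the plant:

* **Shoots** — top/side RGB images yield projected area, convex hull
  area, height/width and the Excess Green index
  `ExG = (2G − (R+B)) / (R+G+B)`, as time series over days after shoot
  emergence (DASE).
* **Leaves** — CPMG NMR echo decays are inverted into continuous T2
  relaxation-time distributions; the longest-T2, highest-intensity peaks
  track vacuolar water in spongy (vs) and palisade (vl) mesophyll cells,
  and the splitting/merging of that vacuolar signal follows leaf
  development and water status.
* **Tubers** — 3-D MR volumes of the pot are segmented from manual seeds
  by statistical region growing, tubers are counted (3-D connected
  components), measured (volume in cm³, equivalent-sphere diameter
  `(6V/π)^(1/3)`), filtered by the yield rule (under 15 mm at the final
  session ⇒ excluded), and tracked individually across imaging sessions
  by centroid proximity.

The scientific core is the inverse-Laplace machinery: a maximum-entropy
solver (`invertMem`) that maximises the Skilling entropy
`S(f) = Σ fⱼ − mⱼ − fⱼ log(fⱼ/mⱼ)` subject to the χ² ≈ K discrepancy
constraint on the kernel `K[k,j] = exp(−t_k/T2_j)`, and an independent
Tikhonov-regularised NNLS solver (`invertNnls`) used as a cross-check.
Supporting utilities implement leaf water status (`LWD = 1 − RWC`),
weighing-based watering to 70/40/20% of field capacity
(Control/MWD/SWD), and ANOVA + Tukey HSD compact letter displays.
Seeded fixture generators (`makePlantImages`, `makeLeafT2Series`,
`makeMriScene`) produce inputs with known ground truth for all three
modalities, so everything is testable with no external data.

## Worked example

```r
library(tuberphen)

## 1. Shoot traits from a synthetic growth series
scenario <- plantImageScenario(seed = 7, maxArea = 6000)
fixtures <- makePlantImages(scenario, dase = c(25, 33, 41, 49))
traits   <- buildTraitSeries(lapply(fixtures, function(f) f$image))
traits[, c("plant_id", "view", "dase", "projected_area", "hull_area", "exg_mean")]
#>   plant_id view dase projected_area hull_area  exg_mean
#>  sim-plant  top   25           1112    3021.0 0.6880111
#>  sim-plant  top   33           4281   11703.5 0.6966242
#>  sim-plant  top   41           5338   14646.0 0.7035079
#>  sim-plant  top   49           5456   14910.5 0.6967909
```

The silhouette grows along its logistic curve (areas in px²; hull area
always bounds projected area) while the mask-mean ExG stays at the
green-leaf level ≈ 0.7.

```r
## 2. T2 distribution of a two-pool leaf decay (tau = 0.2 ms, SNR 1000)
decay <- simulateCpmg(cbind(c(40, 400), c(0.4, 0.6)), tau = 0.2,
                      nEchoes = 5000, noiseSigma = 1e-3, seed = 7)
fit <- invertMem(decay)
fit
#> T2Distribution (mem): 200-pt grid [0.5, 3000] ms, total area 1.002, chi2/K = 0.994
findPeaks(fit)[, c("t2_mode", "area_fraction")]
#>    t2_mode area_fraction
#>   39.58571     0.3993146
#>  401.58711     0.5984366
```

The true pools (40 ms at 40%, 400 ms at 60%) are recovered within one
grid step and half a percent of area, with the reconstruction fitting
the decay at its noise level (χ²/K ≈ 1).

```r
## 3. Tuber segmentation, measurement and longitudinal tracking
out  <- makeMriScene(mriScene(seed = 7))      # 4 sessions, 6 tubers + mother
recs <- do.call(rbind, lapply(out$sessions, function(s) {
  lm <- regionGrow(s$volume, s$seeds, k = 2.5)
  measureTubers(lm, dase = s$dase, excludeLabels = out$motherLabel)
}))
trackTubers(recs)$ranking
#>  track_id tuber_label final_volume_cm3
#>         4    Tuber-01           5.7706
#>         6    Tuber-02           4.2614
#>         2    Tuber-03           3.9886
#>         3    Tuber-04           3.3165
#>         5    Tuber-05           2.6609
#>         1    Tuber-06           1.1286

## 4. Leaf water status
rwcLwd(0.9, 1.0, 0.0)
#>  rwc lwd
#>  0.9 0.1
```

Tubers keep their identity across sessions and are ranked Tuber-01…n by
final volume; a leaf at 90% relative water content has a 10% water
deficit, the level typical of well-watered controls.

A command-line interface wrapping these functions ships in
`inst/scripts/tuberphen.R` (subcommands `rgb-traits`, `t2sim`, `t2fit`,
`mri-segment`, `mri-track`, `simulate`, `water`, `letters`).

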