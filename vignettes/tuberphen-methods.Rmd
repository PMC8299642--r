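---
title: "tuberphen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tuberphen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuberphen)
```

tuberphen implements the computational side of a multi-modal, non-invasive
drought-phenotyping workflow for potato (*Solanum tuberosum*): shoot traits
from RGB images, leaf water compartmentation from CPMG NMR relaxometry, and
tuber counts/volumes from 3-D MRI, plus the physiological arithmetic and
group statistics that tie the measurements together. This vignette explains
the models behind each module, the parameters that matter, the numerical
choices, and what the synthetic fixtures do and do not demonstrate.

## Shoot traits from RGB images

Plants are imaged from the top and the side; all traits derive from a
boolean foreground mask. The colour feature is the Excess Green index

$$ExG = \frac{2G - (R + B)}{R + G + B},$$

which is large for chlorophyll-rich pixels (pure green scores 2, grey 0,
pure red −1). Pixels with $R+G+B=0$ are defined as 0 (background-black
convention); the choice is configurable via `zeroValue`.

The production systems this package models use a proprietary
machine-learning segmenter. `segmentPlant()` is a documented reference
segmenter behind a pluggable interface (`buildTraitSeries(segmenter=)`
accepts any function returning a `PlantMask`): per-pixel ExG, Otsu
threshold on the ExG map, morphological opening then closing with a 3×3
box, and retention of connected components of at least 0.5% of the frame.
When the ExG map is constant, Otsu's criterion is undefined and a fixed
threshold (default 0.1) decides, so a uniform grey frame gives an empty
mask and a uniform green frame a full one.

Trait conventions:

* **Pixel geometry.** Pixels are unit squares, and the convex hull is taken
  over the four corners of every foreground pixel. A single pixel therefore
  has hull area 1 px², and projected area can never exceed hull area.
* **Extents.** Height and width are inclusive bounding-box extents
  (single pixel → 1 × 1), reported for side views.
* **Units.** Default px/px²; a `scaleMmPerPx` calibration converts to
  mm/mm² and is recorded in the output's `units` column. No calibration is
  assumed by default because camera geometry varies between installations.
* **Mean ExG** is computed over the segmented plant pixels by default
  (the background would otherwise dilute the signal and track soil colour,
  not plant status); `exgOverMask = FALSE` switches to the whole frame.

## T2 distributions from CPMG decays

A CPMG echo train samples transverse relaxation at $t_k = 2k\tau$
(half-echo spacing $\tau$ = 0.2 ms in the reference acquisition). Water in
distinct cell compartments relaxes at distinct rates, so the decay is
multi-exponential,

$$S(t) = \sum_i A_i e^{-t/T_{2,i}} + \varepsilon,$$

and the object of interest is the continuous distribution $f(T_2)$ on a
log grid with kernel $K_{kj} = e^{-t_k/T_{2,j}}$. Two independent solvers
recover $f \ge 0$:

* **`invertMem()`** maximises the Skilling entropy
  $S(f) = \sum_j f_j - m_j - f_j \log(f_j/m_j)$ against a uniform prior
  $m$, subject to $\chi^2 \approx K$, via a Lagrange multiplier $\alpha$
  on a cooling schedule; each subproblem is solved by active-set damped
  Newton iterations directly in $f$ (the objective is convex there and
  the entropy gradient is a natural positivity barrier).
* **`invertNnls()`** solves Tikhonov-regularised non-negative least
  squares, $\min_{f\ge0}\|W(y-Kf-b)\|^2+\lambda\|f\|^2$, with $\lambda$
  chosen by the discrepancy principle. It exists as an independent
  cross-check: the two solvers share only the kernel.

Numerical choices that matter:

* **Echo compression.** Echoes are averaged into at most 150 log-time
  bins; the kernel is bin-averaged *exactly* (mean of $e^{-t_k/T_2}$ over
  the echoes in a bin), so the compression introduces no model bias, and
  the per-bin noise sd shrinks with $\sqrt{n_{bin}}$.
* **Goodness of fit.** The discrepancy target is enforced on the binned
  statistic, but the reported `fitChisq()` is computed over the full echo
  train, whose sampling sd ($\sqrt{2/K}$) is an order of magnitude
  smaller; accepted fits satisfy $\chi^2/K \in [0.8, 1.2]$. On a small
  fraction of noise realisations the *minimum* binned $\chi^2/N$ exceeds
  the nominal target; the solvers then return the best-achievable fit
  rather than failing, and validity is judged on the full-train statistic.
* **Noise.** $\sigma$ is taken from the decay, estimated from the last 5%
  of echoes (via first differences, robust to residual decay) when
  absent, and floored at $2\times10^{-4}$ of the signal maximum so that
  noiseless decays are fitted to 0.02% relative accuracy — safely above
  the ~$10^{-4}$ discretisation error of the 200-point grid — instead of
  an unreachable machine-precision target. When the floor is active there
  is no noise to overfit, so the first fit at or below the target is
  accepted without bisection.
* **Grid.** 200 log-spaced points over [0.5, 3000] ms. The lower bound
  sits at the first-echo time: grid points decaying faster than the first
  recorded echo are unidentifiable and can otherwise absorb arbitrarily
  large invisible amplitude that distorts the area fractions of real
  peaks.
* **Prior level.** The MEM prior is uniform at 1% of $S(0)/n$
  (`priorScale`), well below any real peak, so unconstrained grid points
  relax to a negligible baseline instead of phantom peaks.
* **Baseline.** A signed constant offset (instrument baseline) is fitted
  by default (`offset = TRUE`).

`findPeaks()` reports local maxima with supports bounded by flanking
minima (the minimum belongs to the left peak). Maxima closer than a
factor 1.5 in $T_2$ are merged first: components within that ratio are
physically unresolvable by inverse-Laplace inversion, and sparse NNLS
solutions routinely split one component into adjacent grid spikes.
Peaks below 1% of total area (`minAreaFraction`) are dropped.

`assignVacuolar()` operationalises the convention that the longest-$T_2$,
highest-intensity peaks carry vacuolar water: candidates need a mode above
30 ms and at least 15% of the area; two candidates become vs (spongy,
smaller vacuoles) and vl (palisade, larger), one becomes vt. The 30 ms /
15% quantification is this package's choice — the underlying convention is
qualitative — and both knobs are exposed. `detectSplitMerge()` reads
split (1→2) and merge (2→1) events off the component-count trajectory,
recording each at the first day the new count is observed; repeated
merge–split–merge sequences, as seen in senescing leaves, are supported.
`averageHomogeneous()` averages replicate $T_2$ parameters only within
groups with the same vacuolar component count, never mixing one- and
two-peak spectra; which replicates are "two-component" is decided by the
same `minAreaFraction` threshold, a rule this package adopts where the
methodology leaves the marginal-peak criterion unstated.

## Tuber volumetry from 3-D MRI

Volumes are (Z, Y, X) arrays with anisotropic voxels, default
1.1 × 1.0 × 1.0 mm (slice × in-plane), matching the reference 3-D FSE
acquisition; the 50% slice-direction interpolation of that acquisition is
assumed already baked into the stated voxel size, and no resampling is
performed. Physical coordinates are 0-based voxel indices times voxel
size, at voxel centres.

`regionGrow()` stands in for the level-set seed expansion of the original
semi-automatic workflow, whose exact energy is not published: each seed's
intensity statistics define an acceptance band $\mu \pm k\sigma$
(default $k = 2.5$), and the seed grows to the connected component
(26-connectivity by default) of the band's support that contains it.
Voxels eligible for two labels go to the label with the smaller seed
z-score, ties to the lower label id — tubers rarely touch, so this rule
is almost never exercised. A seed whose sd is (numerically) zero grows
over the exactly-matching uniform region, the documented degenerate case.
An optional `minNeighbors` pass removes grown voxels with too few
same-label neighbours. Manual mask adjustment in the original workflow is
out of band here; seeds may be edited and re-grown deterministically.

`labelAndCount()` counts 3-D connected components (26-connectivity
default, matching common 3-D object counters; 6 by flag) with a
frontier-based flood fill whose work scales with object size, not volume
size. `measureTubers()` converts voxel counts to cm³ and to the
equivalent-sphere diameter $(6V/\pi)^{1/3}$ — the package's
operationalisation of "diameter", since a caliper measure is not
available from images.

Two diameter rules shape the analysis: tubers are detectable from about
3 mm, and tubers **under** 15 mm at the final session are excluded from
all sessions (they do not count towards yield). Both inequalities are
strict; exactly 15.0 mm is retained. `filterTubers()` applies the yield
rule and flags sub-3 mm records; it refuses to run when a tuber lacks a
final-session record, because the rule is defined at that session.

`trackTubers()` propagates identities between sessions by greedy
nearest-centroid matching within 15 mm (pots are repositioned on a mark
between scans, so centroids barely move): globally smallest distances
first, so when two tubers compete for one predecessor the closer wins and
the other opens a new track. Tracks are ranked Tuber-01, Tuber-02, … by
final observed volume, descending. The shrinking mother tuber is
segmented like any object but carries its own seed label and is excluded
from counts and totals via `excludeLabels`.

## Physiology utilities

`rwcLwd()` computes relative water content
$RWC = (fresh-dry)/(turgid-dry)$ and the leaf water deficit
$LWD = 1 - RWC$; the identity $RWC + LWD = 1$ is exact. `wateringAmount()`
returns the non-negative mass of water bringing a pot to
$tare + soil + fraction \times FC$, with the Control/MWD/SWD regimes at
70/40/20% of field capacity; water is never removed. `psiFullTurgor()`
applies the Van't Hoff dilution correction
$\psi_\pi(\text{full turgor}) = \psi_\pi(RWC)\times RWC$ — an assumption
(solute conservation), stated as such, since no instrument reports the
full-turgor value directly. Soil and leaf water potentials are instrument
data; the package only stores and plots them.

`anovaTukeyLetters()` is deliberately plain statistics: one-way
`aov()`, `TukeyHSD()`, and a compact letter display built from the
maximal cliques of the "not significantly different" graph, ordered by
decreasing group mean (so relabelling groups merely permutes letters).
Zero residual variance is handled as "no difference" among equal-mean
groups; a singleton group suppresses letters but keeps the means.

## Synthetic fixtures: what they demonstrate

Every generator is a pure function of its scenario (including the seed)
and returns ground truth alongside the data, so the entire toolkit is
testable offline.

* **Plant images** (`makePlantImages`): random-walk stems with elliptical
  leaflets, green hues over a textured grey-brown background, silhouette
  area following a logistic curve $A_{max}/(1+e^{-r(d-d_0)})$ (defaults
  $A_{max} = 6000$ px², $r = 0.3$/day, $d_0 = 30$ DASE — a sigmoid shoot
  growth curve on a 200×200 frame). Not emulated: specular highlights,
  occlusion by hardware, leaf wilting geometry, illumination drift. A
  segmenter that scores IoU ≥ 0.95 here has demonstrated correct
  thresholding and cleanup, not robustness to field imagery.
* **Leaf T2 series** (`makeLeafT2Series`): a short non-vacuolar component
  (8 ms, 25% of amplitude) plus either one vacuolar component rising
  150→300 ms (pre-split) or a stable vs = 150 ms and a rising
  vl = 400→550 ms (post-split), vl > vs always; SNR defaults to 10³,
  matching a well-averaged benchtop acquisition. Diffusion exchange
  between compartments and $T_1$ weighting are not modelled.
* **MRI scenes** (`makeMriScene`): up to six ellipsoidal tubers on a
  well-separated lattice (overlap is checked at construction and is an
  error), logistic volume growth ($V_{max}$ uniform in 0.8–6 cm³ so the
  15 mm yield rule bites for some tubers; $k = 0.35$/day; $t_0$ in 18–28
  DASE so every tuber is detectable from the first session), a mother
  tuber shrinking to depletion at the final session, object/background
  contrast with SNR (contrast/noise sd) 10, sessions at 25/32/39/73 DASE.
  Not emulated: partial-volume effects, bias fields, roots and stolons,
  touching tubers — so the Dice ≥ 0.95 recovery demonstrates the region
  statistics and connectivity machinery, not robustness to coil shading.

## Problem sizes in the test-suite

The automated checks run at desk scale: 100 noise seeds for the
bi-exponential recovery Monte Carlo (5000 echoes, 200-point grid), 50
seeds for segmentation IoU, 20 random MRI scenes (4 sessions of
56×96×96 voxels each) for Dice/tracking/yield checks, 100 random 20³
arrays for the connectivity oracle, and 100 simulated experiments for the
type-I-error property of the letters display. These sizes give the
property estimates quoted by `scripts/acceptance.R` binomial standard
errors of a few percent.

## Known limitations

* The reference segmenter is threshold-based; it will underperform on
  senescent (yellowing) leaves where ExG fades — the pluggable interface
  exists precisely so a learned segmenter can replace it.
* Inverse-Laplace inversion cannot separate components closer than about
  a factor 1.5 in $T_2$ regardless of solver; the peak merger makes this
  explicit rather than pretending otherwise.
* Region growing assumes approximately Gaussian within-tuber intensities;
  strong bias fields would require a correction step upstream.
* Tracking assumes near-stationary centroids between sessions; large pot
  disturbances break the 15 mm matching radius and start spurious tracks
  (visible in the tracking log).
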