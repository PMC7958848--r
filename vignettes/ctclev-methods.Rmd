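---
title: "ctclev: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctclev: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctclev)
```

## The assay and the model

Slide-based liquid biopsies plate all nucleated cells from a blood draw as
a monolayer (millions of cells per slide) and scan them with a three-color
immunofluorescence panel: DAPI (DNA), pan-cytokeratin (CK, epithelial
cytoskeleton) and CD45 (leukocyte marker). Objects of interest are rare and
heterogeneous:

* **CTC** — intact circulating tumor cell: DAPI+, CK+, CD45−, and larger
  than the surrounding white blood cells;
* **LEV** — large extracellular vesicle (large oncosome): CK+, CD45−,
  **anucleate**, round, 6 µm and larger. Smaller CK+ specks are abundant
  but unverifiable at scan resolution, so they are deliberately omitted;
* **apoptotic-like cell** — DAPI+, CK+ with a fragmented/blebbing nucleus
  or speckled cytoskeleton;
* **WBC** — DAPI+, CD45+, CK−; not reported, but its size distribution
  anchors the CTC size gate.

`ctclev` implements detection, morphometrics, gating, cohort statistics and
downstream imaging-mass-cytometry (IMC) scoring for this object taxonomy,
together with synthetic generators that emulate the assay's statistical
structure with known ground truth.

## Detection and morphometrics

Background per channel is the median pixel intensity with spread estimated
as `1.4826 × MAD` (floored at machine epsilon). The median/MAD pair is
robust because true objects occupy a small fraction of slide pixels; on
dense synthetic tiles the MAD is inflated by a few percent, which slightly
raises thresholds but affects all classes alike.

The CK channel is thresholded at `background + 5·MAD-SD`. Components are
labeled with 8-connectivity (a union-find diagonal merge on top of
`EBImage::bwlabel`, which is 4-connected) and hole-filled, the convention
under which vesicles and speckled cells stay single filled masks.
Candidates below `min_detect_um = 4` µm equivalent diameter are discarded
— deliberately *below* the 6 µm LEV rule so that the "< 6 µm omitted" gate
is applied exactly once, during classification, and is itself testable.

Morphometrics per mask:

* equivalent diameter `2·sqrt(area/π)·scale` (µm);
* circularity `4πA/P²` with a contour-following perimeter: the boundary
  pixel chain is smoothed with a circular 3-point moving average and its
  polygon length is corrected by `+π`, the perimeter of the Minkowski
  half-pixel offset between pixel centers and the true mask boundary.
  Rasterized disks score 0.98–1.05 down to radius 3 px and squares land
  near `π/4 ≈ 0.785 (± 0.05)`; uncorrected chain lengths would bias small
  disks by 5–15%. Values slightly above 1 are expected discretization
  effects; the documented tolerance is ± 0.05;
* per-channel SNR `(object mean − background)/MAD-SD`, floored at −1;
* DAPI-positive area and fragment count (number of DAPI components
  overlapping the mask), nucleus solidity (pixels over convex-hull lattice
  count, Pick-corrected), and the CV of CK intensity inside the mask.

Coordinates are 0-based (row, col) pixel indices internally; reports emit
(x, y) in µm from the top-left origin.

## Classification gates

The decision tree is evaluated in fixed order; disruption trumps
intactness, so an object meeting both apoptotic and CTC criteria is
apoptotic. Defaults, all configurable in `classify_config()`:

| gate | rule | default | rationale |
|---|---|---|---|
| CK+ | `snr_CK ≥` | 3 | conservative positivity on a robust SNR |
| CD45 exclusion | `snr_CD45 ≥` → WBC | 2 | leukocyte veto before anything else |
| nucleation | DAPI area ≥ 10 µm² and `snr_DAPI ≥ 3` | — | area term rejects speckle; SNR term rejects dim haze |
| LEV roundness | circularity ≥ | 0.80 | automatable surrogate for manual brightfield membrane confirmation of "round events" |
| LEV size | diameter ≥ | 6 µm | membranes below this are unverifiable at 10× scan resolution |
| apoptotic | fragments ≥ 2 **or** solidity < 0.85 **or** CK texture CV > 0.8 | — | any independent sign of nuclear/cytoskeletal disruption |
| CTC size | diameter > 1.25 × median WBC | 12 µm absolute fallback below 50 WBCs | operationalizes "larger than surrounding WBCs" robustly |

The WBC context uses DAPI+/CD45+/CK− nuclei only, so CK+ objects (LEVs
included) can never shift the CTC gate.

## Synthetic slides

`render_slide()` places non-overlapping anti-aliased ellipses on a
Gaussian-noise background (additive read noise matches fluorescence
physics; the optional overlap mode is excluded from all validation). Pixel
scale defaults to 0.65 µm/px (typical 10× slide scanner; 0.1625 µm/px for a
40× surrogate). The default tile plants 5,000 WBCs on a 3000² px tile — a
desk-scale stand-in for the ~3 × 10⁶ cells of a physical slide; rare-event
counts are therefore specified per tile, and validation suites use smaller
tiles (512–1400 px) with proportionally scaled counts.

Class size distributions are truncated normals whose **truncated** mean and
SD equal the reference statistics (LEV 9.8 ± 3.0 µm on [6.3, 20.4], CTC
25.3 ± 5.9 µm on [15, 45], apoptotic 13.5 ± 3.7 µm on [6.7, 25.1], WBC
10 ± 1 µm). The parent parameters are solved by moment matching at
configuration time; naively truncating `N(9.8, 3.0)` to [6.3, 20.4] would
inflate the realized mean by ~0.7 µm. Sampling uses the inverse-CDF, exact
for any truncation.

Signal amplitudes are calibrated to the detection rule: CK and DAPI render
at twice background with read noise at a tenth of background, so the
`+5·MAD` threshold cuts the object rim at half amplitude. With symmetric
noise, rim-pixel inclusion is then unbiased and measured equivalent
diameters center on the planted truth (module tests observe |bias| < 0.05
µm). Apoptotic CK speckle (lognormal, CV 0.9) is applied only to the
interior, leaving a clean 1–2 px rim so the texture cannot erode the mask;
nuclear fragments render at six times background because the fragmented
nucleus fills only a small fraction of the cell and the *whole-mask* DAPI
SNR must still clear the nucleation gate. Fragment radii scale with cell
size (`0.12·d`, clamped to [1.4, 3.0] µm) and counts grow from 2 (< 12 µm)
to 4, keeping fragments separable at 0.65 µm/px.

What the generator does **not** emulate: optical blur and chromatic shifts,
uneven illumination, staining batch effects, touching/overlapping cells,
out-of-focus planes, and autofluorescent debris with intermediate CK
levels. Passing recovery tests therefore demonstrates correctness of the
measurement and gating logic under the assay's idealized geometry, not
robustness to those artifacts.

## Synthetic cohorts

`generate_cohort_counts()` draws one latent CTC rate per patient from a
log-normal (`mean_rate = 16` events/slide, `sdlog = 1`), then per-slide CTC
and LEV counts from negative binomials (`dispersion = 100`); the LEV rate
is `lev_ratio = 1.9` times the CTC rate times a per-patient log-normal
jitter (`lev_ratio_sdlog = 0.18`) representing biological variation in
vesicle shedding relative to tumor-cell burden. The defaults are
**calibrated, not derived**: over 200 seeded 44-patient cohorts they yield
a mean cross-patient Pearson R of ≈ 0.95 and a mean OLS slope within a few
percent of the configured 1.9. The jitter term is what makes both
attainable at once — slide-level count noise on the CTC axis attenuates the
OLS slope, whereas ratio jitter only lowers R.

Known limitations: rates are not zero-inflated, so the default cohort has
essentially no event-negative patients (real cohorts have many); the
detection-rate and rescue arithmetic is therefore exercised on explicit
margin tables rather than generator output. Inter-slide CV comes out
similar for all classes (~0.23–0.29) because one dispersion is shared.

Percent summaries round half away from zero (`round_percent()`); exact
fractions are always reported alongside, so no information is lost to the
rounding convention.

## IMC rendering and 0–3 scoring

Each ROI is 200 × 200 px at 1 µm/px (one pixel per ablation pulse): a
centered object of known class plus ≥ 5 surrounding WBC disks, with every
channel drawn as Poisson ion counts (WBC rate 10 counts/px, ambient 1).
Scoring is fully relative: `SNR = object mean / WBC mean` within the same
ROI, binned left-closed at 2, 5 and 10 — an SNR of exactly 2 scores 1 and
exactly 10 scores 3. The bin edges are chosen defaults (analyst-assigned
scales have no published cutoffs) and are config-exposed; all shipped
validation uses the defaults. The DNA intercalator channel is held apart
from the 33 protein markers and thresholded at 1.5 (weak) and 5 (positive),
matching the observation that some anucleate vesicles carry trace nucleic
acid visible to IMC but not to DAPI.

Planted score bins map to SNR multipliers drawn uniformly from ranges set
*inside* the scoring bins (`[0.7,1.4] [2.6,4.4] [5.8,9.2] [11,18]`), so
Poisson noise rarely crosses a bin boundary; end-to-end bin recovery
exceeds 95% by a wide margin at the default object sizes.

Per-class bin profiles are the generator's calibration surface. Named
markers fix the headline statistics — EpCAM split 49/32/19 across all
classes; HSPD1 near-universal and predominantly strong in tumor objects;
AR/PSA/PSMA planted **jointly** with per-class all-negative fractions
(0.14/0.37/0.55), because panel positivity is a joint property that
per-marker marginals cannot pin down — and the remaining markers carry
Binomial(3, t/3) bins with `t` solved per class so the expected sum of all
33 protein scores is 11.9 (CTC), 8.1 (LEV) and 4.8 (apoptotic-like).

Bins are realized by largest-remainder quota within each class (seeded
shuffle decides which object gets which bin) plus a mean-correcting
promote/demote step: plain quota clips rare high bins and would bias the
CTC sum of scores by about −0.4. Quota planting is a variance-reduction
choice — the cohort margins are design parameters, not estimands — while
object-level assignments remain random.

`cluster_objects()` performs average-linkage hierarchical clustering of
objects and of markers (Euclidean distance on scores) and a 2-D t-SNE
embedding. The t-SNE is an exact-gradient implementation (no Barnes–Hut):
per-point bandwidths by bisection to the target perplexity
(`min(30, ⌊(n−1)/3⌋)`), early exaggeration 12 for 100 of 500 iterations,
momentum descent, seeded initialization — deterministic given the seed,
appropriate at the few-hundred-object scale of an IMC cohort.

## Numerical and degenerate-input conventions

* Constant rasters: background MAD is floored at machine epsilon; a
  constant-zero channel yields background (0, floor) without error.
* Empty masks are input errors; empty candidate sets produce header-only
  reports.
* Unscorable ROIs (no WBC pixels) are flagged and dropped with a message;
  an all-unscorable cohort is an error.
* Inter-slide CV uses the n−1 SD and a *strict* `> 5` mean-count filter
  (a patient at exactly 5 is excluded); an empty filter result warns rather
  than errors.
* Zero CTC variance makes the LEV–CTC regression an explicit error.
* Ordinal covariates are coded low/intermediate/high → 0/1/2 and no/yes →
  0/1, the simplest monotone coding for count–covariate correlations.
* All generators consume an isolated RNG stream (`set.seed` with fixed
  Mersenne-Twister/Inversion/Rejection kinds, caller state restored), so
  identical `(config, seed)` pairs are bit-reproducible across sessions.

## Validation problem sizes

The shipped suites run at desk scale by design: 50 seeded 700² px slides
(~21 planted tumor objects + 80 WBCs each) for recall/precision and
per-class classification accuracy (all ≥ 0.95); 8 slides × 80 objects per
class (640 objects, 150 WBCs per tile) for size-recovery means; 200 seeded
cohorts for the regression calibration; and the full 170-ROI IMC cohort
(51 CTC / 79 LEV / 40 apoptotic) for scoring statistics. The
`scripts/acceptance.R` entry point re-runs exactly these computations from
scratch under a caller-supplied seed.
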