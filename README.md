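# ctclev

Parallel single-object identification of **circulating tumor cells (CTCs)**
and **large extracellular vesicles (LEVs, "large oncosomes")** from
multichannel immunofluorescence slide scans, with downstream cohort
statistics and per-object **imaging mass cytometry (IMC)** protein scoring.

Slide-based liquid biopsies plate every nucleated blood cell as a monolayer
and scan it in three fluorescence channels (DAPI, pan-cytokeratin, CD45).
Tumor-derived events are rare — a handful among millions of white blood
cells — and come in several flavors: intact CTCs (DAPI+/CK+/CD45−, larger
than surrounding WBCs), anucleate CK+ vesicles ≥ 6 µm (LEVs), and
apoptotic-like cells with fragmented nuclei or speckled cytokeratin.
`ctclev` implements the full analysis chain for this assay, plus seeded
synthetic generators with ground-truth manifests so every stage can be
validated end to end. It is aimed at researchers building or benchmarking
rare-event liquid-biopsy pipelines.

## What it computes

**Detection.** Channels are thresholded at `background + 5·MAD` (robust
median/MAD background), 8-connected components are labeled and hole-filled,
and each candidate gets morphometrics: equivalent diameter
`2·sqrt(A/π)·scale`, circularity `4πA/P²` (contour-following perimeter),
per-channel SNR `(object mean − background)/MAD`, DAPI-positive area,
nuclear fragment count, nucleus solidity, CK texture CV.

**Classification.** A deterministic gate tree: CK+ (SNR ≥ 3) → CD45− (SNR
< 2) → nucleation (DAPI area ≥ 10 µm², SNR ≥ 3). DAPI− objects are LEVs if
round (circularity ≥ 0.80) and ≥ 6 µm; DAPI+ objects are apoptotic-like if
the nucleus is fragmented/disrupted, else CTC if larger than 1.25× the
median WBC diameter.

**Cohort statistics.** Per-patient means, inter-slide coefficient of
variation (patients with mean > 5 events), OLS regression of mean LEV on
mean CTC counts with Pearson R, detection rates and the *LEV rescue rate*
(fraction of CTC-negative patients with ≥ 1 LEV), covariate group summaries.

**IMC scoring.** Each 200 × 200 µm ion-count ROI holds one object of
interest among WBCs; every marker is scored 0–3 from the object/WBC
signal-to-noise ratio (bins `[0,2) [2,5) [5,10) [10,∞)`), DNA load is
called negative/weak/positive, and the object × marker score matrix feeds
sum-of-score summaries, marker/panel positivity, hierarchical clustering
and a deterministic t-SNE embedding.

**Synthetic data.** `render_slide()`, `generate_cohort_counts()` and
`render_imc_rois()` produce calibrated slides, count tables and ROI stacks
with known ground truth (class sizes: LEV 9.8 ± 3.0 µm on 6.3–20.4 µm,
CTC 25.3 ± 5.9 µm on 15–45 µm, apoptotic 13.5 ± 3.7 µm on 6.7–25.1 µm;
LEV counts 1.9× CTC counts with cross-patient regression R ≈ 0.95; IMC
class profiles with mean score sums 11.9/8.1/4.8).

## Worked example

```r
library(ctclev)

cfg <- slide_config(dim_px = c(900, 900), n_wbc = 150, n_ctc = 3,
                    n_lev = 6, n_apoptotic = 2, n_debris = 2)
rs  <- render_slide(cfg, seed = 1, slide_id = "demo")
res <- analyze_slide(rs$slide)
table(res$records$klass)
#> APOPTOTIC       CTC  EXCLUDED       LEV
#>         2         3         2         6
head(res$report[, c("object_id", "class", "diameter_um", "circularity")], 3)
#>   object_id     class diameter_um circularity
#> 1 demo-0009       CTC       22.74       0.975
#> 2 demo-0007 APOPTOTIC       13.26       0.948
#> 3 demo-0012       LEV        6.39       1.004
```

All 11 planted tumor-derived objects are recovered and classified; the two
sub-6-µm CK+ debris specks are detected but gated out (`EXCLUDED`), which is
exactly the assay's reporting rule. Diameters are within a pixel of the
planted truth and the WBC context (median 10.3 µm, n = 150) anchors the
"larger than WBCs" CTC gate.

The IMC arm works the same way:

```r
sm <- imc_score_cohort(imc_profile_config(), seed = 171)  # 170 ROIs
class_score_sums(sm)
#> APOPTOTIC       CTC       LEV
#>      4.68     12.10      8.22
marker_positivity(sm, "EpCAM")[1, c("pct0", "pct1", "pct_ge2")]
#>   pct0 pct1 pct_ge2
#> 1   49   32      19
```

The mean per-object protein load separates the classes (CTC > LEV >
apoptotic) while EpCAM stays negative in about half of all CK+ objects —
the heterogeneity that motivates multi-marker panels.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/slide_report.R", package="ctclev"))')" \
  --demo --out report.csv
```

## Further reading

The methods vignette (`vignettes/ctclev-methods.Rmd`) documents the
generator calibrations, gate thresholds, numerical choices (perimeter
estimation, truncated-normal moment matching, quota bin planting) and known
limitations.
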