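Package: ctclev
Title: Detection, Classification and Multiplexed Scoring of Circulating
    Tumor Cells and Large Extracellular Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rare-event analysis for slide-based liquid biopsies. Segments
    candidate objects from multichannel immunofluorescence scans (DAPI,
    pan-cytokeratin, CD45), computes per-object morphometrics (equivalent
    diameter, circularity, channel signal-to-noise), and applies a
    rule-based gating tree to classify circulating tumor cells (CTCs),
    large extracellular vesicles (LEVs), and apoptotic-like cells.
    Includes cohort-level statistics (inter-slide coefficient of
    variation, LEV-CTC regression, detection-rate and sensitivity-gain
    summaries), per-object 0-3 scoring of imaging mass cytometry (IMC)
    ion-count regions of interest relative to surrounding white blood
    cells, and seeded synthetic-data generators (slides, IMC ROI stacks,
    patient cohorts) with ground-truth manifests for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
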