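Package: iprmtools
Title: Multiplexed MALDI TIMS MS/MS Imaging (iprm-PASEF) Analysis Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: An open analysis pipeline for ion-mobility-resolved MALDI mass
    spectrometry imaging of tryptic peptides with multiplexed MS/MS
    (iprm-PASEF). Covers monoisotopic peptide mass arithmetic, in-silico
    tryptic digestion with variable modifications and b/y fragment series;
    imzML and MGF input/output with per-peak ion mobility (1/K0); RMS
    normalization, ion-image extraction and spatial smoothing; tolerance
    based MS1 feature finding in (m/z, 1/K0) space; bisecting k-means tissue
    segmentation under correlation distance and Pearson co-localization
    statistics; exact weighted-interval scheduling of non-overlapping ion
    mobility precursor windows; mobilogram-filtered MS2 extraction,
    spectrum averaging and decoy-controlled peptide-spectrum matching with
    q-values; cross-platform (MALDI vs. LC-ESI) mass and mobility
    corroboration; and a fully seeded phantom-tissue simulator providing
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    xml2,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
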