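Package: cfepi
Title: Multimodal Epigenetic Analysis of Cell-Free DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts four epigenetic modalities from non-destructive
    methylation sequencing of cell-free DNA (cfDNA): per-CpG and per-region
    DNA methylation ratios, nucleosome occupancy, nucleosome fuzziness, and
    the windowed protection score (WPS). Features are computed over targeted
    panels of CpG markers and 1-kb regions flanking transcription start and
    polyadenylation sites, filtered and ranked with a shadow-feature (Boruta)
    procedure, and integrated by a stacked ensemble of per-modality random
    forests under leakage-free leave-one-out cross-validation with inner
    ten-fold stacking. Includes spike-in conversion QC, a synthetic cfDNA
    cohort generator for offline validation, evaluation metrics (AUC,
    sensitivity at fixed specificity, F1, multiclass accuracy), cross-cohort
    validation, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    ranger,
    glmnet,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
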