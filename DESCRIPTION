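Package: scsmatrisome
Title: Matrisome Fold-Change and Treatment-Reversal Analysis for Pooled
    TMT Proteomics and Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification and classification pipeline for pooled
    tandem-mass-tag (TMT) proteomic and phosphoproteomic experiments with a
    four-group injury/treatment design (uninjured, untreated-injured, and two
    spinal cord stimulation therapies). Computes peptide-level log2 fold
    changes with one-sample t-tests, run-level phospho-isoform fold changes
    with propagated coefficients of variation, applies threshold- and
    significance-based rules for calling proteins affected by the pain model
    and back-regulated by treatment, rolls results up by matrisome functional
    category (structural, adhesion, junction, signaling) with category
    overlap (Venn) counts, and exports tri-state heatmap matrices and
    machine-readable summaries. Includes a synthetic-data generator that
    plants ground-truth effect classes so the full pipeline can be verified
    end to end without access to restricted raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
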