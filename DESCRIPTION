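Package: sepfdr
Title: Sensitivity and Reliability of Peptide Identification Under
    Proteogenomic Database Inflation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how inflation of proteogenomic search
    databases affects sensitive and reliable peptide identification.
    Builds reference, simulated-proteogenomic and six-frame-translated
    protein databases with peptide-level (pseudo-reversed or
    pseudo-shuffled) decoys; simulates per-spectrum best-match scores
    with known ground truth under a Gaussian (correct) plus Gumbel
    (incorrect, extreme-value) mixture with database-size-dependent
    random-hit competition; applies target-decoy, boosted-rescoring and
    mixture-model validation with pooled or separate (class-specific)
    filtering of known and novel peptides, plus a two-stage FDR; and
    orchestrates inflation sweeps reporting accepted known/novel peptide
    counts and FDR diagnostics at a chosen q-value cut-off.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    MASS,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
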