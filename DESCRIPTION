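Package: brcaConcord
Title: Concordance of Breast Cancer Biomarker Calls Across IHC, Digital
    Image Analysis and RT-qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing breast cancer biomarker determinations
    (ER, PR, HER2, Ki67) across routine immunohistochemistry, manual
    re-evaluation, digital image analysis and RT-qPCR. Implements
    delta-delta-Cq relative-units quantification centered on
    marker-specific cutoffs, categorical classification with equivocal
    zones, HER2 reflex-FISH resolution, paired-method agreement
    statistics (intraclass correlation, Pearson correlation,
    Bland-Altman flagging, discordance rates), St. Gallen surrogate
    molecular subtyping with redistribution accounting, and a synthetic
    paired-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
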