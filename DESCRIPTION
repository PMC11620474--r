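Package: barwalk
Title: Barcoded Lineage Tracking, Pooled Fitness Assays, and Growth-Phase
    Performance Decomposition for Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-step barcoded microbial evolution studies: simulation
    of barcoded lineage dynamics and pooled competition fitness assays across
    serial-transfer regimes with multi-phase growth cycles; UMI-deduplicated
    amplicon barcode counting with dual-index demultiplexing and metagrid well
    assignment; lineage fitness inference against neutral reference pools;
    decomposition of per-cycle fitness into per-hour fermentation, respiration
    and stationary-phase performances with error propagation; pleiotropy
    quadrant classification under measurement-error resampling, exact
    contingency and partial-correlation tests; inversion of the beneficial
    distribution of fitness effects through a lineage-detection kernel; and
    recurrence-based mutation annotation rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
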