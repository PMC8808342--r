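Package: hrvalidate
Title: Nocturnal Heart-Rate-Variability Device Validation Against Reference ECG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for validating wearable (PPG/interbeat-interval)
    nocturnal heart rate and heart-rate-variability measurements against a
    single-lead reference electrocardiogram. Provides synthetic paired-night
    generation with ground truth, zero-phase Butterworth band-pass ECG cleaning,
    two-round R-peak detection with refractory and search-back rules, signal
    quality based window validation, 5-minute time-domain (HR, RMSSD, AVNN,
    SDNN, pNN50) and Lomb-Scargle frequency-domain (LF, HF, LF:HF) parameter
    extraction with a 30 percent interbeat-interval validity gate, per-night
    aggregation, and three-way agreement statistics (Pearson correlation,
    linear regression with r-squared, Bland-Altman limits of agreement) at both
    5-minute-window and per-night granularity.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    rlang,
    tools
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
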