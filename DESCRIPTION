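Package: eegdan
Title: Cross-Subject Depression Detection from Few-Electrode EEG via Deep Domain Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for cross-subject detection of major
    depressive disorder from three-channel prefrontal (Fp1, Fpz, Fp2)
    resting-state EEG. Provides a synthetic multi-subject cohort generator
    with controlled class structure and between-subject distribution shift,
    a Butterworth filter-chain preprocessor (high-pass, mains notch,
    band-pass) with core-segment selection and one-second windowing, two
    signal-to-image encoders (merged three-trace grayscale chart and
    per-channel RGB synthesis), and a small convolutional network trained
    with deep domain-adaptation losses: multi-kernel maximum mean
    discrepancy (DAN), adversarial gradient reversal (DANN), and covariance
    alignment (DeepCORAL). Includes subject-level source/target split
    protocols and group-accuracy evaluation utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
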