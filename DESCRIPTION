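Package: snorescreen
Title: Snore-Based Screening for Obstructive Sleep Apnea from Overnight Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens overnight audio recordings for obstructive sleep
    apnea-hypopnea syndrome (OSAHS) from snore sounds alone. Segments snore
    episodes from whole-night recordings by dual-threshold endpoint detection,
    extracts mel-frequency (MFCC), linear-predictive (LPCC) and hybrid (LPMFCC)
    cepstral features, classifies episodes as apnea-related or normal with
    small convolutional and LSTM neural networks implemented on base matrix
    operations, and converts abnormal-snore counts into an apnea-hypopnea
    index (AHI) estimate with a four-level severity grade. Includes a
    synthetic snore and session generator so the full pipeline can be trained
    and evaluated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
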