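Package: qeeg
Title: Quantitative EEG Features for Post-Stroke Cognitive Impairment Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-modal quantitative EEG analysis of 19-channel 10-20
    recordings for discriminating normal, post-stroke mild cognitive
    impairment and post-stroke dementia subjects. Implements Butterworth
    band-pass preprocessing and rational resampling, Daubechies-2 wavelet
    band segmentation with Welch relative band power, inter- and
    intrahemispheric magnitude-squared coherence over canonical electrode
    pair schemes, spectral entropy, dispersion entropy and spectral
    dispersion entropy, per-feature one-way ANOVA with Tukey HSD post hoc
    screening, and stratified cross-validated SVM and k-NN classification
    with macro-averaged metrics. Includes a reproducible synthetic cohort
    generator emulating the groups' spectral, coherence and complexity
    signatures, plus EDF and delimited-text readers for the 10-20 montage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
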