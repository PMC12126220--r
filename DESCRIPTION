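Package: fearsemble
Title: Neural-Ensemble and Psychophysiology Analysis of Fear Generalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for fear-generalization experiments combining
    single-neuron calcium imaging, fiber photometry, freezing behavior, and
    human fear-potentiated startle with plasma endocannabinoid measurements.
    Provides peri-tone alignment, 1-second binning and pre-tone Z-scoring of
    neuron-by-time activity matrices; threshold-based responsive-neuron
    classification and the 9-type NT-by-CS+ response taxonomy; a signed
    stimulus-preference-strength index; Ward hierarchical clustering of
    bounded-rescaled response traces; population-vector PCA with Mahalanobis
    and instantaneous Euclidean trajectory distances; two-channel photometry
    dF/F with peri-tone Z-scoring and freezing-based trial pooling; freezing
    and generalization-index behavior metrics; ITI-standardized startle
    scoring with endocannabinoid correlation and bootstrap regression; and a
    synthetic-data generator with planted ground truth for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
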