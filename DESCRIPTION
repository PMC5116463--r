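Package: wpemg
Title: Wavelet-Packet Feature Extraction and Channel Selection for
    High-Density Surface EMG Pattern Recognition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Myoelectric pattern recognition for high-density surface
    electromyography (sEMG). Implements depth-4 wavelet-packet log-energy
    features with best-basis selection driven by Fisher's class
    separability index (FCSI), the Hudgins time-domain feature set,
    uncorrelated linear discriminant analysis (ULDA) with a Gaussian
    linear discriminant classifier, repetition-wise cross-validation, and
    three electrode channel-selection algorithms: FCSI ranking, sequential
    feedforward selection (SFS), and the combined FCSI+SFS search. A
    synthetic high-density sEMG generator with planted informative
    channels provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, signal, yaml, jsonlite
Suggests: testthat (>= 3.0.0), MASS, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: AllClasses.R AllGenerics.R accessors.R io.R preprocess.R wpt.R
    features.R fcsi.R ulda.R ldc.R crossval.R channel_selection.R
    synthetic.R pipeline.R
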