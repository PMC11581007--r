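Package: tunespace
Title: Tuning Subspace Analysis of Neural Network Auditory Encoding Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits spectro-temporal encoding models (linear-nonlinear and
    population convolutional network architectures) to time-varying neural
    firing rates evoked by sound, extracts the dynamic spectro-temporal
    receptive field (dSTRF) as the Jacobian of a fitted model at every
    stimulus timepoint, reduces the dSTRF collection to a low-dimensional
    tuning subspace by principal component analysis, refits compact subspace
    readout models, and computes tuning descriptors (subspace similarity
    index, tuning symmetry index, tuning surfaces, response-field tiling,
    modulation power spectra). Includes a gammatone spectrogram frontend,
    natural-segment stimulus construction utilities, and a synthetic
    ground-truth generator (linear, quadrature-energy, gain-control and
    and-gate neurons) for end-to-end validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'wav.R'
    'frontend.R'
    'stimulus.R'
    'models.R'
    'fitting.R'
    'dstrf.R'
    'subspace.R'
    'metrics.R'
    'synthetic.R'
    'bundle.R'
    'pipeline.R'
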