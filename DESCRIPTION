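Package: tubavision
Title: Quantitative OCT and Autofluorescence Biomarkers for Endoscopic
    Fallopian-Tube Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for helically scanned endoscopic optical
    coherence tomography with co-registered autofluorescence imaging (OCT-AFI)
    of ex vivo fallopian tubes. Provides luminal-surface and sheath
    segmentation with noise-floor based A-line truncation, depth-calibrated
    autofluorescence in micromolar fluorescein units, depth-resolved optical
    attenuation coefficient estimation with superficial/deep stratification,
    gamma speckle statistics and gray-level co-occurrence (Haralick) texture
    features, anatomical region and diagnosis label assignment along the
    pullback, region-level median biomarker extraction, and a normality-gated
    statistical comparison battery. A synthetic cylindrical tissue phantom
    generator with full ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    minpack.lm,
    car
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'coords.R'
    'segmentation.R'
    'attenuation.R'
    'calibration.R'
    'coregistration.R'
    'io.R'
    'methods.R'
    'phantom.R'
    'texture.R'
    'pipeline.R'
    'stats.R'
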