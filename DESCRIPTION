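Package: PerturbKit
Title: Perturbation-Robustness Evaluation for Binary Image Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring and improving the robustness of binary
    grayscale-image classifiers to common acquisition perturbations
    (Gaussian noise, contrast, rotation, tilt, blur). Builds training-set
    variants in which a controlled fraction of images is replaced by
    perturbed versions, evaluates classifiers on replicated randomly
    perturbed test sets under single and simultaneous perturbations,
    measures perturbation intensity by structural similarity (SSIM), and
    compares perturbation-trained against clean-trained classifiers with
    an exact Wilcoxon signed-rank test. Includes a gradient-free SPSA
    adversarial attack as a control condition, a seeded random-feature
    reference classifier, and a synthetic labeled-image generator so the
    full protocol runs without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, png, yaml, jsonlite, EBImage
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'LabeledImageSet-methods.R'
    'PerturbKit-package.R'
    'imaging.R'
    'rng.R'
    'classifiers.R'
    'adversarial.R'
    'synthetic.R'
    'wilcoxon.R'
    'metrics.R'
    'perturbations.R'
    'protocol.R'
    'experiment.R'
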