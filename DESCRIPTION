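Package: boldfill
Title: Adversarial Restoration of Missing ROI-Level BOLD Time-Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Restores missing region-of-interest (ROI) BOLD time-series in
    resting-state fMRI data with a U-shaped convolutional transformer trained
    adversarially against a multi-resolution discriminator. The generator
    alternates multi-level temporal-correlated attention across ROIs with
    strided one-dimensional convolutional down- and up-sampling; the
    discriminator scores samples at three temporal resolutions through a
    multi-head-attention branch and a central-connectivity-perception branch
    built on Pearson functional connectivity. Training minimises a hybrid
    least-squares adversarial objective plus a multi-resolution consistency
    loss combining temporal mean absolute error, row-wise cross-correlation
    and connectivity-matrix agreement across an average-pooling pyramid.
    Includes evaluation metrics restricted to the missing ROIs (MAE, RMSE,
    R-squared, dynamic time warping, connectivity error), a latent-factor
    generator of BOLD-like synthetic multi-ROI signals, fill-strategy and
    cumulative-masking experiment drivers, and a command-line interface.
    All neural-network machinery (reverse-mode automatic differentiation,
    attention, convolutional sampling, Adam) is implemented in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
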