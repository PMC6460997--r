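Package: ndnseg
Title: Nested Dilation Networks for Multimodal Brain Tumor Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-to-fine three-dimensional brain tumor segmentation with
    nested dilation networks (NDN). Provides NIfTI case input/output for
    four-modality MRI volumes, intensity normalization and tumor-centered
    patch sampling, label-consistent data augmentation, an encoder-decoder
    network assembled from residual blocks, squeeze-and-excitation blocks and
    residual blocks nested with hybrid dilated convolutions (with analytic
    receptive-field computation and gridding validation), four
    class-imbalance-aware training objectives, a three-stage cascade refining
    whole tumor to tumor core to enhancing tumor, connected-component
    post-processing, and a multimodal phantom generator so the whole pipeline
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
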