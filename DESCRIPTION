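Package: endokey
Title: SSIM Keyframe Summarization and Lesion Classification for Endoscopic Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes endoscopic (video-laryngoscopy) recordings by selecting
    keyframes whose structural similarity (SSIM) to the preceding frame falls
    below a threshold, exports keyframe datasets with manifests and stratified
    train/validation splits, and classifies frames (healthy vocal folds,
    nodules, polyps) with a dual-backbone feature-fusion convolutional network
    supporting frozen and fine-tune-last-k transfer modes. Includes a
    from-scratch windowed SSIM, a calibrated synthetic laryngoscopy video
    generator with scene-cut ground truth, and a full evaluation stack
    (confusion matrices, per-class and macro precision/recall/F1, multiclass
    Matthews correlation coefficient, one-vs-rest ROC/AUC, stratified
    cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    optparse,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    pROC,
    MASS
Config/testthat/edition: 3
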