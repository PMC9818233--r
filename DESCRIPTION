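Package: pvcnet
Title: Premature Ventricular Contraction Recognition from Single-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for recognising premature ventricular
    contractions (PVCs) in annotated single-lead ECG recordings. Provides
    reading and writing of PhysioNet WFDB-convention records, a synthetic
    ECG generator with ground-truth R-peak annotations, a from-scratch
    Pan-Tompkins QRS detector operating at 200 Hz, midpoint beat
    segmentation with deterministic beat-to-RGB-image rendering, a
    residual-network (ResNet-18 family) classifier with a two-class head
    and optional pretrained backbone, class-imbalance-aware training
    (weighted binary cross-entropy, weighted random sampling, on-the-fly
    augmentation, Adam with plateau learning-rate decay and early
    stopping), and patient-specific evaluation harnesses (cross-dataset,
    leave-one-subject-out, hold-out and stratified k-fold) with a full
    confusion-matrix metrics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
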