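Package: dermseg
Title: Dermoscopic Skin Lesion Segmentation with Border and Hair Artifact Removal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage pipeline for segmenting pigmented skin lesions in
    dermoscopic images. Dark corner borders left by the round dermatoscope lens
    are located by a diagonal threshold walk and detached; hairs are detected by
    a morphological closing difference, sliced into a binary mask and removed by
    fast-marching inpainting; contrast is boosted by a monotone log-exp transfer
    applied to the HSV value channel; and the lesion is extracted by an
    automatically initialized GrabCut (Gaussian mixture colour models refined by
    graph min-cut). Includes Jaccard/Dice evaluation, batch reporting, and a
    seeded synthetic dermoscopy fixture generator with paired ground truth so
    the whole pipeline is testable without any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
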