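Package: panicle3D
Title: Semantic Segmentation of Rice Panicle Point Clouds with Continuous
    Point Convolutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments 3D point clouds of rice plants into stem and panicle
    (grain-bearing ear) points. Implements an encoder-decoder neural network
    built from PointConv continuous convolutions with inverse-density
    weighting, squeeze-and-excitation channel recalibration, two-scale
    Inception neighborhoods, and configurable long and short skip
    connections, together with the surrounding pipeline: PLY/PCD/XYZ point
    cloud I/O, statistical outlier removal, Gaussian neighborhood smoothing,
    farthest point sampling to a fixed input size, label-preserving data
    augmentation, a synthetic labeled panicle generator for testing and
    benchmarking, Adam training with reduce-on-plateau scheduling, and
    accuracy/IoU evaluation. All network forward and backward passes are
    implemented in vectorised base R.
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
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
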