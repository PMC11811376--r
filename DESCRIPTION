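Package: hasm
Title: Heatmap-Based Active Shape Model for Lumbar Spine Landmark Correction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Corrects the positions of the 22 lumbar-spine landmarks (four
    corners of L1-L5 plus the two endpoints of the sacral upper endplate)
    from per-landmark heatmap responses, such as those produced by keypoint
    regression networks. Provides a point-distribution shape model built by
    generalized Procrustes analysis and principal component analysis, with
    artificial spondylolisthesis augmentation to de-bias the model; an
    iterative correction loop alternating heatmap-gradient updates (Sobel
    magnitude and orientation, bilinear subpixel sampling) with projection
    onto the shape subspace; optional snap-back post-processing toward
    heatmap maxima; evaluation metrics (per-image maximum and mean errors,
    allowable-error normalization, interval histograms, paired t-tests);
    and a parametric synthetic generator of spine configurations and
    corrupted heatmap stacks so every stage can be exercised without images
    or trained networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
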