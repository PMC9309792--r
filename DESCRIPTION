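Package: spineload
Title: Patient-Specific Static Musculoskeletal Models of the Thoracolumbar
    Spine from Labeled Segmentation Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds static musculoskeletal models of the thoracolumbar spine
    from multi-label vertebra segmentation volumes and computes muscle forces
    and lumbar vertebral loads (compression, anterior-posterior shear, lateral
    shear) for static loading tasks.  Includes a parametric synthetic-spine
    generator with configurable sagittal and frontal curvature, landmark and
    joint extraction from subregion masks, CT-intensity tissue classification
    with per-level mass partitioning, a nonlinear toe-region ligament law,
    lumped intervertebral disc stiffness, a nine-group trunk muscle
    architecture, and a static optimization solver that minimises the sum of
    cubed muscle stresses subject to joint-moment equilibrium and
    physiological force bounds.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
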