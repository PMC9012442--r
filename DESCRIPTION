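Package: spinekin
Title: In Silico CT Kinematics of the Equine Thoracolumbar Spine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and measurement pipeline for computed-tomography based
    kinematic evaluation of interspinous ligament desmotomy (ISLD) in the
    equine thoracolumbar spine. Generates articulated nine-vertebra (T11-L1)
    spine phantoms with known per-joint kinematics, voxelizes them into
    Hounsfield-unit CT volumes, segments individual vertebrae by HU
    thresholding and connected components, superimposes imaging phases on an
    anchor vertebra by rigid (Kabsch/ICP) registration, and quantifies local
    (inter-spinous-process distances, per-space range of motion) and global
    (L1 excursion, Hausdorff distance, rotation) mobility changes with a
    paired repeated-measures statistical workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
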