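Package: voxflap
Title: Hybrid Voxel/Mesh Modeling of DIEP-Flap Presurgical 3D-Print Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds patient-specific, multi-material 3D-print models for
    deep inferior epigastric perforator (DIEP) flap planning from CT
    angiography-like volumes. Segments anatomy by Hounsfield range,
    composites structures in a multi-channel voxel grid (boolean
    subtraction and material-channel arithmetic), stamps a measured grid
    of plane-halo bands onto the rectus abdominis muscle, classifies
    vessels as intra- or extra-muscular by containment, and exports
    watertight multi-part STL meshes with a print-material manifest.
    Includes a seeded synthetic abdomen phantom with per-structure ground
    truth so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
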