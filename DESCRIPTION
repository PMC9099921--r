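Package: archssm
Title: Statistical Shape Models of Dental Arch Borderlines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds point-distribution statistical shape models of dental
    arch soft-tissue borderlines and reconstructs the mucogingival
    borderline (MG-BL) of a jaw from the gingival margin (the mucous-tooth
    borderline, MT-BL) alone.  Provides rigid Kabsch registration,
    generalized Procrustes analysis restricted to a landmark subset,
    thin-plate-spline bending energy and sliding-semilandmark relaxation,
    PCA shape models with posterior-mean prediction from partial
    observations, leave-one-out cross-validation with pooled percentile
    error statistics, a synthetic dental-arch population generator, and
    readers/writers for 3D Slicer markups (.fcsv, .mrk.json) and PLY
    meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
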