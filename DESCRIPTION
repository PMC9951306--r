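Package: azokin
Title: Thermal Isomerization Kinetics of Azo Photoswitches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated workflow for predicting thermal cis-to-trans
    isomerization kinetics of azobenzene-like photoswitches. Locates
    rotation and inversion transition states by relaxed scans and
    eigenvector following, traces intrinsic reaction coordinates, finds
    singlet-triplet minimum-energy crossing points, and computes rates and
    half-lives by both Eyring transition-state theory and a Landau-Zener
    intersystem-crossing rate theory. Potential-energy surfaces are
    pluggable: analytic fixture surfaces, a toy Cartesian force field, and
    a miniature equivariant message-passing neural potential with
    ensemble-based active learning.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, yaml, Matrix
Suggests: testthat (>= 3.0.0), ChemmineOB, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
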