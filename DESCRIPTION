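Package: coildeploy
Title: Discrete Elastic Rod Simulation of Endovascular Coil Embolization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the deployment of embolization coils into cerebral
    aneurysms with a discrete elastic rod model: natural-shape bending and
    twist on a Bishop-frame parametrization, symplectic Euler dynamics with
    micro-catheter insertion boundary conditions, octree-accelerated
    coil-coil and coil-wall contact with Coulomb stick-slip friction, and an
    in silico Raymond-Roy-type occlusion classification built on coil
    voxelization and signed-distance-field region partitioning of the
    aneurysm sack.  Includes a synthetic dome-aneurysm generator, ASCII
    STL/OBJ/PLY mesh input/output, VTK trajectory export and a scenario
    runner for reproducible in silico coiling studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
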