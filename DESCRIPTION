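Package: emod
Title: Ephaptic Modulation Indices on Cortical Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes ephaptic modulation indices (EMOD1 and configurable
    variants) on triangulated cortical surface meshes: analytic quasi-static
    current-dipole potentials and fields in a homogeneous conductive medium,
    the lambda-E membrane perturbation rule, orientation- and distance-gated
    1/r^3 pair sums over surface vertices, and power-law decay fitting.
    Includes readers and writers for FreeSurfer binary surfaces and curv
    maps, ASCII PLY and OFF; mesh repair, vertex normals and areas, radius
    neighbor search and geodesic distances; synthetic folded-surface
    phantoms (sulcus, parallel plates, sphere, flat sheet) and an
    age-parameterized synthetic cohort; and the morphometric statistics
    stage (thickness and gyrification proxies, geodesic Gaussian smoothing,
    vertex-wise Pearson correlation with Benjamini-Hochberg FDR control,
    and polynomial trend fits).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
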