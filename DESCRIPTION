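Package: voxpocket
Title: Voxel-Based Detection and Ranking of Protein-Ligand Binding Pockets
Version: 0.1.0
Authors@R:
    person("voxpocket", "developers", email = "voxpocket@example.org",
           role = c("aut", "cre"))
Description: Geometric detection of candidate ligand-binding pockets on
    protein surfaces. A structure read from a PDB file is discretized onto
    a van der Waals occupancy voxel grid; every surface voxel receives a
    solid angle estimated from the occupied fraction of a virtual sphere;
    the most concave voxels are clustered into candidate pockets; each
    pocket is scored by a discretized cavity-depth indicator and a
    directional-ray cavity-volume indicator, and pockets are ranked by a
    weighted combination of both. Includes confusion-matrix evaluation
    against annotated binding residues and a generator of analytic solid
    fixtures (spheres, slabs, wells, carved pockets) so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
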