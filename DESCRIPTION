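Package: craniotome
Title: Computational Geometry for Virtual Craniotomy Planning and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless computational core of a virtual craniotomy training
    simulator for intracranial-aneurysm surgery. Provides triangle-mesh and
    surface-contour data structures with STL/PLY/OBJ readers and writers, a
    deterministic synthetic-anatomy phantom (skull shell, brain lobes split
    at a fissure plane, Circle-of-Willis stand-in vessel, landmarks and
    craniotomy template contours), clamped two-axis head positioning,
    freehand craniotomy simulation (contour projection onto the skull,
    barrier-bounded region growing and bone-patch excision), ray-cast
    exposure evaluation toward an intracranial target, mass-spring brain
    retraction with position-Verlet integration, and contour-precision
    metrics (tolerance-based surface Dice similarity coefficient and
    Hausdorff distance).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
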