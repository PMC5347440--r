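Package: mvnflow
Title: Discrete Red-Blood-Cell Blood Flow Simulation in Cortical Microvascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates blood flow in cortical microvascular networks with
    discrete tracking of individual red blood cells (RBCs). Provides a vascular
    graph data model with vessel-type labeling and geometric trimming, the
    empirical in-vitro apparent-viscosity law with tube/discharge hematocrit
    conversion, a sparse Poiseuille pressure/flow solver, histogram-based
    upscaling of capillary diameters to a goal beta distribution, a synthetic
    cortical vasculature generator (stacked hexagonal capillary bed plus
    penetrating arteriole/venule trees), a hierarchical boundary-condition
    scheme based on implanting a network into an artificial host, and an
    RBC-trajectory analysis suite (layer-specific pressure drops, capillary
    transit-time statistics, preferred paths and feeding properties).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
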