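Package: lfpnet
Title: Rule-Based Neuronal Network Construction, Spiking Simulation, and
    Extracellular Potential Forward Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds large heterogeneous neuronal network models from
    high-level rules into a type-instance relational file format (HDF5
    instance tables plus editable CSV type tables), simulates them with
    built-in leaky integrate-and-fire and passive multi-compartment cable
    models, and forward-models multi-electrode extracellular potentials by
    the line-source method. Includes deterministic counter-based random
    streams so that network builds and simulations are reproducible and
    independent of how cells are partitioned across logical ranks, buffered
    HDF5 simulation reports with per-rank temporary files merged at the end
    of a run, SWC morphology loading and discretization with
    distance-constrained synapse placement, and synthetic fixture
    generators (ball-and-stick morphologies, Poisson spike trains, example
    network compositions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rhdf5,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
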