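Package: nephrosim
Title: Discrete Multiscale Simulation of Nephroblastoma Response to
    Preoperative Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clinically oriented, predominantly discrete multiscale simulator
    of Wilms' tumor (nephroblastoma) response to preoperative vincristine plus
    actinomycin-D chemotherapy as given in the SIOP/GPOH protocol. The engine
    advances an age-structured cytokinetic compartment model (stem, limited
    mitotic potential, terminally differentiated, apoptotic and necrotic cells,
    with explicit G0 dormancy) in fixed one-hour steps, applies cell-kill-ratio
    based pharmacodynamics with drug-specific death points, and evolves the
    tumor either as a well-mixed population or on a 3D lattice of geometrical
    cells with content-shifting expansion and shrinkage. Includes equilibrium
    (dominant-eigenvector) initialization, growth-rate and volume-reduction
    metrics, one-at-a-time parameter ranking and two-parameter grid sensitivity
    analyses, five packaged virtual-tumor scenarios, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
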