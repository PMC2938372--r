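Package: viscocell
Title: Sub-Cellular Viscoelastic Simulation of Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based biomechanical simulation of deformable epithelial
    cells in two dimensions. Each cell is a network of Kelvin-Voigt
    (spring-dashpot) elements joining discretized plasma-membrane and
    nuclear-membrane rings, with radial cytoskeletal elements, diametral
    nucleoskeletal chords, and an osmotic pressure load. Cells interact
    through distance-gated adhesion bonds with rupture hysteresis, short
    range elastic repulsion, and a deformable extracellular-matrix chain;
    substrate adhesion intensity is represented by a per-node drag
    coefficient. Rule-based cellular processes (growth by node insertion,
    mitosis with spindle and contractile-ring forces, apoptosis,
    polarization, and crawling motility) let cultures emerge from one or
    two founder cells. Includes tissue-geometry statistics (form factor,
    cell edge density, neighbor graphs), scenario constructors for
    monolayer, cyst, acinus, ECM-gap and tensegrity-bud case studies,
    plain-text frame input/output and a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
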