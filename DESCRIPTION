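Package: csfsim
Title: Desk-Scale Simulation of Intrathecal Drug Dispersion in Oscillatory CSF Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates dispersion of an intrathecally injected drug in the spinal
    subarachnoid space. An idealized axisymmetric annular spinal-canal geometry
    (dura outer wall, spinal cord inner wall, lumped cranial reservoir) carries
    oscillatory cerebrospinal-fluid flow driven by synthesized cardiac and
    respiratory waveforms plus steady production. Unsteady incompressible
    laminar flow is solved with a staggered finite-volume pressure-projection
    scheme; drug transport follows a conservative advection-diffusion update
    with limited second-order upwind fluxes and a strict mass ledger. Includes
    a needle-injection model (gauge, speed, duration), the nine-run injection
    parameter matrix, post-processing metrics (level-window concentrations,
    domain-mean drug percentage, cranial arrival times), and verification
    tools (mesh-independence and time-step studies, analytic annular Poiseuille
    and oscillatory Womersley-type oracles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
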