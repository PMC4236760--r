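Package: crnemu
Title: Morphisms and Kinetic Emulation of Chemical Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating the structure and kinetics of chemical
    reaction networks (CRNs) through network morphisms.  Networks are built
    directly from reaction lists (a plain-text '.crn' format) or compiled
    from activation/inhibition influence networks via a three-species
    triplet motif.  Species/reaction maps between networks can be checked
    statically, by integer and rate-weighted matrix algebra, for the
    reactant-morphism, homomorphism, stoichiomorphism and
    net-stoichiomorphism conditions; a morphism satisfying the reactant and
    stoichiometry conditions is a kinetic emulation, meaning the source
    network exactly retraces every mass-action trajectory of the target.
    The package verifies emulations dynamically (derivative identities and
    paired trajectories via stiff ODE integration), lifts rate changes
    across stoichiomorphisms, transfers steady states, and searches for
    emulation morphisms between networks by unit-rate homomorphism
    enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
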