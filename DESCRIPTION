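Package: acvconf
Title: Conformational Analysis of Acyclic Nucleoside Analogues
Version: 1.0.0
Authors@R:
    person("Mar", "Quesada", email = "mquesada@example.org",
           role = c("aut", "cre"))
Description: Tools for the conformational analysis of acyclovir-like acyclic
    nucleoside analogues. Computes chain-placement descriptors (the five
    exocyclic torsions phi1-phi5, the pseudo-bond distance R and angles beta
    and Phi), classifies conformers as syn/anti about the glycosidic-like
    N9-C1' bond, derives Boltzmann tautomer and conformer populations from
    tabulated relative energies, quantifies purine-ring nonplanarity,
    detects and types intramolecular and intermolecular hydrogen bonds in
    monomers and multimer assemblies, and runs a five-torsion grid
    conformational search with local relaxation under a pluggable energy
    model. Quantum-chemical energies are consumed as tabulated inputs; a
    synthetic-data module builds idealized templates, posed assemblies and
    surrogate conformer ensembles so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
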