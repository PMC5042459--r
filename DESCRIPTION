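Package: polyion
Title: Protonation, Aggregation and Sizing Analysis for Weak-Base Polyelectrolyte Solutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis tools for hydrophobic weak-base polyelectrolytes such as
    linear polyethylenimine (PEI) in salt solutions. Decomposes dynamic light
    scattering autocorrelation curves into free-chain and aggregate relaxation
    modes using sums of stretched exponentials (Kohlrausch-Williams-Watts),
    sizes each mode through the Stokes-Einstein relation, and checks diffusive
    q-squared scaling across scattering angles. Infers the amine protonation
    fraction from constant-concentration pH titrations by charge balance
    (electroneutrality), with polymer-free control correction, buffering
    capacity, apparent pKa location, and detection of stalled charge states.
    Fits the dilute-solution osmotic virial expansion and flags association
    (plateau or maximum) signatures in vapor-pressure osmometry data. A
    forward simulator generates all three measurement types from an explicit
    ground-truth protonation isotherm so that every analysis stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
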