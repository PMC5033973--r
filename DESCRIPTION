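Package: glycoMCA
Title: Kinetic Modeling and Metabolic Control Analysis of Cancer Glycolysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Kinetic ODE models of glycolysis in AS-30D hepatoma and HeLa
    cervical cancer cells built from enzyme rate equations (reversible
    Michaelis-Menten transporters, random Bi-Bi hexokinase with
    fructose-1,6-bisphosphate feedback, multi-inhibitor hexose phosphate
    isomerase with competitive, uncompetitive and mixed mechanisms, a
    Monod-Wyman-Changeux phosphofructokinase-1, ordered Ter-Bi GAPDH, and
    random bisubstrate kinases). Computes steady states by stiff
    integration with Newton refinement, flux and concentration control
    coefficients by finite differences and by the elasticity matrix method
    of metabolic control analysis, and runs in-silico enzyme titrations,
    feedback-inhibition scenarios, and inhibition-mechanism/Ki scans.
    Includes a synthetic parameter and observation generator with Haldane
    thermodynamic consistency and SBML import and export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    xml2,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
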