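Package: cvloop
Title: Closed-Loop Beta-Blocker and Volume Therapy Simulation on the
    Circulatory Equilibrium Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates and scores automated closed-loop administration of an
    ultra-short-acting beta-blocker (landiolol) together with volume therapy
    (dextran infusion, furosemide boluses) in acute heart failure.  The
    hemodynamic backbone is the circulatory-equilibrium framework: logarithmic
    Frank-Starling curves for both ventricles intersected with a planar venous
    return surface.  The package estimates the four mechanistic parameters
    (left and right Frank-Starling slopes, systemic vascular resistance,
    stressed blood volume) from measured hemodynamics, derives target values
    from clinician-set arterial and left atrial pressure goals, closes the
    loop with a proportional-integral landiolol controller and a nonlinear
    volume controller, exercises the loop against a virtual canine
    heart-failure patient with one-compartment pharmacokinetics and Emax
    pharmacodynamics, and reports Varvel-style controller performance
    statistics (MDPE, MDAPE, wobble, divergence, time in acceptable range).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
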