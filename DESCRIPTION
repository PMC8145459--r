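Package: pedpbpk
Title: Virtual Chinese Paediatric Population PBPK Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates virtual Chinese paediatric subjects (0-18 years) from
    published sex-specific growth, body-surface-area, cardiac-output and organ
    volume equations, couples them to minimal and full perfusion-rate-limited
    physiologically based pharmacokinetic (PBPK) drug models, and simulates
    literature trial designs for four intravenous probe drugs (theophylline,
    fentanyl, ceftazidime, vancomycin).  Includes in vitro-in vivo
    extrapolation of hepatic clearance with CYP ontogeny and microsomal
    protein scaling, glomerular-filtration-rate maturation for renal
    clearance, noncompartmental analysis, and predicted-versus-observed
    evaluation with the conventional 2-fold acceptance band.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
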