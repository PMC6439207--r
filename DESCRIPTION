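Package: pahlung
Title: Bioaccessibility-Based Inhalation Cancer Risk Assessment for
    Particle-Bound PAHs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the inhalation carcinogenic risk of
    polycyclic aromatic hydrocarbons (PAHs) bound to airborne fine
    particles (biochar fine particles, PM2.5) with and without
    accounting for bioaccessibility in simulated lung fluids.
    Implements the bioaccessible-fraction computation from desorption
    experiments, the daily-intake (DI) versus acceptable-daily-intake
    (ADI) exposure model, and the benzo[a]pyrene toxic-equivalency
    (BaP-TEQ) concentration model, each runnable in total-concentration
    and bioaccessibility modes. Bundles reference datasets for twelve
    biochar fine-particle matrices and an urban PM2.5 PAH profile, a
    seeded synthetic desorption-series generator, and a command-line
    interface for CSV-driven assessments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
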