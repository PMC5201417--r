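Package: myotension
Title: Myosin Motor Activity, Epithelial Tension and Apical Constriction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline linking non-muscle myosin II motor
    activity to epithelial tissue contraction. Fits steady-state actin-activated
    ATPase data to the Michaelis-Menten model and derives allelic-series summary
    statistics (k_basal, k_cat, K_app, k_100, fold activation); quantifies
    tissue tension from laser-ablation recoil by kymograph edge extraction and
    Kelvin-Voigt and power-law viscoelastic fits (initial recoil velocity, time
    decay constant, power-law exponent, R-squared acceptance filtering);
    implements myosin-accumulation-normalized apical constriction rate analysis
    (trace smoothing, instantaneous rates, 1-2 SD accumulation-event detection
    against control statistics, embryo alignment, time to 50% initial area);
    and provides a seeded synthetic-data generator with known ground truth for
    all three data classes, nonparametric group comparisons, and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
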