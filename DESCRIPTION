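Package: agavin
Title: Fructan Structure Inference from Glycosidic-Linkage Data and HPTLC Chemometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for structural characterization of fructans (inulins, levans,
    graminans and the highly branched neo-fructans known as agavins) from
    glycosidic-linkage data. Represents fructan polymers as rooted trees of
    hexose residues, predicts the partially methylated alditol acetate (PMAA)
    linkage census any structure would yield, classifies PMAA electron-impact
    spectra into linkage classes by diagnostic-ion rules, and implements the
    glucose-normalized molar-ratio procedure that infers core degree of
    polymerization, per-linkage molecule counts, branching frequency and the
    graminan/neo-fructan proportion of a mixture, with scaling of proposed
    structures to a chromatographically determined maximum DP. Also provides
    chemometrics for thin-layer-chromatography band tables (Pareto scaling,
    PCA, two-class OPLS-DA with permutation and CV-ANOVA validation, S-plot
    marker selection, Rf-to-DP calibration) and seeded forward simulators for
    fructan mixtures, PMAA spectra and band tables so every stage can be tested
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
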