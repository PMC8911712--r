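Package: vocscreen
Title: Volatile-Compound Profiling and Control-Anchored Docking Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for summarizing headspace GC-MS volatile-compound
    abundance tables, triaging docking scores against positive and negative
    control ligands with ANOVA and Tukey HSD compact letter displays,
    correlating molecular descriptors with per-site docking affinities, and
    fingerprinting protein-ligand interfaces through probe-excluded pairwise
    atomic contact areas with prosthetic-group subsite aggregation. Includes
    deterministic synthetic-data generators (planted score panels, toy
    complexes with closed-form contact areas, threshold-straddling peak
    tables) so every stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
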