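Package: pepassembly
Title: pH-Responsive Peptide Charge Models, Beta-Turn Assignment and
    Aggregate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale analysis chain for short self-assembling peptides
    such as uncapped A6K (H2N-AAAAAAK-OH). Computes per-site
    Henderson-Hasselbalch protonation, net charge, titration curves,
    isoelectric points and molecular mass for peptides with free or
    blocked termini; reads and writes multi-model multi-chain PDB and
    single-configuration GRO coordinate files; generates synthetic
    backbone conformers and multi-peptide systems by internal-coordinate
    construction with controllable secondary structure and dispersed or
    micellar spatial organisation; assigns coarse secondary structure
    from backbone dihedrals and detects beta-turns by the classic
    i to i+3 hydrogen-bond and C-alpha distance criteria; and
    characterises aggregates by contact clustering, radius of gyration,
    amphiphilic radial ordering and coarse pairwise electrostatic
    scores. A seeded pipeline driver reproduces a full analysis from one
    YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
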