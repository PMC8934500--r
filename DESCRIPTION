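Package: coilscreen
Title: Ensemble Mutational Screening and Trajectory Analysis for
    Coiled-Coil Homodimer Stabilization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering dimer-stabilizing
    mutations in two-chain parallel coiled-coil homodimers such as the
    N-terminal dimerization domain of the Siah-1-interacting protein
    (SIP/CacyBP). Generates ideal Crick-parameterized coiled-coil models
    and synthetic trajectories with programmable interaction schedules,
    scores complexes with a pluggable residue-centroid contact potential
    (total_score, mono_score, binding dG), runs ensemble design screens
    with native re-introduction and selects candidates by negative
    ddG and near-zero delta mono_score, analyzes trajectories (Kabsch
    superposition, backbone RMSD profiles, salt-bridge/stacking
    occupancy, per-frame binding-energy aggregation over replicates),
    and predicts ExPASy-compatible isoelectric points and average
    molecular weights for variant sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
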