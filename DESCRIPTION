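Package: slimscan
Title: Fragment-Scan Consensus Mapping of Domain-Linear Motif Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mapping the interface between a folded bait domain
    and a short linear motif (SLiM) in a disordered tail from ensembles of
    predicted two-chain structure models and from molecular dynamics
    trajectories.  The tail is tiled into overlapping fragments anchored at
    its start, middle and end; each fragment/domain pair is one prediction
    run.  Inter-chain residue contacts are extracted from the top-ranked
    model of each run under a heavy-atom distance rule and aggregated into
    a consensus contact-frequency matrix whose hotspots localise the motif.
    Companion functions compute residue contact maps, marginal interaction
    profiles, hydrogen-bond persistence and motif-anchoring classification
    from replicate trajectories, and perform Kabsch least-squares
    superposition.  A synthetic-data module generates toy complexes, mock
    prediction-run directories and toy trajectories with planted interfaces
    so that the full pipeline can be exercised and validated without
    external prediction or simulation engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
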