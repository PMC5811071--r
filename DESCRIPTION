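Package: memprobe
Title: Conformational Gating Probes, Cholesterol Occupancy Maps and Motif
    Scanning for Membrane-Transporter Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trajectory-analysis toolkit for membrane-transporter molecular
    dynamics, built around the out-to-inward transition of SLC6
    neurotransmitter transporters. Provides the six-probe transition metric
    suite (TM5 RMSD, helicity, kink angle, Na2-site water count, and
    solvent-accessible surface areas of the intracellular exit pathway),
    extracellular/intracellular gate distance monitors, per-residue RMSF,
    cholesterol occupancy grids with enrichment-based binding-site detection
    and bound/unbound event traces, CRAC/CARC cholesterol-recognition motif
    scanning, and C-alpha principal component analysis with cosine-content
    diagnostics and extreme-structure export. A deterministic synthetic
    toy-transporter generator with ground-truth labels makes every stage
    testable without simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
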