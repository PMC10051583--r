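Package: memtopo
Title: Membrane Topology and Dynamics of Helical Peptides from NMR Observables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines the membrane topology and dynamics of amphipathic
    helical peptides from solution- and solid-state NMR observables. Builds
    ideal alpha-helix models from backbone dihedrals, forward-computes
    motionally averaged oriented-sample 15N chemical shifts from a chemical
    shift anisotropy tensor with Gaussian wobble and azimuthal fluctuations,
    and inverts measured shifts into tilt/pitch compatibility maps with
    connected solution regions. Also implements chemical-shift-deviation
    secondary-structure calling, amide-proton dispersion, paramagnetic
    relaxation enhancement percentage-loss profiles with linear error
    propagation, helical-periodicity fitting, amphipathic-face statistics,
    and deuterium order-parameter profiles of lipid acyl chains from
    quadrupolar splittings. A seed-controlled synthetic-data module generates
    every input format so the full pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
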