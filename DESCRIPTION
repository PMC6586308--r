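Package: mstrkit
Title: Mouse Cell Line Authentication with Tetranucleotide STR Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for authenticating mouse cell lines with a multiplex
    short tandem repeat (STR) assay of 19 tetranucleotide mouse markers and
    two human contamination-screen markers. Converts capillary-electrophoresis
    peak tables into allele calls using calibrant-anchored size bins with
    +/- 4 bp extrapolation and minus-4/plus-4 stutter-ratio rules, derives
    marker- and allele-specific stutter filters (mean plus three standard
    deviations) with a Friedman test for instrument effects, compares profiles
    with Master's percent-match algorithm, scores interlaboratory concordance
    by agreement proportions, and simulates realistic peak tables, stutter
    observations, and multi-laboratory studies for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'alleles.R'
    'AllClasses.R'
    'panel.R'
    'binset.R'
    'peaks.R'
    'profiles.R'
    'fixtures.R'
    'caller.R'
    'stutter.R'
    'matching.R'
    'concordance.R'
    'synthetic.R'
    'cli.R'
    'mstrkit-package.R'
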