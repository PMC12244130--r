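Package: gradientnet
Title: Tissue-Gradient Co-Expression Grouping and Signed Gene Network
    Assembly for Seed Germination
Version: 0.1.0
Authors@R: person("Maintainer", "Gradientnet", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies groups of co-expressed hormone-responsive genes along
    the Arabidopsis funiculus to chalazal-seed-coat expression continuum from
    three-tissue microarray signal tables, partitions them into subgroups by
    a pairwise squared-correlation threshold, validates subgroups by
    leave-one-out profile sums, and assembles a signed, directed seed
    germination gene network integrating auxin, abscisic-acid and
    brassinosteroid regulons.  Includes paired germination-assay statistics
    and a synthetic-data generator with planted ground truth so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
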