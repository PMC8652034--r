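Package: sse2d
Title: Family-Wide Protein Secondary Structure 2D Diagrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects alpha-helices and beta-strands from C-alpha traces of
    protein domains, cross-annotates topologically equivalent elements across
    a family so that they share labels, groups strands into sheets, and lays
    out each domain in the plane by minimizing the error of projecting the 3D
    arrangement of secondary structure elements into 2D, optionally restrained
    towards a previously computed family member's layout. Renders per-domain
    SVG cartoons and a family-wide overlay diagram in which each element's
    opacity equals its occurrence frequency. Includes a synthetic-structure
    generator (ideal helices, strands, sheets, perturbed families with ground
    truth) so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
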