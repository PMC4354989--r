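Package: featuretrack
Title: Sequence Feature Annotation Tracks Rendered as Static SVG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Parses feature annotations of a single nucleotide or protein
    sequence from a generic JSON dialect and from three per-residue
    prediction formats (PSIPRED '.ss2' secondary structure, Paircoil2
    '.pc2' coiled-coil, DISOPRED '.diso' disorder), computes collapsed and
    expanded track layouts for overlapping annotations using interval
    merging and greedy first-fit sub-track packing, and renders
    publication-quality, coordinate-aligned SVG track views with summary
    bars, marker lines, tooltips (SVG title elements) and hyperlinks.
    Includes deterministic generators of synthetic annotation sets and
    format files, and a command-line interface for rendering, format
    conversion and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    grDevices,
    stats
Suggests: testthat (>= 3.0.0), IRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
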