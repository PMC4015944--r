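Package: granno
Title: Overlap and Neighbor Annotation of Genomic Regions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates sets of genomic query regions with overlapping and
    neighboring features from one or more annotation sources. Implements a
    complete 16-class taxonomy of overlap configurations between two genomic
    intervals, including zero-length (insertion-point) elements, a
    start-sorted sweep engine with memoized cursors for batch overlap and
    nearest-non-overlapping-neighbor queries, and strand-aware anchored
    distance calculation (5'/3'/start/end/center anchors, e.g. distance to
    the nearest transcription start site). Reads query regions in tolerant
    position-coordinate dialects or BED, reads annotation files in BED or
    with user-specified column indices, builds promoter regions around
    transcription start sites, and writes tab-delimited annotation tables
    with UCSC genome browser links. Includes seeded synthetic fixture
    generators and brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
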