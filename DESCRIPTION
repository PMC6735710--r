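Package: gelwarp
Title: Alignment and Differential Analysis of Complexome Profiling Gels
Version: 0.1.0
Authors@R: person("gelwarp", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: In-silico alignment of complexome profiling gel lanes by
    multi-dimensional dynamic time warping and progressive alignment along a
    single-linkage guide tree, followed by per-protein quantification of
    case-versus-control migration differences with the Hausdorff distance on
    rescaled migration curves, a Hausdorff effect size (HES) ranking, and
    export of ranked lists for preranked gene-set enrichment analysis.
    Includes a synthetic-profile generator with known ground truth and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
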