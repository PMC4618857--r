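Package: mapbench
Title: Individualized Benchmarking and Parameter Optimization for NGS Read Mappers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks short-read mappers on data that looks like yours.
    Samples non-overlapping regions from a reference genome by genome-size
    tiers, concatenates them into an N-padded artificial chromosome,
    simulates truth-tracked reads under a SNP/indel/sequencing-error model,
    executes mappers (external adapters, a built-in k-mer baseline, a
    truth-reading oracle) over cartesian parameter grids while recording
    mapping wall time and peak memory, classifies every read as correctly,
    wrongly, or not mapped, and reports precision, recall, F-measure and
    correctly-mapped-reads-per-second, including an accuracy-versus-
    throughput quadrant analysis relative to a baseline setting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
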