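---
title: "Benchmarking read mappers on individualized synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking read mappers on individualized synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapbench)
```

## The problem

Close to a hundred short-read mappers exist, and none dominates across read
lengths, error profiles, SNP densities and genome complexities. Most studies
nevertheless run one popular mapper with default parameters, which can cost
percentage points of correctly placed reads — and, downstream, coverage,
heterozygosity and allele-specific signals. `mapbench` benchmarks mappers on
data that *looks like yours*: it simulates reads whose true origin is known,
with the read length, SNP/indel rates and sequencing error you specify, from
the genome you will actually map against, then measures each mapper and
parameter setting on those reads.

A full-genome benchmark is slow (hours for a mammalian genome). The central
shortcut is to **simulate from a subsample of the genome but map against the
whole genome**. Mappers still face the complete search space — repeats,
decoys, every contig — while only a fraction of the reads must be generated
and evaluated.

## The subsampling scheme

Regions of exactly $10 \times$ the average read length (or insert size, for
paired-end libraries) are sampled uniformly at random, without overlap, each
wholly inside one contig. Sampling stops once the cumulative sampled length
reaches a genome-size-dependent target:

| genome size $G$     | target                |
|---------------------|-----------------------|
| $G < 100$ Mb        | $0.50\,G$             |
| $100 \le G < 500$ Mb| $0.25\,G$             |
| $G \ge 500$ Mb      | $0.01\,G$             |

with a global floor of 15 Mb to keep the measurement robust for small
genomes. Because all regions share one length $L$, the total lands in
$[\mathrm{target}, \mathrm{target} + L)$. The sampled regions are
concatenated into an *artificial chromosome*, separated by runs of
$2 \times$ the read unit of `N`, so no simulated read can straddle two
regions. Reads are simulated from the artificial chromosome; their
coordinates are lifted back to the reference through the region map, and the
mappers are run against the **full** reference.

### Why not rejection sampling

The obvious sampler — draw a uniform start, reject on overlap — is a random
sequential adsorption process that jams at a packing density of about 74.8%
for long segments. The 15 Mb floor on a 20 Mb genome requires 75%, so a
rejection sampler cannot reliably meet the scheme's own floor and stalls
pathologically as it approaches the jam. We instead draw an exact uniform
sample over *all* non-overlapping placements with the order-statistics
spacing construction: to place $m$ regions of length $L$ in a gap of width
$w$, draw $m$ values uniformly on $\{0, \dots, w - mL\}$, sort them, and add
$(j-1)L$ to the $j$-th. This is feasible at any density up to 100%,
vectorises, and is seed-reproducible. Region counts per contig (or per
remaining gap, when N-rich candidates are redrawn) are allocated uniformly
over capacity slots.

Candidate regions with more than 10% `N` are discarded and replaced —
reads simulated from `N` runs are meaningless — and contigs shorter than one
region are excluded. A genome too N-rich to reach the target fails loudly
rather than silently under-sampling. Genomes smaller than the 15 Mb floor
cap the target at their own length (with a warning); the tier scheme is
simply silent about that regime.

## The simulation model

The artificial chromosome is first mutated: per-base SNPs at `snp_rate`
(alternate allele uniform over the other three bases), indels initiated
per-base at `indel_rate`, split insertion/deletion by `insertion_fraction`
(default 0.5), lengths uniform on 1–`max_indel_length` (default 10 bp).
Overlapping events are resolved greedily left-to-right, `N` positions are
never mutated, and the mutation map records every event plus an exact
monotone lift-over from mutated to original coordinates (inserted bases map
to their anchor; deleted bases have no image, so a read starting inside a
deletion inherits the nearest preceding original position).

Reads are drawn from uniformly random starts inside the mutated region
images, strand uniform; paired-end mode emits FR-oriented mates with insert
length $\sim \mathcal{N}(\mu, \sigma)$ truncated to at least $2 \times$ the
read length. Sequencing errors are uniform per-base substitutions at
`error_rate`, and base qualities are the constant matching Phred score
$-10\log_{10}(\text{error rate})$, capped at 41 (41 when the rate is 0).
The model is deliberately haploid and platform-agnostic: there is no
quality-by-cycle profile, no homopolymer error mode, no PCR duplicates, no
structural variants. Platform-specific data (e.g. Ion-Torrent-like) is
emulated by raising `error_rate`; exactly modelled reads from external
simulators enter through the gold-standard import path (FASTQ + SAM), which
takes the contig, 1-based leftmost position and strand flag of each gold
record as the truth.

Defaults (100 bp reads, SNP 0.1%, indel 0.03%, error 0.6%, coverage
$1\times$ of the sampled regions) mirror a standard human-resequencing
Illumina scenario. Coverage is exposed rather than fixed because the read
count per sampled base is a free choice; $1\times$ keeps run times
proportional to the sampled length.

Truth is carried twice: authoritatively in a sidecar TSV
(`read_id, mate, contig, pos0, strand`; 0-based on disk) and as a
convenience mirror in the read names
(`sim:<serial>|<contig>|<pos1-based>|<F/R>|<mate>`). Evaluation always uses
the sidecar, so contig ids containing the delimiter cannot corrupt results.

## Execution harness

Mappers are declared as shell command templates with `{reference}`,
`{fastq1}`, `{fastq2}`, `{params}`, `{output}` placeholders. The index
command (if any) runs first and is excluded from the mapping wall time,
which is measured around the map command alone — so reported throughput
extrapolates to larger read sets. Peak memory is the maximum resident set of
the mapper's process tree, polled every 50 ms; this is a portable lower
bound on the true peak. Parameter grids expand to every cartesian
combination, in input order, each with a readable label.

Two built-in mappers make the whole pipeline testable without external
binaries: a k-mer **baseline** mapper (candidates from exact first-k-mer
matches on both strands, verified by full-read Hamming distance; mapq 60
when uniquely best, 0 on ties, ties broken leftmost; default
$k = \min(17, \text{read length})$) and an **oracle** mapper that emits
every read at its truth position — downstream evaluation of an oracle run
must yield 100% correct, which pins the whole evaluation chain.

## Evaluation

Only primary alignments count (secondary 0x100 and supplementary 0x800
records are dropped). A mapped read with mapping quality below the
threshold (default 0, which excludes nothing) is counted as **not mapped**.
A read passing the threshold is **correct** iff it is on the truth contig
and strand and its reported leftmost position is within
$X = \lfloor 0.5 \times \text{read length} \rfloor$ bp of the truth,
inclusive; otherwise it is **wrong**. "Within" is read inclusively; the
boundary is covered by tests either way. The threshold comparison is
`mapq >= threshold`, so the default 0 is a no-op. With $C + W + N$ always
equal to the truth count, the six summary statistics are

* $P = C/(C+W)$ — precision, the fraction of mapped reads that are correct;
* $R = C/(C+N)$ — recall *as defined by the scheme*: the denominator
  excludes wrongly mapped reads, so $R \ge C/\text{total}$ whenever $W > 0$.
  The conventional $C/\text{total}$ is reported alongside as
  `recall_conventional`, not silently substituted;
* $F = 2PR/(P+R)$ — F-measure, 0 when $P + R = 0$ (all 0/0 ratios define
  to 0);
* correctly mapped reads per second (mapping wall time only);
* percent mapped, which replaces accuracy for genuine reads, whose true
  positions are unknown — there the denominator is the FASTQ read count,
  so reads the mapper dropped entirely still count as unmapped;
* mapping wall time and peak memory.

Paired-end mates are classified independently against per-mate truth; no
proper-pair requirement is imposed, since the rules are per-read. For
variable-length real reads, $X$ uses the configured read length, not
per-read lengths. Evaluation is by position/strand distance, not CIGAR
overlap — fast, and standard for mapper benchmarking.

## Reporting

`render_report()` writes a TSV and JSON (canonical, numbers to 5
significant digits in both) and a self-contained HTML page with an inline
SVG accuracy-vs-throughput scatter. Quadrants are drawn through a declared
baseline setting: `N++` beats the baseline on both axes, `N+-` trades speed
for accuracy, `N-+` the reverse, `N--` loses on both. A `+` requires a
*strictly* greater value; ties are `-`, so `N++` settings are always
preferable to the baseline. `A` marks the highest-accuracy and `S` the
highest-throughput setting, ties broken by parameter label
lexicographically. Rendering is deterministic — no timestamps — so
re-rendering identical inputs is byte-identical.

## Coordinate conventions

Internally everything is 1-based, closed intervals — the R/Bioconductor
convention — with conversions confined to file boundaries: SAM is natively
1-based; the truth sidecar (`pos0`) and the region-map TSV are written
0-based (half-open for regions) as documented in their headers. Keeping a
single in-memory convention avoids off-by-one drift; the inclusive tolerance
boundary and the padding/region offsets are pinned by exhaustive round-trip
tests on toy genomes.

## What the tests do and do not show

The test suite runs the pipeline end to end on synthetic random genomes:
sampling-tier totals at 20/60/120 Mb, exhaustive zero-noise identity
(every simulated read is an exact substring of the reference at its truth
position), binomial 3-sigma recovery of SNP/indel/error rates at $10^6$
bases, oracle perfection, equivalence of the classifier with a brute-force
transcription of the rules over an exhaustive offset/strand/mapq grid, and
monotonicity of the mapped count in the mapq threshold. Problem sizes are
chosen so the full suite runs in about a minute of CPU: i.i.d. genomes of
20–120 Mb for the tiers and 20 kb–300 kb toys elsewhere.

Random i.i.d. genomes have no repeat structure, so the baseline mapper's
task is easier there than on real genomes; passing tests validate the
*bookkeeping* (coordinates, truth, classification, counting) and the
simulator's statistical calibration, not any claim about how real mappers
rank on real data. That ranking is exactly what the tool exists to measure
per dataset, with external mappers declared as adapters.

## Known limitations

* The simulator's error model is uniform; systematic platform artifacts
  (homopolymer indels, quality decay along the read) must come through the
  gold-standard import path.
* Peak memory via polling underestimates short-lived spikes.
* The baseline mapper requires an exact first-k-mer match; highly mutated
  reads can lose their seed and go unmapped. It is a pipeline reference
  point, not a competitive aligner.
* Real-data mode can only report mapped percentages; mapping more reads is
  not proof of mapping them better, and the report says which axis it used.
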