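# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# a small genome from explicit sequences
toy_genome <- function(...) {
  genome(c(...))
}

# sampled regions + artificial chromosome + zero-noise (or noisy) reads on a
# synthetic genome, small enough for exhaustive checks
toy_simulation <- function(genome_bp = 1e5, n_contigs = 2, read_length = 50,
                           min_total = 2e4, coverage = 1,
                           snp_rate = 0, indel_rate = 0, error_rate = 0,
                           paired = FALSE, seed = 101) {
  g <- generate_synthetic_genome(genome_bp, n_contigs, 0.5, seed = seed)
  cfg <- sampling_config(
    read_length = read_length,
    insert_size = if (paired) 3L * read_length else NULL,
    min_total = min_total, seed = seed + 1L
  )
  regions <- sample_regions(g, cfg)
  art <- build_artificial_chromosome(g, regions, cfg)
  profile <- simulation_profile(
    read_length = read_length, snp_rate = snp_rate, indel_rate = indel_rate,
    error_rate = error_rate, coverage = coverage, paired = paired,
    insert_mean = if (paired) 3 * read_length else NULL,
    seed = seed + 2L
  )
  sim <- simulate_reads(art$record, art$region_map, profile)
  list(genome = g, config = cfg, regions = regions, art = art,
       profile = profile, reads = sim$reads, truth = sim$truth)
}

sum_regions <- function(regions) {
  sum(regions$end - regions$start + 1)
}

write_sam_tmp <- function(lines) {
  f <- tempfile(fileext = ".sam")
  writeLines(lines, f)
  f
}

# minimal hand-written SAM with one @SQ contig
sam_fixture <- function(records, contig = "chr1", len = 10000) {
  write_sam_tmp(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", contig, len),
    records
  ))
}

# independent transcription of the classification rules, used as the
# oracle for classify_read
brute_classify <- function(mapped, mapq, contig_match, strand_match,
                           offset, x, threshold) {
  if (!mapped) return("not_mapped")
  if (mapq < threshold) return("not_mapped")
  if (contig_match && strand_match && abs(offset) <= x) "correct" else "wrong"
}
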