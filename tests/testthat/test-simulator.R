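# independent reconstruction of a mutated sequence from the event list,
# used as the oracle for mutate_sequence
rebuild_from_events <- function(original, events) {
  chars <- strsplit(original, "")[[1]]
  out <- character(0)
  i <- 1L
  ev <- events[order(events$pos), , drop = FALSE]
  k <- 1L
  while (i <= length(chars)) {
    if (k <= nrow(ev) && ev$pos[k] == i) {
      e <- ev[k, ]
      if (e$kind == "SNP") {
        out <- c(out, e$alt)
        i <- i + 1L
      } else if (e$kind == "deletion") {
        i <- i + nchar(e$ref)
      } else {  # insertion: anchor base first, inserted bases after it
        out <- c(out, chars[i], strsplit(e$alt, "")[[1]])
        i <- i + 1L
      }
      k <- k + 1L
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

test_that("zero rates leave the sequence untouched", {
  prof <- simulation_profile(read_length = 50, snp_rate = 0, indel_rate = 0,
                             error_rate = 0, seed = 1)
  s <- generate_synthetic_genome(1000, 1, 0.5, seed = 2)$records[[1]]
  mut <- mutate_sequence(s, prof)
  expect_identical(mut$sequence, s)
  expect_equal(nrow(mut$map$events), 0)
  expect_identical(mut$map$origin, seq_len(1000L))
})

test_that("SNP counts recover the configured rate (binomial 3-sigma)", {
  n <- 1e6
  s <- generate_synthetic_genome(n, 1, 0.5, seed = 3)$records[[1]]
  prof <- simulation_profile(read_length = 50, snp_rate = 0.01,
                             indel_rate = 0, error_rate = 0, seed = 4)
  mut <- mutate_sequence(s, prof)
  n_snp <- sum(mut$map$events$kind == "SNP")
  expect_lt(abs(n_snp - n * 0.01), 3 * sqrt(n * 0.01 * 0.99))
  # a SNP's alternate allele always differs from its reference
  ev <- mut$map$events
  expect_true(all(ev$ref[ev$kind == "SNP"] != ev$alt[ev$kind == "SNP"]))
})

test_that("mutation events and lift-over are exact on a toy sequence", {
  s <- generate_synthetic_genome(1000, 1, 0.5, seed = 5)$records[[1]]
  prof <- simulation_profile(read_length = 10, snp_rate = 0.02,
                             indel_rate = 0.01, error_rate = 0, seed = 6)
  mut <- mutate_sequence(s, prof)
  ev <- mut$map$events
  expect_gt(nrow(ev), 0)
  # recorded reference alleles match the original sequence
  for (j in which(ev$kind != "insertion")) {
    expect_identical(
      substr(s, ev$pos[j], ev$pos[j] + nchar(ev$ref[j]) - 1), ev$ref[j]
    )
  }
  # the event list reconstructs the mutated sequence exactly
  expect_identical(rebuild_from_events(s, ev), mut$sequence)
  # lift-over is monotone and maps unmutated bases to identical bases
  org <- mut$map$origin
  expect_true(all(diff(org) >= 0))
  mut_chars <- strsplit(mut$sequence, "")[[1]]
  orig_chars <- strsplit(s, "")[[1]]
  touched <- unique(c(ev$pos[ev$kind == "SNP"],
                      rep(ev$pos[ev$kind == "insertion"], 2)))
  clean <- !(org %in% touched) & !duplicated(org)
  expect_identical(mut_chars[clean], orig_chars[org[clean]])
  # N positions are never mutated
  s_n <- paste0(substr(s, 1, 500), strrep("N", 100), substr(s, 601, 1000))
  mut_n <- mutate_sequence(s_n, prof, seed = 7)
  expect_false(any(mut_n$map$events$pos %in% 501:600))
})

test_that("read count follows coverage of the sampled length", {
  prof <- simulation_profile(read_length = 150, coverage = 1)
  expect_equal(determine_read_count(36e6, prof), 240000L)
  prof2 <- simulation_profile(read_length = 100, coverage = 0.5)
  expect_equal(determine_read_count(1e6, prof2), 5000L)
  # paired counts are decremented to even
  prof3 <- simulation_profile(read_length = 100, coverage = 1, paired = TRUE)
  expect_equal(determine_read_count(100100, prof3), 1000L)
  expect_error(determine_read_count(50, prof),
               class = "mapbench_config_error")
})

test_that("zero-noise reads are exact reference substrings (exhaustive)", {
  sim <- toy_simulation(genome_bp = 1e5, read_length = 50, seed = 201)
  expect_equal(nrow(sim$truth),
               determine_read_count(sum(sim$regions$end - sim$regions$start + 1),
                                    sim$profile))
  rd <- sim$reads$sequence
  rev <- sim$truth$strand == "R"
  rd[rev] <- mapbench:::revcomp(rd[rev])
  ref <- unname(substring(sim$genome$records[sim$truth$contig],
                          sim$truth$pos, sim$truth$pos + 49))
  expect_identical(rd, ref)
  # zero error rate gives the maximum quality, Phred 41
  expect_true(all(sim$reads$quality == strrep(rawToChar(as.raw(33 + 41)), 50)))
})

test_that("sequencing errors hit at the configured rate with matching quality", {
  sim <- toy_simulation(genome_bp = 2e5, read_length = 100, min_total = 1e5,
                        coverage = 10, error_rate = 0.01, seed = 301)
  # Phred 20 quality string
  expect_true(all(sim$reads$quality == strrep("5", 100)))
  rd <- sim$reads$sequence
  rev <- sim$truth$strand == "R"
  rd[rev] <- mapbench:::revcomp(rd[rev])
  ref <- unname(substring(sim$genome$records[sim$truth$contig],
                          sim$truth$pos, sim$truth$pos + 99))
  mism <- sum(charToRaw(paste(rd, collapse = "")) !=
                charToRaw(paste(ref, collapse = "")))
  total <- 100L * length(rd)
  expect_gt(total, 1e6 - 1)
  expect_lt(abs(mism / total - 0.01), 3 * sqrt(0.01 * 0.99 / total))
})

test_that("paired reads are FR-oriented with both mates truth-tracked", {
  sim <- toy_simulation(genome_bp = 1e5, read_length = 50, paired = TRUE,
                        coverage = 1, seed = 401)
  expect_equal(nrow(sim$truth) %% 2, 0)
  expect_setequal(unique(sim$truth$mate), c(1L, 2L))
  n_pairs <- nrow(sim$truth) / 2
  t1 <- sim$truth[sim$truth$mate == 1L, ]
  t2 <- sim$truth[sim$truth$mate == 2L, ]
  # mates of a pair sit on opposite strands
  expect_true(all(t1$strand != t2$strand))
  # zero noise: every mate is an exact (reverse-complemented) substring
  rd <- sim$reads$sequence
  rev <- sim$truth$strand == "R"
  rd[rev] <- mapbench:::revcomp(rd[rev])
  ref <- unname(substring(sim$genome$records[sim$truth$contig],
                          sim$truth$pos, sim$truth$pos + 49))
  expect_identical(rd, ref)
})

test_that("read names encode and decode the truth", {
  expect_identical(
    decode_truth_name("sim:17|chr2|1001|R|1"),
    list(serial = 17L, contig = "chr2", pos = 1001, strand = "R", mate = 1L)
  )
  expect_null(decode_truth_name("SRR000001.5"))
  expect_null(decode_truth_name("sim:1|a|b|F|1"))
  # encode -> decode round trip on simulated truths
  sim <- toy_simulation(genome_bp = 5e4, read_length = 50, min_total = 1e4,
                        seed = 501)
  for (i in sample.int(nrow(sim$truth), 20)) {
    d <- decode_truth_name(sim$truth$read_id[i])
    expect_identical(d$contig, sim$truth$contig[i])
    expect_equal(d$pos, sim$truth$pos[i])
    expect_identical(d$strand, sim$truth$strand[i])
  }
})

test_that("truth sidecar TSV agrees with the name encoding", {
  sim <- toy_simulation(genome_bp = 5e4, read_length = 50, min_total = 1e4,
                        seed = 601)
  f <- tempfile(fileext = ".tsv")
  write_truth(sim$truth, f)
  back <- read_truth(f)
  expect_equal(back$pos, sim$truth$pos)
  expect_identical(back$contig, sim$truth$contig)
  # on disk the position column is 0-based
  raw <- utils::read.table(f, sep = "\t", header = TRUE)
  expect_equal(raw$pos0, sim$truth$pos - 1)
  d <- decode_truth_name(back$read_id[1])
  expect_equal(d$pos, back$pos[1])
})

test_that("gold-standard import builds truth from SAM positions and strands", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c(
    "@r1", "ACGTACGT", "+", "IIIIIIII",
    "@r2", "ACGTACGT", "+", "IIIIIIII",
    "@r3", "ACGTACGT", "+", "IIIIIIII"
  ), fq)
  sam <- sam_fixture(c(
    "r1\t0\tchr1\t1001\t60\t8M\t*\t0\t0\tACGTACGT\tIIIIIIII",
    "r2\t16\tchr1\t51\t60\t8M\t*\t0\t0\tACGTACGT\tIIIIIIII",
    "r3\t0\tchr1\t5\t60\t8M\t*\t0\t0\tACGTACGT\tIIIIIIII"
  ))
  truth <- import_gold_standard(fq, sam)
  expect_equal(nrow(truth), 3)
  expect_equal(truth$pos[truth$read_id == "r1"], 1001)
  expect_identical(truth$strand[truth$read_id == "r2"], "R")
  # and 0-based on disk
  f <- tempfile(fileext = ".tsv")
  write_truth(truth, f)
  raw <- utils::read.table(f, sep = "\t", header = TRUE)
  expect_equal(raw$pos0[raw$read_id == "r1"], 1000)

  # a FASTQ read missing from the gold SAM is an import error naming it
  writeLines(c("@r9", "ACGTACGT", "+", "IIIIIIII"), fq)
  expect_error(import_gold_standard(fq, sam), "r9",
               class = "mapbench_import_error")
  # unmapped gold records are rejected
  sam_u <- sam_fixture("r9\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGT\tIIIIIIII")
  expect_error(import_gold_standard(fq, sam_u),
               class = "mapbench_import_error")
})

test_that("FASTQ subsampling is uniform, verbatim, and pair-preserving", {
  sim <- toy_simulation(genome_bp = 5e4, read_length = 50, min_total = 1e4,
                        seed = 701)
  fq <- write_fastq(sim$reads, tempfile())
  out <- tempfile(fileext = ".fastq")
  subsample_reads(fq, 100, out, seed = 702)
  expect_equal(nrow(read_fastq(out)), 100)
  # sampled records appear verbatim in the input
  expect_true(all(readLines(out) %in% readLines(fq)))
  # determinism
  out2 <- tempfile(fileext = ".fastq")
  subsample_reads(fq, 100, out2, seed = 702)
  expect_identical(readLines(out), readLines(out2))
  # n larger than the file passes everything through
  out3 <- tempfile(fileext = ".fastq")
  subsample_reads(fq, 1e6, out3, seed = 703)
  expect_identical(readLines(out3), readLines(fq))
  # paired: both mates of every sampled pair present
  simp <- toy_simulation(genome_bp = 1e5, read_length = 50, paired = TRUE,
                         seed = 704)
  fqp <- write_fastq(simp$reads, tempfile())
  outp <- c(tempfile(fileext = "_1.fastq"), tempfile(fileext = "_2.fastq"))
  subsample_reads(fqp, 100, outp, seed = 705)
  r1 <- read_fastq(outp[1])
  r2 <- read_fastq(outp[2])
  expect_equal(nrow(r1), 50)
  s1 <- vapply(r1$id, function(x) decode_truth_name(x)$serial, integer(1))
  s2 <- vapply(r2$id, function(x) decode_truth_name(x)$serial, integer(1))
  expect_identical(unname(s1), unname(s2))
})
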