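test_that("expand_grid builds the cartesian product in input order", {
  sets <- expand_grid(list("-L" = c(20, 22), "-D" = c(15, 20, 25)))
  expect_length(sets, 6)
  expect_identical(sets[[1]]$label, "-L=20,-D=15")
  expect_identical(sets[[1]]$args, "-L 20 -D 15")
  # last parameter varies fastest
  expect_identical(sets[[2]]$label, "-L=20,-D=20")
  expect_identical(sets[[4]]$label, "-L=22,-D=15")

  expect_length(expand_grid(list()), 1)
  expect_identical(expand_grid(list())[[1]]$label, "default")

  ord <- expand_grid(list("-R" = c(1, 2, 3)))
  expect_identical(vapply(ord, `[[`, character(1), "label"),
                   c("-R=1", "-R=2", "-R=3"))

  expect_error(expand_grid(list("-L" = numeric(0))),
               class = "mapbench_config_error")
})

test_that("grid size is the product of value-list lengths (property)", {
  set.seed(77)
  for (rep in 1:10) {
    np <- sample(1:4, 1)
    grid <- stats::setNames(
      lapply(seq_len(np), function(i) sample(100, sample(1:5, 1))),
      paste0("-p", seq_len(np))
    )
    sets <- expand_grid(grid)
    expect_length(sets, prod(lengths(grid)))
    expect_false(anyDuplicated(vapply(sets, `[[`, character(1),
                                      "label")) > 0)
  }
})

test_that("the bundled parameter-optimization config expands to 34 settings", {
  cfg <- read_run_config(
    system.file("extdata", "bowtie2_grid.yaml", package = "mapbench")
  )
  sets <- cfg$mappers[[1]]$parameter_sets
  expect_length(sets, 34)
  labels <- vapply(sets, `[[`, character(1), "label")
  expect_true(all(c("default", "very-sensitive-local") %in% labels))
  expect_equal(sum(grepl("^-L=", labels)), 25)
})

test_that("adapters validate their command templates", {
  expect_error(mapper_adapter("x", "mapper {reference} {output}"),
               class = "mapbench_config_error")
  a <- mapper_adapter("x", "mapper {reference} {fastq1} {output}")
  expect_s3_class(a, "MapperAdapter")
})

test_that("run_mapper times the map command only and records resources", {
  # stub mapper: a shell script that copies a precomputed SAM
  sim <- toy_simulation(genome_bp = 2e4, read_length = 50, min_total = 5e3,
                        seed = 801)
  sam_lines <- oracle_map(sim$truth, sim$reads, sim$genome)
  precomputed <- write_sam_tmp(sam_lines)
  ref <- tempfile(fileext = ".fa")
  write_fasta(sim$genome, ref)
  fq <- write_fastq(sim$reads, tempfile())

  stub <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", sprintf("cp %s \"$3\"", shQuote(precomputed))),
             stub)
  Sys.chmod(stub, "0755")
  adapter <- mapper_adapter(
    "stub", sprintf("%s {reference} {fastq1} {output}", shQuote(stub)),
    # artificially slow index step: must not count towards mapping time
    index_command = "sleep 2 && true > /dev/null # {reference}"
  )
  rec <- run_mapper(adapter, parameter_set("default"), ref, fq)
  expect_equal(rec$exit_status, 0L)
  expect_gt(rec$mapping_wall_time, 0)
  expect_lt(rec$mapping_wall_time, 1.5)
  obs <- load_alignments(rec$alignment_path)
  expect_equal(nrow(obs), nrow(sim$reads))

  # missing executable is a configuration error naming it
  bad <- mapper_adapter("gone", "no_such_mapper_xyz {reference} {fastq1} {output}")
  expect_error(run_mapper(bad, parameter_set("default"), ref, fq),
               "no_such_mapper_xyz", class = "mapbench_config_error")

  # nonzero exit is recorded and surfaced
  failing <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "exit 3"), failing)
  Sys.chmod(failing, "0755")
  fa <- mapper_adapter("fail",
                       sprintf("%s {reference} {fastq1} {output}",
                               shQuote(failing)))
  expect_warning(rec2 <- run_mapper(fa, parameter_set("default"), ref, fq),
                 "status 3")
  expect_equal(rec2$exit_status, 3L)
  expect_true(is.na(rec2$alignment_path))
})

test_that("run_mapper drives the built-in baseline end to end", {
  sim <- toy_simulation(genome_bp = 2e4, read_length = 50, min_total = 5e3,
                        seed = 811)
  ref <- tempfile(fileext = ".fa")
  write_fasta(sim$genome, ref)
  fq <- write_fastq(sim$reads, tempfile())
  rec <- run_mapper(builtin_adapter(k = 17), parameter_set("default"),
                    ref, fq)
  expect_equal(rec$exit_status, 0L)
  expect_gt(rec$mapping_wall_time, 0)
  expect_gt(rec$peak_memory, 0)
  res <- evaluate_run(rec$alignment_path, sim$truth,
                      eval_config(read_length = 50),
                      mapping_wall_time = rec$mapping_wall_time)
  expect_equal(res$accuracy, 1)
})

# exhaustive all-positions Hamming scan: the oracle for baseline_map
brute_force_map <- function(read, genome) {
  best <- NULL
  rl <- nchar(read)
  rc <- mapbench:::revcomp(read)
  for (ci in seq_along(genome$records)) {
    s <- genome$records[[ci]]
    for (pos in seq_len(nchar(s) - rl + 1)) {
      ref <- charToRaw(substr(s, pos, pos + rl - 1))
      for (rev in c(FALSE, TRUE)) {
        d <- sum(ref != charToRaw(if (rev) rc else read))
        cand <- list(contig = ci, pos = pos, rev = rev, d = d)
        if (is.null(best) || d < best$d) {
          best <- cand
          best$ties <- 1L
        } else if (d == best$d) {
          best$ties <- best$ties + 1L
        }
      }
    }
  }
  best
}

test_that("baseline mapper agrees with an exhaustive Hamming scan", {
  g <- generate_synthetic_genome(5000, 2, 0.5, seed = 821)
  set.seed(822)
  # reads at random positions, some with substitution noise
  n <- 25
  reads <- data.frame(id = paste0("r", 1:n), sequence = "", quality = "",
                      mate = 0L, stringsAsFactors = FALSE)
  for (i in 1:n) {
    ci <- sample(2, 1)
    pos <- sample(nchar(g$records[[ci]]) - 49, 1)
    s <- substr(g$records[[ci]], pos, pos + 49)
    if (i %% 3 == 0) {  # two substitutions
      ch <- strsplit(s, "")[[1]]
      at <- sample(50, 2)
      ch[at] <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
      s <- paste(ch, collapse = "")
    }
    if (i %% 2 == 0) s <- mapbench:::revcomp(s)
    reads$sequence[i] <- s
    reads$quality[i] <- strrep("I", 50)
  }
  sam <- baseline_map(reads, g, k = 17)
  f <- write_sam_tmp(sam)
  obs <- load_alignments(f)
  for (i in 1:n) {
    o <- obs[obs$read_id == reads$id[i], ]
    if (!o$is_mapped) next  # noisy first k-mer can kill the seed; allowed
    bf <- brute_force_map(reads$sequence[i], g)
    # the k-mer mapper can only ever reach the brute-force optimum
    ref <- charToRaw(substr(g$records[[o$contig]], o$pos, o$pos + 49))
    qry <- charToRaw(if (o$strand == "R") mapbench:::revcomp(reads$sequence[i])
                     else reads$sequence[i])
    expect_gte(sum(ref != qry), bf$d)
    # with an intact seed it finds exactly the optimum
    if (sum(ref != qry) == bf$d && bf$ties == 1L) {
      expect_equal(o$pos, bf$pos)
      expect_identical(o$contig, names(g$records)[bf$contig])
      expect_identical(o$strand, if (bf$rev) "R" else "F")
    }
  }
  # clean reads (exact substrings) must all hit their true optimum
  clean <- which(1:n %% 3 != 0)
  hit <- obs$read_id %in% reads$id[clean]
  expect_true(all(obs$is_mapped[hit]))
})

test_that("baseline mapper flags unmappable and ambiguous reads", {
  # genome without any A: a poly-A read cannot seed anywhere
  set.seed(831)
  s <- paste(sample(c("C", "G", "T"), 3000, replace = TRUE), collapse = "")
  g <- genome(c(c1 = s))
  reads <- data.frame(id = "lost", sequence = strrep("A", 50),
                      quality = strrep("I", 50), mate = 0L,
                      stringsAsFactors = FALSE)
  obs <- load_alignments(write_sam_tmp(baseline_map(reads, g, k = 17)))
  expect_false(obs$is_mapped)

  # a sequence duplicated verbatim at two loci maps with quality 0,
  # tie broken to the leftmost coordinate
  seg <- substr(s, 1, 200)
  g2 <- genome(c(c1 = paste0(seg, strrep("ACGT", 200), seg)))
  reads2 <- data.frame(id = "dup", sequence = substr(seg, 50, 149),
                       quality = strrep("I", 100), mate = 0L,
                       stringsAsFactors = FALSE)
  obs2 <- load_alignments(write_sam_tmp(baseline_map(reads2, g2, k = 17)))
  expect_true(obs2$is_mapped)
  expect_equal(obs2$mapq, 0)
  expect_equal(obs2$pos, 50)
})

test_that("oracle mapper reproduces the truth exactly", {
  sim <- toy_simulation(genome_bp = 5e4, read_length = 50, min_total = 1e4,
                        seed = 841)
  obs <- load_alignments(
    write_sam_tmp(oracle_map(sim$truth, sim$reads, sim$genome))
  )
  res <- evaluate_run(obs, sim$truth, eval_config(read_length = 50))
  expect_equal(res$correct, nrow(sim$truth))
  expect_equal(res$wrong + res$not_mapped, 0)

  # paired data keeps mate flags consistent with truth mates
  simp <- toy_simulation(genome_bp = 1e5, read_length = 50, paired = TRUE,
                         seed = 842)
  obsp <- load_alignments(
    write_sam_tmp(oracle_map(simp$truth, simp$reads, simp$genome))
  )
  expect_setequal(unique(obsp$mate), c(1L, 2L))
  resp <- evaluate_run(obsp, simp$truth, eval_config(read_length = 50))
  expect_equal(resp$accuracy, 1)

  # truth missing a read errors and names it
  short_truth <- truth_table(sim$truth[-1, ])
  expect_error(oracle_map(short_truth, sim$reads, sim$genome),
               sim$truth$read_id[1], fixed = TRUE)
})
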