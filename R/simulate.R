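#' Read-simulation profile
#'
#' Mutation and sequencing-error model for the built-in simulator. SNPs are
#' independent per-base substitutions; indels are initiated per base with
#' `indel_rate`, split between insertions and deletions by
#' `insertion_fraction`, with lengths uniform on `[1, max_indel_length]`.
#' Sequencing errors are uniform substitutions applied to the read after
#' sampling. Defaults mirror a human-resequencing Illumina scenario:
#' 100 bp reads, 0.1% SNPs, 0.03% indels, 0.6% sequencing error, 1x coverage
#' of the sampled regions.
#'
#' @param read_length read length in bp.
#' @param snp_rate per-base SNP probability.
#' @param indel_rate per-base indel initiation probability.
#' @param insertion_fraction proportion of indels that are insertions.
#' @param max_indel_length maximum indel length in bp.
#' @param error_rate per-base sequencing error probability.
#' @param paired simulate paired-end reads?
#' @param insert_mean,insert_sd insert-size distribution (paired only);
#'   `insert_mean` must be at least `2 * read_length`.
#' @param coverage fold coverage of the sampled regions.
#' @param seed integer seed.
#' @return an object of class `SimulationProfile`.
#' @export
simulation_profile <- function(read_length = 100L,
                               snp_rate = 0.001,
                               indel_rate = 0.0003,
                               insertion_fraction = 0.5,
                               max_indel_length = 10L,
                               error_rate = 0.006,
                               paired = FALSE,
                               insert_mean = NULL,
                               insert_sd = 50,
                               coverage = 1,
                               seed = NULL) {
  if (!is_count(read_length)) stop_config("read_length must be >= 1")
  for (r in list(snp_rate, indel_rate, insertion_fraction, error_rate)) {
    if (!is_proportion(r)) stop_config("rates must be in [0, 1]")
  }
  if (!is_count(max_indel_length)) stop_config("max_indel_length must be >= 1")
  if (coverage <= 0) stop_config("coverage must be positive")
  if (paired) {
    if (is.null(insert_mean)) insert_mean <- 3 * read_length
    if (insert_mean < 2 * read_length) {
      stop_config("insert_mean must be at least 2 * read_length")
    }
  }
  structure(list(
    read_length = as.integer(read_length),
    snp_rate = snp_rate,
    indel_rate = indel_rate,
    insertion_fraction = insertion_fraction,
    max_indel_length = as.integer(max_indel_length),
    error_rate = error_rate,
    paired = paired,
    insert_mean = if (paired) insert_mean else NULL,
    insert_sd = if (paired) insert_sd else NULL,
    coverage = coverage,
    seed = seed
  ), class = "SimulationProfile")
}

#' Apply a SNP/indel model to a sequence
#'
#' Every non-N base is independently substituted with probability `snp_rate`
#' (alternate allele uniform over the other three bases). Indel events start
#' at a base with probability `indel_rate`; overlapping events are resolved
#' greedily left to right; deletions never extend past the sequence end or
#' into N runs. N positions are never mutated. The returned map records every
#' event and an exact monotone lift-over from mutated to original
#' coordinates (inserted bases map to their anchor base; deleted bases have
#' no image).
#'
#' @param sequence character scalar over `{A,C,G,T,N}`.
#' @param profile a [simulation_profile()].
#' @param seed optional integer seed (defaults to the profile seed).
#' @return list with `sequence` (mutated string) and `map` (class
#'   `MutationMap`: list with `events` data.frame
#'   (`pos`, `kind`, `ref`, `alt`; `pos` 1-based on the original) and
#'   `origin`, an integer vector giving the original position of every
#'   mutated-sequence base).
#' @export
mutate_sequence <- function(sequence, profile, seed = profile$seed) {
  stopifnot(inherits(profile, "SimulationProfile"))
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop_config("sequence must be a non-empty character scalar")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  informative <- chars %in% DNA_BASES
  with_seed(seed, {
    snp_pos <- which(stats::runif(n) < profile$snp_rate & informative)
    indel_pos <- which(stats::runif(n) < profile$indel_rate & informative)
    k <- length(indel_pos)
    indel_is_ins <- stats::runif(k) < profile$insertion_fraction
    indel_len <- sample.int(profile$max_indel_length, k, replace = TRUE)

    # deletions must stay inside the sequence and inside informative runs
    if (k > 0L) {
      ok <- rep(TRUE, k)
      del <- which(!indel_is_ins)
      for (j in del) {
        e <- indel_pos[j] + indel_len[j] - 1L
        if (e > n || !all(informative[indel_pos[j]:e])) ok[j] <- FALSE
      }
      indel_pos <- indel_pos[ok]
      indel_is_ins <- indel_is_ins[ok]
      indel_len <- indel_len[ok]
      k <- length(indel_pos)
    }

    # greedy left-to-right overlap resolution; an insertion occupies its
    # anchor base, a deletion its whole span
    if (k > 1L) {
      o <- order(indel_pos)
      indel_pos <- indel_pos[o]
      indel_is_ins <- indel_is_ins[o]
      indel_len <- indel_len[o]
      keep <- logical(k)
      last_end <- 0L
      for (j in seq_len(k)) {
        if (indel_pos[j] > last_end) {
          keep[j] <- TRUE
          last_end <- if (indel_is_ins[j]) indel_pos[j] else
            indel_pos[j] + indel_len[j] - 1L
        }
      }
      indel_pos <- indel_pos[keep]
      indel_is_ins <- indel_is_ins[keep]
      indel_len <- indel_len[keep]
      k <- length(indel_pos)
    }

    del_pos <- indel_pos[!indel_is_ins]
    del_len <- indel_len[!indel_is_ins]
    ins_pos <- indel_pos[indel_is_ins]
    ins_len <- indel_len[indel_is_ins]

    # drop SNPs falling inside deletion spans or on insertion anchors,
    # so the event list is strictly non-overlapping
    if (length(del_pos) > 0L && length(snp_pos) > 0L) {
      j <- findInterval(snp_pos, del_pos)
      inside <- j >= 1L & snp_pos <= del_pos[pmax(j, 1L)] + del_len[pmax(j, 1L)] - 1L
      snp_pos <- snp_pos[!inside]
    }
    if (length(ins_pos) > 0L && length(snp_pos) > 0L) {
      snp_pos <- setdiff(snp_pos, ins_pos)
    }

    out <- chars
    snp_alt <- character(0L)
    if (length(snp_pos) > 0L) {
      b <- match(chars[snp_pos], DNA_BASES)
      pick <- sample.int(3L, length(snp_pos), replace = TRUE)
      snp_alt <- ALT_BASES[cbind(b, pick)]
      out[snp_pos] <- snp_alt
    }

    keep_mask <- rep(TRUE, n)
    del_ref <- character(length(del_pos))
    for (j in seq_along(del_pos)) {
      span <- del_pos[j]:(del_pos[j] + del_len[j] - 1L)
      keep_mask[span] <- FALSE
      del_ref[j] <- paste(chars[span], collapse = "")
    }

    ins_bases <- character(0L)
    ins_anchor <- integer(0L)
    ins_offset <- integer(0L)
    ins_alt <- character(length(ins_pos))
    if (length(ins_pos) > 0L) {
      total_ins <- sum(ins_len)
      drawn <- DNA_BASES[sample.int(4L, total_ins, replace = TRUE)]
      ends <- cumsum(ins_len)
      starts <- ends - ins_len + 1L
      ins_alt <- vapply(seq_along(ins_pos), function(j) {
        paste(drawn[starts[j]:ends[j]], collapse = "")
      }, character(1L))
      ins_bases <- drawn
      ins_anchor <- rep(ins_pos, ins_len)
      ins_offset <- sequence(ins_len)
    }

    kept_pos <- which(keep_mask)
    key_pos <- c(kept_pos, ins_anchor)
    key_tie <- c(rep(0L, length(kept_pos)), ins_offset)
    ord <- order(key_pos, key_tie)
    origin <- key_pos[ord]
    mutated <- paste(c(out[kept_pos], ins_bases)[ord], collapse = "")

    events <- rbind(
      if (length(snp_pos) > 0L) data.frame(
        pos = snp_pos, kind = "SNP", ref = chars[snp_pos], alt = snp_alt,
        stringsAsFactors = FALSE
      ),
      if (length(del_pos) > 0L) data.frame(
        pos = del_pos, kind = "deletion", ref = del_ref, alt = "",
        stringsAsFactors = FALSE
      ),
      if (length(ins_pos) > 0L) data.frame(
        pos = ins_pos, kind = "insertion", ref = "", alt = ins_alt,
        stringsAsFactors = FALSE
      )
    )
    if (is.null(events)) {
      events <- data.frame(pos = integer(), kind = character(),
                           ref = character(), alt = character(),
                           stringsAsFactors = FALSE)
    } else {
      events <- events[order(events$pos), , drop = FALSE]
      rownames(events) <- NULL
    }
    map <- structure(list(events = events, origin = origin),
                     class = "MutationMap")
    list(sequence = mutated, map = map)
  })
}

#' Number of reads to simulate
#'
#' `round(coverage * sampled_length / read_length)`, decremented to an even
#' count in paired mode.
#'
#' @param sampled_length total sampled region length in bp.
#' @param profile a [simulation_profile()].
#' @return read count.
#' @export
determine_read_count <- function(sampled_length, profile) {
  stopifnot(inherits(profile, "SimulationProfile"))
  if (sampled_length < profile$read_length) {
    stop_config("sampled length is shorter than one read")
  }
  count <- round(profile$coverage * sampled_length / profile$read_length)
  if (profile$paired && count %% 2 == 1) count <- count - 1
  as.integer(count)
}

phred_char <- function(error_rate) {
  q <- if (error_rate <= 0) 41L else
    min(41L, as.integer(round(-10 * log10(error_rate))))
  rawToChar(as.raw(33L + q))
}

# uniform substitution errors over a vector of equal-length reads
apply_sequencing_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  rl <- nchar(seqs[1L])
  all <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  hit <- which(stats::runif(length(all)) < error_rate & all %in% DNA_BASES)
  if (length(hit) > 0L) {
    b <- match(all[hit], DNA_BASES)
    pick <- sample.int(3L, length(hit), replace = TRUE)
    all[hit] <- ALT_BASES[cbind(b, pick)]
  }
  m <- matrix(all, nrow = rl)
  do.call(paste0, lapply(seq_len(rl), function(i) m[i, ]))
}

encode_truth_name <- function(serial, contig, pos, strand, mate) {
  sprintf("sim:%d|%s|%.0f|%s|%d", serial, contig, pos, strand, mate)
}

#' Decode a simulated read name
#'
#' Read names follow the grammar `sim:<serial>|<contig>|<pos1-based>|<F/R>|<mate>`
#' as a convenience mirror of the truth sidecar (which stays authoritative —
#' contig ids containing the delimiter cannot corrupt evaluation). Non-
#' matching ids return `NULL` rather than erroring.
#'
#' @param read_id read name.
#' @return list with `serial`, `contig`, `pos` (1-based leftmost reference
#'   position), `strand` (`"F"`/`"R"`) and `mate` (0 = single-end), or
#'   `NULL` if the id does not match the grammar.
#' @export
decode_truth_name <- function(read_id) {
  m <- regexec("^sim:([0-9]+)\\|([^|]+)\\|([0-9]+)\\|([FR])\\|([0-9]+)$",
               read_id)
  g <- regmatches(read_id, m)[[1L]]
  if (length(g) == 0L) return(NULL)
  list(
    serial = as.integer(g[2L]),
    contig = g[3L],
    pos = as.numeric(g[4L]),
    strand = g[5L],
    mate = as.integer(g[6L])
  )
}

#' Simulate truth-tracked reads from the artificial chromosome
#'
#' The artificial chromosome is first mutated under the profile's SNP/indel
#' model; reads are then drawn from uniformly random starts inside the
#' (mutated images of the) sampled regions, on a uniform strand, with
#' per-base substitution errors at `error_rate` and constant base qualities
#' at the matching Phred score (capped at 41). Because the N padding is at
#' least twice the read unit, no read can span two regions; starts are drawn
#' only from positions whose whole span stays inside one region. The true
#' position of a read is the reference lift-over of its leftmost base
#' (leftmost for both strands, matching SAM POS).
#'
#' @param artificial list `id`/`sequence` from
#'   [build_artificial_chromosome()].
#' @param region_map the matching `RegionMap`.
#' @param profile a [simulation_profile()].
#' @param seed optional integer seed (defaults to the profile seed).
#' @return list with `reads` (data.frame `id`, `sequence`, `quality`,
#'   `mate`; mate 0 for single-end) and `truth` (class `TruthTable`:
#'   data.frame `read_id`, `mate`, `contig`, `pos` (1-based), `strand`).
#' @export
simulate_reads <- function(artificial, region_map, profile,
                           seed = profile$seed) {
  stopifnot(inherits(region_map, "RegionMap"),
            inherits(profile, "SimulationProfile"))
  rl <- profile$read_length
  pad <- attr(region_map, "pad_length")
  if (pad < 2 * rl) {
    stop_config("padding must be at least twice the read length")
  }
  with_seed(seed, {
    mut <- mutate_sequence(artificial$sequence, profile, seed = NULL)
    origin <- mut$map$origin

    # mutated-coordinate images of the regions (origin is monotone)
    widths <- region_map$end - region_map$start + 1
    a_start <- region_map$artificial_offset
    a_end <- a_start + widths - 1
    ms <- findInterval(a_start - 1, origin) + 1L
    me <- findInterval(a_end, origin)

    sampled_length <- sum(widths)
    n_reads <- determine_read_count(sampled_length, profile)

    if (profile$paired) {
      sim <- simulate_paired(mut, ms, me, region_map, profile, n_reads)
    } else {
      sim <- simulate_single(mut, ms, me, region_map, profile, n_reads)
    }
    sim
  })
}

# shared: lift mutated-coordinate leftmost positions to reference
lift_mut_to_ref <- function(origin, region_map, mut_pos) {
  lift_to_reference(region_map, origin[mut_pos])
}

simulate_single <- function(mut, ms, me, region_map, profile, n_reads) {
  rl <- profile$read_length
  navail <- pmax(0L, me - ms + 1L - rl + 1L)
  if (sum(navail) == 0L) {
    stop_config("read length exceeds every sampled region")
  }
  reg <- sample.int(length(navail), n_reads, replace = TRUE,
                    prob = navail / sum(navail))
  start <- ms[reg] +
    floor(stats::runif(n_reads) * navail[reg])
  seqs <- substring(mut$sequence, start, start + rl - 1L)
  rev <- stats::runif(n_reads) < 0.5
  if (any(rev)) seqs[rev] <- revcomp(seqs[rev])
  seqs <- apply_sequencing_errors(seqs, profile$error_rate)
  ref <- lift_mut_to_ref(mut$map$origin, region_map, start)
  strand <- ifelse(rev, "R", "F")
  ids <- encode_truth_name(seq_len(n_reads), ref$contig, ref$position,
                           strand, 0L)
  qual <- strrep(phred_char(profile$error_rate), rl)
  reads <- data.frame(
    id = ids, sequence = seqs, quality = qual, mate = 0L,
    stringsAsFactors = FALSE
  )
  truth <- truth_table(data.frame(
    read_id = ids, mate = 0L, contig = ref$contig, pos = ref$position,
    strand = strand, stringsAsFactors = FALSE
  ))
  list(reads = reads, truth = truth)
}

simulate_paired <- function(mut, ms, me, region_map, profile, n_reads) {
  rl <- profile$read_length
  n_pairs <- n_reads %/% 2L
  widths <- me - ms + 1L
  max_w <- max(widths)
  ins <- round(stats::rnorm(n_pairs, profile$insert_mean, profile$insert_sd))
  ins <- pmax(ins, 2L * rl)
  ins <- pmin(ins, max_w)
  if (any(2L * rl > max_w)) {
    stop_config("insert size exceeds every sampled region")
  }
  reg <- integer(n_pairs)
  frag <- integer(n_pairs)
  for (p in seq_len(n_pairs)) {
    avail <- pmax(0L, widths - ins[p] + 1L)
    reg[p] <- sample.int(length(avail), 1L, prob = avail / sum(avail))
    frag[p] <- ms[reg[p]] + floor(stats::runif(1L) * avail[reg[p]])
  }
  left_start <- frag
  right_start <- frag + ins - rl
  left_seq <- substring(mut$sequence, left_start, left_start + rl - 1L)
  right_seq <- revcomp(substring(mut$sequence, right_start,
                                 right_start + rl - 1L))
  # FR orientation; which mate is the left/forward read is random
  mate1_left <- stats::runif(n_pairs) < 0.5
  m1_start <- ifelse(mate1_left, left_start, right_start)
  m2_start <- ifelse(mate1_left, right_start, left_start)
  m1_seq <- ifelse(mate1_left, left_seq, right_seq)
  m2_seq <- ifelse(mate1_left, right_seq, left_seq)
  m1_strand <- ifelse(mate1_left, "F", "R")
  m2_strand <- ifelse(mate1_left, "R", "F")
  all_seq <- apply_sequencing_errors(c(m1_seq, m2_seq), profile$error_rate)
  m1_seq <- all_seq[seq_len(n_pairs)]
  m2_seq <- all_seq[n_pairs + seq_len(n_pairs)]
  ref1 <- lift_mut_to_ref(mut$map$origin, region_map, m1_start)
  ref2 <- lift_mut_to_ref(mut$map$origin, region_map, m2_start)
  serial <- seq_len(n_pairs)
  id1 <- encode_truth_name(serial, ref1$contig, ref1$position, m1_strand, 1L)
  id2 <- encode_truth_name(serial, ref2$contig, ref2$position, m2_strand, 2L)
  qual <- strrep(phred_char(profile$error_rate), rl)
  reads <- data.frame(
    id = c(id1, id2), sequence = c(m1_seq, m2_seq), quality = qual,
    mate = rep(c(1L, 2L), each = n_pairs),
    stringsAsFactors = FALSE
  )
  truth <- truth_table(data.frame(
    read_id = c(id1, id2), mate = rep(c(1L, 2L), each = n_pairs),
    contig = c(ref1$contig, ref2$contig),
    pos = c(ref1$position, ref2$position),
    strand = c(m1_strand, m2_strand),
    stringsAsFactors = FALSE
  ))
  list(reads = reads, truth = truth)
}

#' Truth tables
#'
#' The gold standard for evaluation: one row per (read, mate) giving the
#' source contig, leftmost 1-based reference position and strand.
#'
#' @param df data.frame with columns `read_id`, `mate`, `contig`, `pos`,
#'   `strand`.
#' @return the data.frame with class `TruthTable`.
#' @export
truth_table <- function(df) {
  need <- c("read_id", "mate", "contig", "pos", "strand")
  if (!all(need %in% names(df))) {
    stop_config(sprintf("truth table needs columns: %s",
                        paste(need, collapse = ", ")))
  }
  if (anyDuplicated(df[c("read_id", "mate")])) {
    stop_config("duplicate (read_id, mate) in truth table")
  }
  rownames(df) <- NULL
  class(df) <- c("TruthTable", "data.frame")
  df
}

#' Write / read the truth sidecar TSV
#'
#' On-disk positions are 0-based (`pos0` column) per the sidecar contract;
#' in-memory truth tables are 1-based.
#' @param truth a `TruthTable`.
#' @param path TSV path.
#' @return `path` (write) or a `TruthTable` (read).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "TruthTable"))
  out <- data.frame(
    read_id = truth$read_id, mate = truth$mate, contig = truth$contig,
    pos0 = truth$pos - 1, strand = truth$strand,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  truth_table(data.frame(
    read_id = as.character(df$read_id), mate = df$mate,
    contig = as.character(df$contig), pos = df$pos0 + 1,
    strand = df$strand, stringsAsFactors = FALSE
  ))
}

# ---- FASTQ ----------------------------------------------------------------
# Minimal 4-line Sanger (Phred+33) FASTQ support. Subsampling must pass
# records through verbatim, so records are handled as raw line quadruples.

#' Read a 4-line FASTQ file
#'
#' Minimal Sanger (Phred+33) FASTQ reader; ids are truncated at the first
#' whitespace.
#' @param path FASTQ path.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop_format(sprintf("%s: FASTQ line count not a multiple of 4", path))
  }
  n <- length(lines) %/% 4L
  i <- seq_len(n)
  hdr <- lines[4L * i - 3L]
  plus <- lines[4L * i - 1L]
  if (any(substr(hdr, 1L, 1L) != "@") || any(substr(plus, 1L, 1L) != "+")) {
    stop_format(sprintf("%s: malformed FASTQ record", path))
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  data.frame(
    id = ids, sequence = lines[4L * i - 2L], quality = lines[4L * i],
    stringsAsFactors = FALSE
  )
}

write_fastq_file <- function(reads, path) {
  lines <- as.vector(rbind(
    paste0("@", reads$id), reads$sequence, "+", reads$quality
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' Single-end reads go to `<prefix>.fastq`; paired reads to
#' `<prefix>_1.fastq` / `<prefix>_2.fastq`.
#'
#' @param reads the `reads` data.frame from [simulate_reads()].
#' @param prefix output path prefix.
#' @return character vector of the file(s) written.
#' @export
write_fastq <- function(reads, prefix) {
  if (all(reads$mate == 0L)) {
    path <- paste0(prefix, ".fastq")
    write_fastq_file(reads, path)
    path
  } else {
    p1 <- paste0(prefix, "_1.fastq")
    p2 <- paste0(prefix, "_2.fastq")
    write_fastq_file(reads[reads$mate == 1L, , drop = FALSE], p1)
    write_fastq_file(reads[reads$mate == 2L, , drop = FALSE], p2)
    c(p1, p2)
  }
}

#' Import an external gold standard
#'
#' Accepts user-simulated reads (FASTQ) plus a SAM file giving their
#' presumably correct alignment positions and strands, e.g. produced by an
#' external read simulator. Every FASTQ read id must appear mapped in the
#' gold SAM.
#'
#' @param fastq_paths character vector of FASTQ path(s).
#' @param gold_sam path to the gold-standard SAM.
#' @return a `TruthTable`.
#' @export
import_gold_standard <- function(fastq_paths, gold_sam) {
  ids <- unlist(lapply(fastq_paths, function(p) read_fastq(p)$id))
  obs <- load_alignments(gold_sam)
  unmapped <- obs$read_id[!obs$is_mapped]
  if (length(unmapped) > 0L) {
    stop_import(sprintf(
      "gold standard contains unmapped record(s): %s",
      paste(utils::head(unique(unmapped), 5L), collapse = ", ")
    ))
  }
  missing <- setdiff(ids, obs$read_id)
  if (length(missing) > 0L) {
    stop_import(sprintf(
      "read(s) in FASTQ but not in gold SAM: %s",
      paste(utils::head(missing, 5L), collapse = ", ")
    ))
  }
  keep <- obs$read_id %in% ids
  truth_table(data.frame(
    read_id = obs$read_id[keep], mate = obs$mate[keep],
    contig = obs$contig[keep], pos = obs$pos[keep],
    strand = obs$strand[keep], stringsAsFactors = FALSE
  ))
}

#' Uniformly subsample a FASTQ file
#'
#' Draws `min(n, available)` reads without replacement, preserving record
#' content verbatim and input order. In paired mode both files are sampled
#' with the same pair indices, so mates stay together.
#'
#' @param fastq_paths one (single-end) or two (paired) FASTQ paths.
#' @param n number of reads to keep (pairs count as two reads in paired
#'   mode).
#' @param out_paths output path(s), same length as `fastq_paths`.
#' @param seed integer seed.
#' @return `out_paths`, invisibly.
#' @export
subsample_reads <- function(fastq_paths, n, out_paths, seed = NULL) {
  if (!is_count(n)) stop_config("n must be >= 1")
  stopifnot(length(fastq_paths) %in% c(1L, 2L),
            length(out_paths) == length(fastq_paths))
  paired <- length(fastq_paths) == 2L
  reads <- lapply(fastq_paths, read_fastq)
  if (paired && nrow(reads[[1L]]) != nrow(reads[[2L]])) {
    stop_format("paired FASTQ files have different read counts")
  }
  units <- nrow(reads[[1L]])
  want <- if (paired) min(ceiling(n / 2), units) else min(n, units)
  idx <- with_seed(seed, sort(sample.int(units, want)))
  for (f in seq_along(reads)) {
    write_fastq_file(reads[[f]][idx, , drop = FALSE], out_paths[f])
  }
  invisible(out_paths)
}
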