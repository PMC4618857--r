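#' Evaluation configuration
#'
#' Controls read classification. A mapped read with mapping quality below
#' `mapq_threshold` counts as not mapped (the default 0 excludes nothing).
#' A passing read is correct iff it is on the truth contig and strand and
#' its reported leftmost position is within `X = floor(tolerance_fraction *
#' read_length)` bp of the truth position, inclusive; otherwise it is wrong.
#'
#' @param read_length the defined read length in bp (used for X even when
#'   real reads vary in length).
#' @param mapq_threshold non-negative integer (default 0).
#' @param tolerance_fraction proportion of the read length (default 0.5).
#' @param strip_chr compare contigs after stripping a leading `"chr"` from
#'   both sides (off by default).
#' @return an object of class `EvalConfig` with the derived tolerance `x`.
#' @export
eval_config <- function(read_length, mapq_threshold = 0L,
                        tolerance_fraction = 0.5, strip_chr = FALSE) {
  if (!is_count(read_length)) stop_config("read_length must be >= 1")
  if (!is.numeric(mapq_threshold) || mapq_threshold < 0) {
    stop_config("mapq_threshold must be >= 0")
  }
  if (!is_proportion(tolerance_fraction)) {
    stop_config("tolerance_fraction must be in [0, 1]")
  }
  structure(list(
    read_length = as.integer(read_length),
    mapq_threshold = as.integer(mapq_threshold),
    tolerance_fraction = tolerance_fraction,
    x = as.integer(floor(tolerance_fraction * read_length)),
    strip_chr = strip_chr
  ), class = "EvalConfig")
}

#' Load primary alignments from a SAM file
#'
#' Parses via Rsamtools after a light structural check (malformed alignment
#' lines are reported with their line number). Secondary (0x100) and
#' supplementary (0x800) records are dropped; only the primary alignment of
#' each (read, mate) is kept, and duplicates raise an error. 1-based SAM
#' POS is retained (package-internal convention is 1-based).
#'
#' @param sam_path path to a SAM file.
#' @return data.frame of class `AlignmentSet` with columns `read_id`,
#'   `mate` (0 = single-end), `is_mapped`, `contig`, `pos`, `strand`
#'   (`"F"`/`"R"`), `mapq`.
#' @export
load_alignments <- function(sam_path) {
  if (!file.exists(sam_path)) {
    stop_format(sprintf("SAM file not found: %s", sam_path))
  }
  lines <- readLines(sam_path, warn = FALSE)
  body <- !startsWith(lines, "@")
  nfields <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE)))
  bad <- which(body & nzchar(lines) & nfields < 10L)
  if (length(bad) > 0L) {
    stop_format(sprintf("malformed SAM line %d in %s", bad[1L], sam_path))
  }
  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq")
    )
  )[[1L]]
  flag <- res$flag
  keep <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  flag <- flag[keep]
  mate <- ifelse(bitwAnd(flag, 0x40L) != 0L, 1L,
                 ifelse(bitwAnd(flag, 0x80L) != 0L, 2L, 0L))
  obs <- data.frame(
    read_id = res$qname[keep],
    mate = mate,
    is_mapped = bitwAnd(flag, 0x4L) == 0L,
    contig = as.character(res$rname[keep]),
    pos = as.numeric(res$pos[keep]),
    strand = ifelse(bitwAnd(flag, 0x10L) != 0L, "R", "F"),
    mapq = ifelse(is.na(res$mapq[keep]), 0L, res$mapq[keep]),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(obs[c("read_id", "mate")])
  if (any(dup)) {
    stop_eval(sprintf(
      "duplicate primary alignment for read(s): %s",
      paste(utils::head(unique(obs$read_id[dup]), 5L), collapse = ", ")
    ))
  }
  class(obs) <- c("AlignmentSet", "data.frame")
  obs
}

contig_eq <- function(a, b, strip_chr) {
  if (strip_chr) {
    a <- sub("^chr", "", a)
    b <- sub("^chr", "", b)
  }
  !is.na(a) & a == b
}

#' Classify one read as correct, wrong, or not mapped
#'
#' Absent or unmapped observations, and mapped reads with `mapq <
#' mapq_threshold`, are not mapped. A passing read is correct iff the
#' contig matches, the strand matches, and the reported leftmost position
#' is within X bp (inclusive) of the truth; any violated condition makes
#' it wrong.
#'
#' @param obs one-row `AlignmentSet` slice (or `NULL` if the read is absent
#'   from the SAM).
#' @param truth one-row `TruthTable` slice.
#' @param config an [eval_config()].
#' @return `"correct"`, `"wrong"`, or `"not_mapped"`.
#' @export
classify_read <- function(obs, truth, config) {
  stopifnot(inherits(config, "EvalConfig"))
  if (is.null(obs) || nrow(obs) == 0L || !obs$is_mapped) return("not_mapped")
  if (obs$mapq < config$mapq_threshold) return("not_mapped")
  ok <- contig_eq(obs$contig, truth$contig, config$strip_chr) &&
    obs$strand == truth$strand &&
    abs(obs$pos - truth$pos) <= config$x
  if (ok) "correct" else "wrong"
}

#' Classify every truth read against an alignment set
#'
#' Vectorised counterpart of [classify_read()]: every truth entry gets a
#' classification; reads missing from the SAM are not mapped.
#'
#' @param obs an `AlignmentSet` from [load_alignments()].
#' @param truth a `TruthTable`.
#' @param config an [eval_config()].
#' @return character vector parallel to `truth` rows with values
#'   `correct`/`wrong`/`not_mapped`.
#' @export
classify_alignments <- function(obs, truth, config) {
  stopifnot(inherits(truth, "TruthTable"), inherits(config, "EvalConfig"))
  j <- match(paste(truth$read_id, truth$mate),
             paste(obs$read_id, obs$mate))
  mapped <- !is.na(j) & obs$is_mapped[pmax(j, 1L)] &
    obs$mapq[pmax(j, 1L)] >= config$mapq_threshold
  jj <- pmax(j, 1L)
  correct <- mapped &
    contig_eq(obs$contig[jj], truth$contig, config$strip_chr) &
    obs$strand[jj] == truth$strand &
    abs(obs$pos[jj] - truth$pos) <= config$x
  ifelse(!mapped, "not_mapped", ifelse(correct, "correct", "wrong"))
}

#' Tally classifications into C/W/N counts
#'
#' @param classifications character vector from [classify_alignments()].
#' @return object of class `EvalCounts`: list with `correct`, `wrong`,
#'   `not_mapped`, `total` (`C + W + N = total` always).
#' @export
aggregate_classifications <- function(classifications) {
  bad <- setdiff(unique(classifications),
                 c("correct", "wrong", "not_mapped"))
  if (length(bad) > 0L) {
    stop_eval(sprintf("unknown classification: %s",
                      paste(bad, collapse = ", ")))
  }
  structure(list(
    correct = sum(classifications == "correct"),
    wrong = sum(classifications == "wrong"),
    not_mapped = sum(classifications == "not_mapped"),
    total = length(classifications)
  ), class = "EvalCounts")
}

#' Summary statistics from C/W/N counts
#'
#' Precision `P = C / (C + W)` (fraction of mapped reads that are correct),
#' recall `R = C / (C + N)` (the denominator excludes wrongly mapped reads;
#' the conventional `C / total` is additionally reported as
#' `recall_conventional`), F-measure `2PR / (P + R)`, correctly mapped
#' reads per second, and the percentage of mapped reads. All 0/0 ratios
#' define to 0.
#'
#' @param counts an `EvalCounts`.
#' @param mapping_wall_time mapping time in seconds (`NA` leaves throughput
#'   `NA`).
#' @return object of class `Metrics`: list with `precision`, `recall`,
#'   `recall_conventional`, `f_measure`, `correct_per_second`,
#'   `percent_mapped`, plus the counts.
#' @export
compute_metrics <- function(counts, mapping_wall_time = NA_real_) {
  stopifnot(inherits(counts, "EvalCounts"))
  C <- counts$correct
  W <- counts$wrong
  N <- counts$not_mapped
  total <- counts$total
  P <- if (C + W > 0) C / (C + W) else 0
  R <- if (C + N > 0) C / (C + N) else 0
  f <- if (P + R > 0) 2 * P * R / (P + R) else 0
  cps <- if (!is.na(mapping_wall_time) && mapping_wall_time > 0) {
    C / mapping_wall_time
  } else NA_real_
  structure(list(
    correct = C, wrong = W, not_mapped = N, total = total,
    precision = P, recall = R,
    recall_conventional = if (total > 0) C / total else 0,
    f_measure = f,
    correct_per_second = cps,
    percent_mapped = if (total > 0) 100 * (C + W) / total else 0
  ), class = "Metrics")
}

#' Percentage of mapped reads (real-data mode)
#'
#' For genuine reads the true positions are unknown, so the criterion is
#' the overall percentage of mapped reads passing the mapq threshold.
#' Reads absent from the SAM count as unmapped: the denominator is the
#' FASTQ read count, not the SAM record count.
#'
#' @param obs an `AlignmentSet`.
#' @param total_reads number of reads given to the mapper.
#' @param config an [eval_config()].
#' @return percentage in `[0, 100]`.
#' @export
evaluate_real <- function(obs, total_reads, config) {
  stopifnot(inherits(config, "EvalConfig"))
  if (!is_count(total_reads)) stop_config("total_reads must be >= 1")
  mapped <- sum(obs$is_mapped & obs$mapq >= config$mapq_threshold)
  100 * mapped / total_reads
}

#' Evaluate one run end to end
#'
#' Loads (or reuses) the alignments, classifies every truth read, and
#' returns one result row combining counts, metrics and resources.
#'
#' @param sam SAM path or an `AlignmentSet`.
#' @param truth a `TruthTable`.
#' @param config an [eval_config()].
#' @param mapper,parameter_label identifiers for the run.
#' @param mapping_wall_time,peak_memory resources from the `RunRecord`.
#' @return one-row data.frame (a `BenchmarkResult` row; see
#'   [render_report()]).
#' @export
evaluate_run <- function(sam, truth, config,
                         mapper = "mapper", parameter_label = "default",
                         mapping_wall_time = NA_real_,
                         peak_memory = NA_real_) {
  obs <- if (is.character(sam)) load_alignments(sam) else sam
  cls <- classify_alignments(obs, truth, config)
  m <- compute_metrics(aggregate_classifications(cls), mapping_wall_time)
  data.frame(
    mapper = mapper, parameter_label = parameter_label,
    threshold = config$mapq_threshold,
    correct = m$correct, wrong = m$wrong, not_mapped = m$not_mapped,
    total = m$total,
    accuracy = if (m$total > 0) m$correct / m$total else 0,
    precision = m$precision, recall = m$recall,
    recall_conventional = m$recall_conventional,
    f_measure = m$f_measure,
    correct_per_second = m$correct_per_second,
    percent_mapped = m$percent_mapped,
    mapping_wall_time = mapping_wall_time,
    peak_memory = peak_memory,
    stringsAsFactors = FALSE
  )
}

#' Metrics across mapping-quality thresholds
#'
#' Re-classifies the same observations at each threshold. The mapped count
#' `C + W` (and `C` itself) is non-increasing in the threshold.
#'
#' @param obs an `AlignmentSet`.
#' @param truth a `TruthTable`.
#' @param config an [eval_config()] (its own threshold is ignored).
#' @param thresholds non-empty integer vector.
#' @return data.frame with one metrics row per threshold.
#' @export
threshold_sweep <- function(obs, truth, config, thresholds) {
  if (length(thresholds) == 0L) stop_config("thresholds must be non-empty")
  do.call(rbind, lapply(thresholds, function(t) {
    cfg <- eval_config(config$read_length, mapq_threshold = t,
                       tolerance_fraction = config$tolerance_fraction,
                       strip_chr = config$strip_chr)
    evaluate_run(obs, truth, cfg)
  }))
}
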