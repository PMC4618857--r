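#' Declare a mapper adapter
#'
#' An adapter wraps one external mapper behind two shell command templates.
#' `map_command` must contain the placeholders `{reference}`, `{fastq1}` and
#' `{output}`; `{fastq2}` (rendered empty for single-end) and `{params}` are
#' optional. `index_command` (placeholder `{reference}`), when present, is
#' executed before mapping and excluded from the mapping wall time.
#'
#' @param name mapper name.
#' @param map_command shell command template producing SAM at `{output}`.
#' @param index_command optional indexing command template.
#' @return an object of class `MapperAdapter`.
#' @export
mapper_adapter <- function(name, map_command, index_command = NULL) {
  need <- c("{reference}", "{fastq1}", "{output}")
  missing <- need[!vapply(need, grepl, logical(1L), x = map_command,
                          fixed = TRUE)]
  if (length(missing) > 0L) {
    stop_config(sprintf("map_command is missing placeholder(s): %s",
                        paste(missing, collapse = ", ")))
  }
  structure(list(
    name = name, map_command = map_command, index_command = index_command
  ), class = "MapperAdapter")
}

#' Built-in baseline mapper as an adapter
#'
#' Runs [baseline_map()] in a child R process through `Rscript`, so the
#' execution harness (timing, memory polling, exit status) is exercised the
#' same way as for external mappers.
#'
#' @param k seed k-mer length passed to [baseline_map()].
#' @return a `MapperAdapter`.
#' @export
builtin_adapter <- function(k = 17L) {
  rscript <- file.path(R.home("bin"), "Rscript")
  cmd <- sprintf(
    paste0("%s -e 'mapbench:::cli_baseline_map(commandArgs(TRUE))' ",
           "{reference} {fastq1} {output} %d {fastq2}"),
    shQuote(rscript), k
  )
  mapper_adapter("baseline", cmd)
}

# entry point for builtin_adapter; args: ref fq1 out k [fq2]
cli_baseline_map <- function(args) {
  genome <- read_fasta(args[1L])
  reads <- read_fastq(args[2L])
  reads$mate <- 0L
  if (length(args) >= 5L && nzchar(args[5L])) {
    r2 <- read_fastq(args[5L])
    reads$mate <- 1L
    r2$mate <- 2L
    reads <- rbind(reads, r2)
  }
  sam <- baseline_map(reads, genome, k = as.integer(args[4L]))
  writeLines(sam, args[3L])
  invisible(NULL)
}

#' Expand a parameter grid into parameter sets
#'
#' Builds the cartesian product of the value lists, in input order (the
#' first parameter varies slowest), labelling each combination. An empty
#' grid yields the single default (empty) parameter set.
#'
#' @param grid named list mapping a flag (e.g. `"-L"`) to a non-empty vector
#'   of values. Use `NA` as the value for a bare flag.
#' @return list of `ParameterSet` objects (list with `label`, `tokens`,
#'   `args`); `args` is the rendered command-line fragment.
#' @export
expand_grid <- function(grid = list()) {
  if (length(grid) == 0L) {
    return(list(parameter_set("default", list())))
  }
  if (is.null(names(grid)) || any(!nzchar(names(grid)))) {
    stop_config("grid must be a named list")
  }
  sizes <- lengths(grid)
  if (any(sizes == 0L)) {
    stop_config(sprintf(
      "empty value list for parameter(s): %s",
      paste(names(grid)[sizes == 0L], collapse = ", ")
    ))
  }
  # odometer with the last parameter fastest, so input order is preserved
  idx <- expand.grid(rev(lapply(sizes, seq_len)), KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(grid)), drop = FALSE]
  names(idx) <- names(grid)
  lapply(seq_len(nrow(idx)), function(r) {
    tokens <- stats::setNames(
      lapply(seq_along(grid), function(j) grid[[j]][[idx[r, j]]]),
      names(grid)
    )
    label <- paste(vapply(seq_along(tokens), function(j) {
      v <- tokens[[j]]
      if (is.na(v)) names(tokens)[j] else
        paste0(names(tokens)[j], "=", v)
    }, character(1L)), collapse = ",")
    parameter_set(label, tokens)
  })
}

#' @rdname expand_grid
#' @param label unique label for the combination.
#' @param tokens named list of flag values (`NA` = bare flag).
#' @export
parameter_set <- function(label, tokens = list()) {
  args <- paste(vapply(seq_along(tokens), function(j) {
    v <- tokens[[j]]
    if (is.na(v)) names(tokens)[j] else paste(names(tokens)[j], v)
  }, character(1L)), collapse = " ")
  structure(list(label = label, tokens = tokens, args = args),
            class = "ParameterSet")
}

# ---- process-tree resource monitoring -------------------------------------

proc_tree <- function(root_pid) {
  pids <- suppressWarnings(
    as.integer(list.files("/proc", pattern = "^[0-9]+$"))
  )
  ppid <- vapply(pids, function(p) {
    stat <- tryCatch(readLines(file.path("/proc", p, "stat"), warn = FALSE),
                     error = function(e) character(0L))
    if (length(stat) == 0L) return(NA_integer_)
    rest <- sub(".*\\) ", "", stat[1L])
    as.integer(strsplit(rest, " ", fixed = TRUE)[[1L]][2L])
  }, integer(1L))
  keep <- root_pid
  repeat {
    more <- pids[!is.na(ppid) & ppid %in% keep & !(pids %in% keep)]
    if (length(more) == 0L) break
    keep <- c(keep, more)
  }
  keep
}

tree_rss_bytes <- function(root_pid) {
  pids <- proc_tree(root_pid)
  page <- 4096
  sum(vapply(pids, function(p) {
    statm <- tryCatch(readLines(file.path("/proc", p, "statm"), warn = FALSE),
                      error = function(e) character(0L))
    if (length(statm) == 0L) return(0)
    as.numeric(strsplit(statm[1L], " ", fixed = TRUE)[[1L]][2L]) * page
  }, numeric(1L)))
}

# Run a shell command, measuring wall time and polling the process tree's
# resident set every `poll` seconds. Peak memory is a lower bound on the
# true peak (short-lived spikes between polls are missed).
run_timed <- function(cmd, timeout = NULL, poll = 0.05) {
  pidf <- tempfile("pid")
  stf <- tempfile("status")
  logf <- tempfile("log")
  wrapped <- sprintf(
    "echo $$ > %s; { %s ; } > %s 2>&1; echo $? > %s",
    shQuote(pidf), cmd, shQuote(logf), shQuote(stf)
  )
  t0 <- proc.time()[["elapsed"]]
  system2("sh", c("-c", shQuote(wrapped)), wait = FALSE)
  peak <- 0
  pid <- NA_integer_
  timed_out <- FALSE
  repeat {
    done <- file.exists(stf) && length(readLines(stf, warn = FALSE)) > 0L
    if (done) break
    if (is.na(pid) && file.exists(pidf)) {
      p <- readLines(pidf, warn = FALSE)
      if (length(p) > 0L) pid <- as.integer(p[1L])
    }
    if (!is.na(pid)) {
      peak <- max(peak, tree_rss_bytes(pid))
    }
    if (!is.null(timeout) &&
        proc.time()[["elapsed"]] - t0 > timeout) {
      if (!is.na(pid)) {
        suppressWarnings(system2(
          "kill", c("-9", as.character(proc_tree(pid))),
          stdout = FALSE, stderr = FALSE
        ))
      }
      timed_out <- TRUE
      break
    }
    Sys.sleep(poll)
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  status <- if (timed_out) NA_integer_ else
    as.integer(readLines(stf, warn = FALSE)[1L])
  list(
    wall_time = elapsed, peak_memory = peak, exit_status = status,
    timed_out = timed_out,
    log = if (file.exists(logf)) readLines(logf, warn = FALSE) else character()
  )
}

render_command <- function(template, reference, fastq1, fastq2, params,
                           output) {
  out <- template
  subst <- c(
    "{reference}" = shQuote(reference),
    "{fastq1}" = shQuote(fastq1),
    "{fastq2}" = if (is.null(fastq2)) "" else shQuote(fastq2),
    "{params}" = params %||% "",
    "{output}" = shQuote(output)
  )
  for (k in names(subst)) out <- gsub(k, subst[[k]], out, fixed = TRUE)
  out
}

#' Execute one mapper run
#'
#' Renders and runs the adapter's commands with shell-safe quoting. The
#' index command (if any) runs first and is excluded from the mapping wall
#' time, which is measured around the map command only, together with the
#' peak resident set of the mapper's process tree (50 ms polling).
#'
#' @param adapter a [mapper_adapter()].
#' @param params a `ParameterSet` (default: empty set).
#' @param reference FASTA path.
#' @param fastq1,fastq2 read file path(s); `fastq2 = NULL` for single-end.
#' @param output SAM output path (default: tempfile).
#' @param timeout optional wall-time limit in seconds for the map command;
#'   exceeding it marks the run failed.
#' @return an object of class `RunRecord`: list with `mapper`,
#'   `parameter_label`, `alignment_path`, `mapping_wall_time` (seconds),
#'   `peak_memory` (bytes), `exit_status`, `timed_out`, `log`.
#' @export
run_mapper <- function(adapter, params = parameter_set("default"),
                       reference, fastq1, fastq2 = NULL,
                       output = tempfile(fileext = ".sam"),
                       timeout = NULL) {
  stopifnot(inherits(adapter, "MapperAdapter"),
            inherits(params, "ParameterSet"))
  for (p in c(reference, fastq1, fastq2)) {
    if (!file.exists(p)) stop_config(sprintf("input not found: %s", p))
  }
  exe <- strsplit(trimws(adapter$map_command), "[[:space:]]")[[1L]][1L]
  exe <- gsub("^'+|'+$", "", exe)
  if (!grepl("/", exe) && Sys.which(exe) == "") {
    stop_config(sprintf("mapper executable not found on PATH: %s", exe))
  }
  if (!is.null(adapter$index_command)) {
    idx_cmd <- render_command(adapter$index_command, reference, fastq1,
                              fastq2, params$args, output)
    idx_status <- system(idx_cmd, ignore.stdout = TRUE, ignore.stderr = TRUE)
    if (idx_status != 0L) {
      stop_config(sprintf("index command failed (exit %d): %s",
                          idx_status, idx_cmd))
    }
  }
  cmd <- render_command(adapter$map_command, reference, fastq1, fastq2,
                        params$args, output)
  res <- run_timed(cmd, timeout = timeout)
  ok <- identical(res$exit_status, 0L) && file.exists(output)
  if (!ok && !res$timed_out) {
    warning(sprintf(
      "mapper %s (%s) exited with status %s",
      adapter$name, params$label, res$exit_status
    ), call. = FALSE)
  }
  structure(list(
    mapper = adapter$name,
    parameter_label = params$label,
    alignment_path = if (ok) output else NA_character_,
    mapping_wall_time = res$wall_time,
    peak_memory = res$peak_memory,
    exit_status = res$exit_status,
    timed_out = res$timed_out,
    log = res$log
  ), class = "RunRecord")
}

# ---- SAM emission ---------------------------------------------------------

sam_header <- function(genome) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%.0f", names(genome$records),
            contig_lengths(genome)))
}

sam_flag <- function(mapped, reverse, mate) {
  flag <- ifelse(mapped, 0L, 4L) + ifelse(mapped & reverse, 16L, 0L)
  flag + ifelse(mate == 1L, 1L + 64L, ifelse(mate == 2L, 1L + 128L, 0L))
}

sam_record <- function(id, flag, rname, pos, mapq, cigar, seq, qual) {
  sprintf("%s\t%d\t%s\t%.0f\t%d\t%s\t*\t0\t0\t%s\t%s",
          id, flag, rname, pos, mapq, cigar, seq, qual)
}

#' Built-in k-mer baseline mapper
#'
#' A deliberately simple seed-and-verify mapper used as the self-contained
#' reference point of the harness: candidate placements come from exact
#' matches of the read's first k-mer (forward, and of its reverse
#' complement), each candidate is verified by Hamming distance over the full
#' read, and the lowest-distance placement wins — mapping quality 60 when
#' uniquely best, 0 on a tie (ties broken towards the leftmost coordinate),
#' unmapped when no seed hits.
#'
#' @param reads data.frame `id`, `sequence`, `quality`, `mate` (as produced
#'   by [simulate_reads()] or [read_fastq()] plus a `mate` column).
#' @param genome a `Genome`.
#' @param k seed length; default `min(17, read length)`.
#' @return character vector of SAM lines (header included).
#' @export
baseline_map <- function(reads, genome, k = NULL) {
  stopifnot(inherits(genome, "Genome"))
  if (is.null(reads$mate)) reads$mate <- 0L
  rl_min <- min(nchar(reads$sequence))
  if (is.null(k)) k <- min(17L, rl_min)
  if (k > rl_min) stop_config("k exceeds the shortest read length")

  contigs <- names(genome$records)
  lens <- contig_lengths(genome)
  kmer_contig <- integer(0L)
  kmer_pos <- integer(0L)
  kmer_seq <- character(0L)
  for (ci in seq_along(contigs)) {
    s <- genome$records[[ci]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmer_seq <- c(kmer_seq, substring(s, starts, starts + k - 1L))
    kmer_pos <- c(kmer_pos, starts)
    kmer_contig <- c(kmer_contig, rep(ci, length(starts)))
  }
  buckets <- split(seq_along(kmer_seq), kmer_seq)
  bucket_names <- names(buckets)

  n <- nrow(reads)
  out <- character(n)
  fwd_k <- substr(reads$sequence, 1L, k)
  rc_all <- revcomp(reads$sequence)
  rc_k <- substr(rc_all, 1L, k)
  # one vectorised hash lookup for all reads, not one match() per read
  jf <- match(fwd_k, bucket_names)
  jr <- match(rc_k, bucket_names)
  raw_fwd <- lapply(reads$sequence, charToRaw)
  raw_rc <- lapply(rc_all, charToRaw)

  for (i in seq_len(n)) {
    rl <- nchar(reads$sequence[i])
    cand_f <- if (is.na(jf[i])) integer(0L) else buckets[[jf[i]]]
    cand_r <- if (is.na(jr[i])) integer(0L) else buckets[[jr[i]]]
    cand <- data.frame(
      contig = c(kmer_contig[cand_f], kmer_contig[cand_r]),
      pos = c(kmer_pos[cand_f], kmer_pos[cand_r]),
      rev = rep(c(FALSE, TRUE), c(length(cand_f), length(cand_r)))
    )
    cand <- cand[cand$pos + rl - 1L <= lens[cand$contig], , drop = FALSE]
    if (nrow(cand) == 0L) {
      out[i] <- sam_record(reads$id[i],
                           sam_flag(FALSE, FALSE, reads$mate[i]),
                           "*", 0, 0L, "*",
                           reads$sequence[i], reads$quality[i])
      next
    }
    dist <- vapply(seq_len(nrow(cand)), function(j) {
      ref <- charToRaw(substr(genome$records[[cand$contig[j]]],
                              cand$pos[j], cand$pos[j] + rl - 1L))
      qry <- if (cand$rev[j]) raw_rc[[i]] else raw_fwd[[i]]
      sum(ref != qry)
    }, numeric(1L))
    best <- min(dist)
    hits <- which(dist == best)
    mapq <- if (length(hits) == 1L) 60L else 0L
    pick <- hits[order(cand$contig[hits], cand$pos[hits], cand$rev[hits])][1L]
    revd <- cand$rev[pick]
    seq_out <- if (revd) rc_all[i] else reads$sequence[i]
    qual_out <- if (revd) paste(rev(strsplit(reads$quality[i], "",
                                             fixed = TRUE)[[1L]]),
                                collapse = "") else reads$quality[i]
    out[i] <- sam_record(reads$id[i],
                         sam_flag(TRUE, revd, reads$mate[i]),
                         contigs[cand$contig[pick]], cand$pos[pick], mapq,
                         sprintf("%dM", rl), seq_out, qual_out)
  }
  c(sam_header(genome), out)
}

#' Oracle mapper
#'
#' A test double that emits every read at exactly its truth position and
#' strand with mapping quality 60, so downstream evaluation must classify
#' 100% of reads correct.
#'
#' @param truth a `TruthTable` covering every read.
#' @param reads data.frame `id`, `sequence`, `quality`, `mate`.
#' @param genome a `Genome` (for the SAM header).
#' @return character vector of SAM lines (header included).
#' @export
oracle_map <- function(truth, reads, genome) {
  stopifnot(inherits(truth, "TruthTable"), inherits(genome, "Genome"))
  if (is.null(reads$mate)) reads$mate <- 0L
  key_r <- paste(reads$id, reads$mate)
  key_t <- paste(truth$read_id, truth$mate)
  j <- match(key_r, key_t)
  if (anyNA(j)) {
    stop_eval(sprintf(
      "no truth entry for read(s): %s",
      paste(utils::head(reads$id[is.na(j)], 5L), collapse = ", ")
    ))
  }
  revd <- truth$strand[j] == "R"
  seq_out <- ifelse(revd, revcomp(reads$sequence), reads$sequence)
  recs <- sam_record(
    reads$id, sam_flag(TRUE, revd, reads$mate),
    truth$contig[j], truth$pos[j], 60L,
    sprintf("%dM", nchar(reads$sequence)), seq_out, reads$quality
  )
  c(sam_header(genome), recs)
}

#' Write SAM lines to a file
#' @param sam character vector of SAM lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, path) {
  writeLines(sam, path)
  invisible(path)
}
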