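#' Region-sampling configuration
#'
#' Controls how regions are subsampled from the reference and concatenated
#' into the artificial chromosome. Defaults follow the benchmarking scheme:
#' region length is `region_factor` (10) times the average read length (or
#' insert size for paired-end libraries), regions are separated by
#' `pad_factor` (2) times that unit of N padding, and sampling stops once the
#' cumulative sampled length reaches a genome-size-dependent target: 50% of
#' the genome below 100 Mb, 25% below 500 Mb, 1% above, with a global floor
#' of `min_total` (15 Mb).
#'
#' @param read_length average read length in bp.
#' @param insert_size outer insert size in bp for paired-end data, or `NULL`
#'   for single-end. When given, it replaces the read length as the unit for
#'   region length and padding.
#' @param region_factor region length multiplier (default 10).
#' @param pad_factor N-padding multiplier (default 2).
#' @param tier_table two-column matrix-like list `(upper_bound_bp, fraction)`
#'   with strictly increasing bounds applied as strict "less than".
#' @param min_total sampling floor in bp (default 15e6).
#' @param max_n_fraction candidate regions with more than this fraction of N
#'   are rejected and replaced (default 0.1).
#' @param seed integer seed driving region placement.
#' @return an object of class `SamplingConfig`.
#' @export
sampling_config <- function(read_length,
                            insert_size = NULL,
                            region_factor = 10,
                            pad_factor = 2,
                            tier_table = default_tier_table(),
                            min_total = 15e6,
                            max_n_fraction = 0.1,
                            seed = NULL) {
  if (!is_count(read_length)) stop_config("read_length must be >= 1")
  if (!is.null(insert_size) && !is_count(insert_size)) {
    stop_config("insert_size must be >= 1 or NULL")
  }
  if (region_factor < 1 || pad_factor < 1) {
    stop_config("region_factor and pad_factor must be >= 1")
  }
  if (!is.data.frame(tier_table) ||
      !all(c("upper_bound", "fraction") %in% names(tier_table))) {
    stop_config("tier_table needs columns upper_bound and fraction")
  }
  if (any(diff(tier_table$upper_bound) <= 0)) {
    stop_config("tier bounds must be strictly increasing")
  }
  if (any(tier_table$fraction <= 0 | tier_table$fraction > 1)) {
    stop_config("tier fractions must be in (0, 1]")
  }
  if (!is_proportion(max_n_fraction)) {
    stop_config("max_n_fraction must be in [0, 1]")
  }
  unit <- if (is.null(insert_size)) read_length else insert_size
  structure(list(
    read_length = as.integer(read_length),
    insert_size = if (is.null(insert_size)) NULL else as.integer(insert_size),
    unit_length = as.integer(unit),
    region_factor = region_factor,
    pad_factor = pad_factor,
    region_length = as.integer(round(region_factor * unit)),
    pad_length = as.integer(round(pad_factor * unit)),
    tier_table = tier_table,
    min_total = min_total,
    max_n_fraction = max_n_fraction,
    seed = seed
  ), class = "SamplingConfig")
}

#' Default genome-size sampling tiers
#'
#' 50% of genomes below 100 Mb, 25% below 500 Mb, 1% otherwise. Bounds are
#' strict upper bounds in bp.
#' @return a data.frame with columns `upper_bound` and `fraction`.
#' @export
default_tier_table <- function() {
  data.frame(
    upper_bound = c(100e6, 500e6, Inf),
    fraction = c(0.50, 0.25, 0.01)
  )
}

#' Total length of reference to sample, in bp
#'
#' Applies the tier fraction for the genome size, then the global floor, then
#' caps at the genome length itself (with a warning) for genomes smaller than
#' the floor — the tier scheme is silent about genomes below 15 Mb.
#'
#' @param genome_length reference genome length in bp.
#' @param config a [sampling_config()].
#' @return target length in bp.
#' @export
compute_sampling_target <- function(genome_length, config) {
  stopifnot(inherits(config, "SamplingConfig"))
  if (!is_count(genome_length)) stop_config("genome_length must be >= 1")
  tiers <- config$tier_table
  i <- which(genome_length < tiers$upper_bound)[1L]
  if (is.na(i)) i <- nrow(tiers)
  target <- max(tiers$fraction[i] * genome_length, config$min_total)
  if (target > genome_length) {
    warning(sprintf(
      "sampling target %.0f bp exceeds genome length %.0f bp; capped",
      target, genome_length
    ), call. = FALSE)
    target <- genome_length
  }
  target
}

# Count of N per fixed-width window, vectorised over windows.
n_fraction_of <- function(seqs) {
  (nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))) / nchar(seqs)
}

# Place `m` non-overlapping length-L regions uniformly at random into `gaps`
# (data.frame contig, start, end; 1-based closed). Counts per gap are drawn
# uniformly over the gap "slots" (capacity floor(width / L)); positions
# within a gap come from the order-statistics spacing construction, which is
# an exact uniform draw over all non-overlapping placements and remains
# feasible at any density up to 100%.
place_regions <- function(gaps, m, L) {
  cap <- pmax(0, floor((gaps$end - gaps$start + 1) / L))
  total <- sum(cap)
  if (m > total) {
    stop_sample(sprintf(
      "cannot place %d regions of %d bp: remaining capacity is %d", m, L, total
    ))
  }
  slot <- sort(sample.int(total, m))
  gap_of <- findInterval(slot - 1L, cumsum(c(0, cap)))  # which gap per slot
  counts <- tabulate(gap_of, nbins = nrow(gaps))
  out <- vector("list", nrow(gaps))
  for (g in which(counts > 0L)) {
    mg <- counts[g]
    a <- gaps$start[g]
    width <- gaps$end[g] - a + 1
    slack <- width - mg * L
    x <- sort(sample.int(slack + 1, mg, replace = TRUE)) - 1L
    starts <- a + x + (seq_len(mg) - 1L) * L
    out[[g]] <- data.frame(
      contig = gaps$contig[g], start = starts, end = starts + L - 1L,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Free space left on the eligible contigs once `kept` regions are excluded.
free_gaps <- function(contigs, kept) {
  out <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    k <- kept[kept$contig == contigs$contig[i], , drop = FALSE]
    k <- k[order(k$start), , drop = FALSE]
    starts <- c(1, k$end + 1)
    ends <- c(k$start - 1, contigs$length[i])
    ok <- ends >= starts
    out[[i]] <- data.frame(
      contig = contigs$contig[i], start = starts[ok], end = ends[ok],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Sample non-overlapping regions from a reference genome
#'
#' Draws regions of exactly `region_factor * read_length` bp (insert size for
#' paired-end) uniformly at random, without overlap, each wholly within one
#' contig, until the cumulative sampled length reaches the tier target from
#' [compute_sampling_target()]. Since all regions share one length, the total
#' satisfies `target <= total < target + region_length`. Candidate regions
#' containing more than `max_n_fraction` N are rejected and replaced.
#' Contigs shorter than one region length are excluded.
#'
#' @param genome a `Genome`.
#' @param config a [sampling_config()]; its `seed` makes sampling
#'   reproducible.
#' @return data.frame of class `RegionSet` with columns `contig`, `start`,
#'   `end` (1-based closed), ordered by contig then start.
#' @export
sample_regions <- function(genome, config) {
  stopifnot(inherits(genome, "Genome"), inherits(config, "SamplingConfig"))
  L <- config$region_length
  lens <- contig_lengths(genome)
  eligible <- lens >= L
  if (!any(eligible)) {
    stop_config(sprintf(
      "no contig is at least one region length (%d bp) long", L
    ))
  }
  target <- compute_sampling_target(genome_length(genome), config)
  m <- ceiling(target / L)
  contigs <- data.frame(
    contig = names(lens)[eligible], length = unname(lens[eligible]),
    stringsAsFactors = FALSE
  )
  capacity <- sum(floor(contigs$length / L))
  if (m > capacity) {
    warning(sprintf(
      "target needs %d regions but contigs only hold %d; sampling %d",
      m, capacity, capacity
    ), call. = FALSE)
    m <- capacity
  }
  has_n <- vapply(
    genome$records[contigs$contig], grepl, logical(1L),
    pattern = "N", fixed = TRUE
  )
  with_seed(config$seed, {
    kept <- data.frame(contig = character(), start = numeric(),
                       end = numeric(), stringsAsFactors = FALSE)
    gaps <- data.frame(contig = contigs$contig, start = 1,
                       end = contigs$length, stringsAsFactors = FALSE)
    stalled <- 0L
    repeat {
      deficit <- m - nrow(kept)
      if (deficit == 0L) break
      cand <- place_regions(gaps, deficit, L)
      if (any(has_n[cand$contig])) {
        seqs <- substring(genome$records[cand$contig], cand$start, cand$end)
        good <- n_fraction_of(seqs) <= config$max_n_fraction
      } else {
        good <- rep(TRUE, nrow(cand))
      }
      if (!any(good)) {
        stalled <- stalled + 1L
        if (stalled >= 30L) {
          stop_sample(sprintf(
            paste0("unable to sample %d more region(s) of %d bp: remaining ",
                   "sequence exceeds the %.0f%% N limit"),
            deficit, L, 100 * config$max_n_fraction
          ))
        }
      } else {
        stalled <- 0L
        kept <- rbind(kept, cand[good, , drop = FALSE])
      }
      if (nrow(kept) < m) gaps <- free_gaps(contigs, kept)
    }
    kept <- kept[order(match(kept$contig, names(lens)), kept$start), ,
                 drop = FALSE]
    rownames(kept) <- NULL
    class(kept) <- c("RegionSet", "data.frame")
    kept
  })
}

#' Build the artificial chromosome from sampled regions
#'
#' Concatenates the region sequences in order, inserting a run of
#' `pad_factor * read_length` N (insert size for paired-end) between
#' consecutive regions, so no simulated read can branch from one region into
#' the next. Returns both the sequence and the region map needed to lift
#' simulated coordinates back to the reference.
#'
#' @param genome a `Genome`.
#' @param regions a `RegionSet` from [sample_regions()].
#' @param config the [sampling_config()] used to sample them.
#' @return list with elements `record` (list `id`, `sequence`) and
#'   `region_map` (class `RegionMap`: data.frame `contig`, `start`, `end`,
#'   `artificial_offset`, all 1-based; attributes `pad_length` and
#'   `artificial_length`).
#' @export
build_artificial_chromosome <- function(genome, regions, config) {
  stopifnot(inherits(genome, "Genome"), inherits(config, "SamplingConfig"))
  if (is.null(regions) || nrow(regions) == 0L) {
    stop_config("empty region list")
  }
  lens <- contig_lengths(genome)
  if (!all(regions$contig %in% names(lens)) ||
      any(regions$start < 1) ||
      any(regions$end > lens[regions$contig])) {
    stop_config("regions fall outside the genome")
  }
  pad <- config$pad_length
  widths <- regions$end - regions$start + 1
  seqs <- substring(genome$records[regions$contig], regions$start, regions$end)
  sequence <- paste(seqs, collapse = strrep("N", pad))
  offsets <- cumsum(c(1, utils::head(widths, -1L) + pad))
  region_map <- data.frame(
    contig = regions$contig,
    start = regions$start,
    end = regions$end,
    artificial_offset = offsets,
    stringsAsFactors = FALSE
  )
  attr(region_map, "pad_length") <- pad
  attr(region_map, "artificial_length") <- nchar(sequence)
  class(region_map) <- c("RegionMap", "data.frame")
  list(
    record = list(id = "mapbench_artificial", sequence = sequence),
    region_map = region_map
  )
}

#' Lift artificial-chromosome positions back to reference coordinates
#'
#' @param region_map a `RegionMap` from [build_artificial_chromosome()].
#' @param artificial_pos vector of 1-based positions on the artificial
#'   chromosome.
#' @return data.frame with columns `contig` and `position` (1-based);
#'   positions falling inside N padding get `NA` in both columns.
#' @export
lift_to_reference <- function(region_map, artificial_pos) {
  stopifnot(inherits(region_map, "RegionMap"))
  art_len <- attr(region_map, "artificial_length")
  if (any(artificial_pos < 1 | artificial_pos > art_len)) {
    stop_eval(sprintf(
      "artificial position out of range 1..%d", art_len
    ))
  }
  i <- findInterval(artificial_pos, region_map$artificial_offset)
  widths <- region_map$end - region_map$start + 1
  inside <- i >= 1L &
    artificial_pos <= region_map$artificial_offset[pmax(i, 1L)] +
      widths[pmax(i, 1L)] - 1
  contig <- ifelse(inside, region_map$contig[pmax(i, 1L)], NA_character_)
  position <- ifelse(
    inside,
    region_map$start[pmax(i, 1L)] + artificial_pos -
      region_map$artificial_offset[pmax(i, 1L)],
    NA_real_
  )
  data.frame(contig = contig, position = position, stringsAsFactors = FALSE)
}

#' Write / read a region map sidecar TSV
#'
#' The on-disk format uses 0-based half-open coordinates (documented in the
#' header line); in-memory objects are 1-based closed.
#'
#' @param region_map a `RegionMap`.
#' @param path TSV path.
#' @return `path` (write) or a `RegionMap` (read).
#' @export
write_region_map <- function(region_map, path) {
  stopifnot(inherits(region_map, "RegionMap"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# mapbench region map; 0-based half-open; pad_length=%d artificial_length=%.0f",
    attr(region_map, "pad_length"), attr(region_map, "artificial_length")
  ), con)
  writeLines("contig\tstart\tend\tartificial_offset", con)
  writeLines(sprintf(
    "%s\t%.0f\t%.0f\t%.0f",
    region_map$contig, region_map$start - 1, region_map$end,
    region_map$artificial_offset - 1
  ), con)
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  header <- readLines(path, n = 1L)
  pad <- as.integer(sub(".*pad_length=(\\d+).*", "\\1", header))
  art_len <- as.numeric(sub(".*artificial_length=(\\d+).*", "\\1", header))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          stringsAsFactors = FALSE)
  rm <- data.frame(
    contig = df$contig,
    start = df$start + 1,
    end = df$end,
    artificial_offset = df$artificial_offset + 1,
    stringsAsFactors = FALSE
  )
  attr(rm, "pad_length") <- pad
  attr(rm, "artificial_length") <- art_len
  class(rm) <- c("RegionMap", "data.frame")
  rm
}
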