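#' Genome objects
#'
#' A `Genome` is an ordered set of named contig sequences over the alphabet
#' `{A, C, G, T, N}`. Sequences are stored as a named character vector;
#' conversion to and from Biostrings objects happens only at file
#' boundaries.
#'
#' @param records named character vector of contig sequences. Names must be
#'   non-empty and unique; sequences are uppercased and any IUPAC ambiguity
#'   code other than N is replaced by N with a warning.
#' @return an object of class `Genome`.
#' @export
genome <- function(records) {
  if (!is.character(records) || length(records) == 0L) {
    stop_format("a genome needs at least one sequence record")
  }
  ids <- names(records)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    stop_format("every genome record needs a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stop_format(sprintf(
      "duplicate record id(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  records <- toupper(records)
  if (any(nchar(records) == 0L)) {
    stop_format("zero-length sequence record")
  }
  cleaned <- gsub("[^ACGTN]", "N", records)
  if (!identical(cleaned, records)) {
    warning("ambiguity codes other than N replaced by N", call. = FALSE)
    records <- cleaned
  }
  structure(list(records = records), class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  n <- length(x$records)
  cat(sprintf(
    "Genome: %d contig%s, %s bp total\n",
    n, if (n == 1L) "" else "s", format(genome_length(x), big.mark = ",")
  ))
  show <- utils::head(x$records, 5L)
  for (i in seq_along(show)) {
    cat(sprintf(
      "  %s (%s bp)\n", names(show)[i], format(nchar(show[i]), big.mark = ",")
    ))
  }
  if (n > 5L) cat(sprintf("  ... and %d more\n", n - 5L))
  invisible(x)
}

#' Total genome length in base pairs
#' @param genome a `Genome`.
#' @return integer-valued total length.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "Genome"))
  sum(as.numeric(nchar(genome$records)))
}

#' Lengths of individual contigs
#' @param genome a `Genome`.
#' @return named numeric vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "Genome"))
  stats::setNames(as.numeric(nchar(genome$records)), names(genome$records))
}

#' Read a reference genome from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()]. Record order is preserved, ids are
#' truncated at the first whitespace (description dropped), sequences are
#' uppercased, and ambiguity codes other than N become N.
#'
#' @param path path to a FASTA file (gzip handled transparently).
#' @return a `Genome`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("file not found: %s", path))
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      stop_format(sprintf("not a readable FASTA file (%s): %s",
                          path, conditionMessage(e)))
    }
  )
  if (length(set) == 0L) {
    stop_format(sprintf("no FASTA records in %s", path))
  }
  ids <- sub("\\s.*$", "", names(set))
  genome(stats::setNames(as.character(set), ids))
}

#' Write a genome to FASTA
#'
#' @param genome a `Genome`.
#' @param path output path.
#' @param line_width positive integer; sequence characters per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, line_width = 60L) {
  stopifnot(inherits(genome, "Genome"))
  if (!is_count(line_width)) {
    stop_config("line_width must be a positive integer")
  }
  set <- Biostrings::DNAStringSet(genome$records)
  Biostrings::writeXStringSet(set, filepath = path, width = line_width)
  invisible(path)
}

# fast iid base generator: raw-byte translation avoids building a
# length-n character vector
draw_bases <- function(n, gc_fraction) {
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
         gc_fraction / 2, (1 - gc_fraction) / 2)
  idx <- sample.int(4L, n, replace = TRUE, prob = p)
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[idx])  # A C G T
}

#' Generate a random synthetic genome
#'
#' Bases are drawn independently with `P(G) = P(C) = gc_fraction / 2` and the
#' remainder split evenly between A and T. The total length is divided as
#' evenly as possible across `n_contigs`. Used as a self-contained stand-in
#' for a real reference so the whole pipeline is testable without downloads.
#'
#' @param length total genome length in bp.
#' @param n_contigs number of contigs (`length >= n_contigs >= 1`).
#' @param gc_fraction expected GC content in `[0, 1]`.
#' @param seed integer seed; identical seeds give byte-identical genomes.
#' @return a `Genome` with contigs named `contig_1`, `contig_2`, ...
#' @export
generate_synthetic_genome <- function(length, n_contigs = 1L,
                                      gc_fraction = 0.5, seed = NULL) {
  if (!is_count(length) || !is_count(n_contigs) || length < n_contigs) {
    stop_config("need length >= n_contigs >= 1")
  }
  if (!is_proportion(gc_fraction)) {
    stop_config("gc_fraction must be in [0, 1]")
  }
  lens <- rep(length %/% n_contigs, n_contigs)
  extra <- length %% n_contigs
  if (extra > 0L) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  with_seed(seed, {
    recs <- vapply(lens, draw_bases, character(1L), gc_fraction = gc_fraction)
    genome(stats::setNames(recs, sprintf("contig_%d", seq_len(n_contigs))))
  })
}
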