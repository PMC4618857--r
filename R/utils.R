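`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded package operations never disturb a user's
#' random stream. A `NULL` seed evaluates `code` against the current stream.
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# classed errors so callers can distinguish configuration mistakes from
# malformed inputs programmatically
mb_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "mapbench_error")))
}

stop_format <- function(msg) mb_stop(msg, "mapbench_format_error")
stop_config <- function(msg) mb_stop(msg, "mapbench_config_error")
stop_import <- function(msg) mb_stop(msg, "mapbench_import_error")
stop_eval   <- function(msg) mb_stop(msg, "mapbench_eval_error")
stop_sample <- function(msg) mb_stop(msg, "mapbench_sampling_error")

DNA_BASES <- c("A", "C", "G", "T")

# ALT_BASES[i, j]: j-th alternative base for DNA_BASES[i]
ALT_BASES <- rbind(
  c("C", "G", "T"),
  c("A", "G", "T"),
  c("A", "C", "T"),
  c("A", "C", "G")
)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_proportion <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}
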