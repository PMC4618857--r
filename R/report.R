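#' Quadrant label of a candidate setting relative to a baseline
#'
#' The accuracy-versus-throughput plane is split into four quadrants at the
#' baseline's position: the first sign is the accuracy axis (fraction of
#' correctly mapped reads; `percent_mapped` in real-data mode), the second
#' the speed axis (correctly mapped reads per second). A `+` means strictly
#' greater than the baseline; ties count as `-`, so `N++` settings are
#' always preferable to the baseline.
#'
#' @param candidate,baseline one-row result data.frames from
#'   [evaluate_run()], evaluated on the same dataset and threshold.
#' @param mode `"simulated"` (accuracy axis) or `"real"` (percent mapped).
#' @return one of `"N++"`, `"N+-"`, `"N-+"`, `"N--"`.
#' @export
assign_quadrant <- function(candidate, baseline, mode = "simulated") {
  if (!identical(candidate$threshold, baseline$threshold)) {
    stop_config("candidate and baseline use different mapq thresholds")
  }
  acc_col <- if (mode == "real") "percent_mapped" else "accuracy"
  acc <- if (candidate[[acc_col]] > baseline[[acc_col]]) "+" else "-"
  spd <- if (isTRUE(candidate$correct_per_second >
              baseline$correct_per_second)) "+" else "-"
  paste0("N", acc, spd)
}

fmt5 <- function(x) signif(x, 5L)

result_numeric_cols <- c(
  "correct", "wrong", "not_mapped", "total", "accuracy", "precision",
  "recall", "recall_conventional", "f_measure", "correct_per_second",
  "percent_mapped", "mapping_wall_time", "peak_memory"
)

#' Render the benchmark report
#'
#' Writes three views of the same results into `out_dir`: `report.tsv` and
#' `report.json` (canonical tables, numbers rounded to 5 significant digits
#' in both) and `report.html`, a self-contained page with the summary
#' table and the accuracy-versus-throughput scatter — quadrant boundaries
#' drawn through the baseline setting, `A` marking the highest-accuracy and
#' `S` the highest-throughput setting (ties broken by parameter label,
#' lexicographically). Rendering is deterministic: identical inputs give
#' identical files.
#'
#' @param results data.frame of result rows from [evaluate_run()]
#'   (optionally several thresholds; the scatter uses the baseline's
#'   threshold).
#' @param baseline row index of the baseline result, or a character
#'   `"mapper/parameter_label"` key.
#' @param out_dir output directory (created if needed).
#' @param mode `"simulated"` (accuracy axis) or `"real"` (percent-mapped
#'   axis, for runs on genuine reads).
#' @return named character vector of the files written, invisibly.
#' @export
render_report <- function(results, baseline = 1L, out_dir,
                          mode = c("simulated", "real")) {
  mode <- match.arg(mode)
  if (is.null(results) || nrow(results) == 0L) {
    stop_config("no results to report")
  }
  if (is.character(baseline)) {
    key <- paste(results$mapper, results$parameter_label, sep = "/")
    baseline <- match(baseline, key)
    if (is.na(baseline)) stop_config("baseline key not found in results")
  }
  if (!is_count(baseline) || baseline > nrow(results)) {
    stop_config("baseline must index one result row")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tab <- results
  rownames(tab) <- NULL
  for (cc in intersect(result_numeric_cols, names(tab))) {
    tab[[cc]] <- fmt5(tab[[cc]])
  }
  base_row <- tab[baseline, , drop = FALSE]
  tab$quadrant <- vapply(seq_len(nrow(tab)), function(i) {
    if (i == baseline) "baseline" else
      assign_quadrant(tab[i, , drop = FALSE], base_row, mode)
  }, character(1L))

  acc_col <- if (mode == "real") "percent_mapped" else "accuracy"
  ord_a <- order(-tab[[acc_col]], tab$parameter_label, tab$mapper)
  ord_s <- order(-ifelse(is.na(tab$correct_per_second), -Inf,
                         tab$correct_per_second),
                 tab$parameter_label, tab$mapper)
  tab$marker <- ""
  tab$marker[ord_a[1L]] <- "A"
  tab$marker[ord_s[1L]] <- paste0(tab$marker[ord_s[1L]], "S")

  tsv <- file.path(out_dir, "report.tsv")
  json <- file.path(out_dir, "report.json")
  html <- file.path(out_dir, "report.html")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mode = mode, baseline = unname(baseline), results = tab),
    json, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  writeLines(render_html(tab, baseline, mode, acc_col), html)
  invisible(c(tsv = tsv, json = json, html = html))
}

svg_scale <- function(v, lo, hi, out_lo, out_hi) {
  if (hi == lo) return(rep((out_lo + out_hi) / 2, length(v)))
  out_lo + (v - lo) / (hi - lo) * (out_hi - out_lo)
}

render_html <- function(tab, baseline, mode, acc_col) {
  w <- 640; h <- 480; m <- 60
  x <- ifelse(is.na(tab$correct_per_second), 0, tab$correct_per_second)
  y <- if (acc_col == "accuracy") 100 * tab$accuracy else tab$percent_mapped
  xr <- range(x); yr <- range(y)
  pad_x <- max(diff(xr) * 0.08, 1e-9)
  pad_y <- max(diff(yr) * 0.08, 1e-9)
  xr <- xr + c(-pad_x, pad_x); yr <- yr + c(-pad_y, pad_y)
  px <- svg_scale(x, xr[1L], xr[2L], m, w - m)
  py <- svg_scale(y, yr[1L], yr[2L], h - m, m)

  pts <- vapply(seq_len(nrow(tab)), function(i) {
    if (i == baseline) {
      sprintf(
        '<polygon points="%.1f,%.1f %.1f,%.1f %.1f,%.1f" fill="black"><title>%s</title></polygon>',
        px[i], py[i] - 7, px[i] - 6, py[i] + 5, px[i] + 6, py[i] + 5,
        paste(tab$mapper[i], tab$parameter_label[i])
      )
    } else {
      sprintf(
        '<circle cx="%.1f" cy="%.1f" r="4" fill="#888" stroke="#444"><title>%s</title></circle>',
        px[i], py[i], paste(tab$mapper[i], tab$parameter_label[i])
      )
    }
  }, character(1L))
  marks <- vapply(which(nzchar(tab$marker)), function(i) {
    sprintf(
      '<text x="%.1f" y="%.1f" font-size="13" font-weight="bold" fill="#c00">%s</text>',
      px[i] + 7, py[i] - 7, tab$marker[i]
    )
  }, character(1L))
  svg <- c(
    sprintf('<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">',
            w, h),
    sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="none" stroke="black"/>',
            m, m, w - 2 * m, h - 2 * m),
    sprintf('<line x1="%.1f" y1="%d" x2="%.1f" y2="%d" stroke="#666" stroke-dasharray="5,4"/>',
            px[baseline], m, px[baseline], h - m),
    sprintf('<line x1="%d" y1="%.1f" x2="%d" y2="%.1f" stroke="#666" stroke-dasharray="5,4"/>',
            m, py[baseline], w - m, py[baseline]),
    pts, marks,
    sprintf('<text x="%d" y="%d" font-size="13">correctly mapped reads / s</text>',
            w / 2 - 90, h - 15),
    sprintf('<text x="15" y="%d" font-size="13" transform="rotate(-90 15 %d)">%s</text>',
            h / 2, h / 2,
            if (acc_col == "accuracy") "% reads correctly mapped"
            else "% reads mapped"),
    "</svg>"
  )

  cells <- function(row) paste0("<td>", unlist(row), "</td>", collapse = "")
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    paste0("<tr>", cells(tab[i, ]), "</tr>")
  }, character(1L))
  c(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'><title>mapbench report</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:3px 8px;font-size:13px}</style>",
    "</head><body>",
    "<h1>mapbench report</h1>",
    sprintf("<p>Mode: %s. Baseline: %s (%s). Quadrants are relative to the baseline; A = highest accuracy, S = highest throughput.</p>",
            mode, tab$mapper[baseline], tab$parameter_label[baseline]),
    "<h2>Accuracy vs throughput</h2>",
    svg,
    "<h2>Results</h2>",
    "<table><tr>",
    paste0("<th>", names(tab), "</th>", collapse = ""),
    "</tr>",
    rows,
    "</table></body></html>"
  )
}
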