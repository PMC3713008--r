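# Tabular result reports: TSV export/import of TOI statistic records and test
# results, with the run configuration echoed as '#'-prefixed header lines so
# that a run is reproducible from its report alone.

#' Assemble a statistics report
#'
#' Bundles the TOI statistic records (the 6 statistics x 4 intervals analysis
#' grid per region and texture map) with the group-test results and a header
#' of configuration values for export via [write_stats_report()].
#'
#' @param records Tibble of TOI statistic records (see [interval_average()]).
#' @param tests Optional tibble of group-test results (see
#'   [run_full_battery()]).
#' @param header Named list of scalar configuration values echoed into the
#'   files.
#' @return An object of class `stat_report`.
#' @export
stat_report <- function(records, tests = NULL, header = list()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("a report needs at least one record")
  keys <- records[, intersect(c("toi_label", "tpm_type", "statistic", "interval"),
                              names(records))]
  if (anyDuplicated(keys))
    stop("duplicate (toi, tpm_type, statistic, interval) record keys")
  structure(list(records = tibble::as_tibble(records),
                 tests = if (!is.null(tests)) tibble::as_tibble(tests),
                 header = header),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %d record(s)%s\n", nrow(x$records),
              if (!is.null(x$tests)) sprintf(", %d test row(s)", nrow(x$tests)) else ""))
  invisible(x)
}

format_report_table <- function(df) {
  cols <- lapply(df, function(col) {
    if (is.factor(col)) as.character(col)
    else if (is.logical(col)) ifelse(is.na(col), "NA", ifelse(col, "TRUE", "FALSE"))
    else if (is.integer(col)) ifelse(is.na(col), "NA", as.character(col))
    else if (is.numeric(col)) format_report_number(col)
    else ifelse(is.na(col), "NA", as.character(col))
  })
  header <- paste(names(df), collapse = "\t")
  rows <- do.call(paste, c(cols, sep = "\t"))
  c(header, rows)
}

report_paths <- function(path) {
  base <- sub("\\.tsv$", "", path)
  list(records = paste0(base, "_records.tsv"),
       tests = paste0(base, "_tests.tsv"))
}

#' Write a statistics report to delimiter-separated text files
#'
#' Writes `<base>_records.tsv` (and `<base>_tests.tsv` when test results are
#' present). Numbers are written with 12 significant digits, so the files
#' re-import losslessly at that precision and a write/read/write cycle is
#' byte-identical. Header configuration values appear as `#key<TAB>value`
#' comment lines.
#'
#' @param report A [stat_report].
#' @param path Base path (a trailing `.tsv` is stripped).
#' @return The records file path, invisibly.
#' @export
write_stats_report <- function(report, path) {
  stopifnot(inherits(report, "stat_report"))
  paths <- report_paths(path)
  hdr <- character(0)
  if (length(report$header) > 0L) {
    vals <- vapply(report$header, function(v) {
      if (is.numeric(v)) format_report_number(v) else paste(as.character(v), collapse = ",")
    }, character(1))
    hdr <- sprintf("#%s\t%s", names(report$header), vals)
  }
  writeLines(c(hdr, format_report_table(report$records)), paths$records)
  if (!is.null(report$tests))
    writeLines(c(hdr, format_report_table(report$tests)), paths$tests)
  invisible(paths$records)
}

read_report_table <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   na.strings = "NA", check.names = FALSE)
  tibble::as_tibble(df)
}

read_report_header <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "#")]
  if (length(lines) == 0L) return(list())
  parts <- strsplit(sub("^#", "", lines), "\t", fixed = TRUE)
  vals <- lapply(parts, function(p) {
    v <- if (length(p) >= 2L) p[2] else ""
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num) && grepl("^[-+0-9.eE]+$", v)) num else v
  })
  setNames(vals, vapply(parts, `[[`, character(1), 1L))
}

#' Read back a statistics report written by [write_stats_report()]
#'
#' @param path The base path or records file path used when writing.
#' @return A [stat_report].
#' @export
read_stats_report <- function(path) {
  paths <- if (grepl("_records\\.tsv$", path)) {
    list(records = path,
         tests = sub("_records\\.tsv$", "_tests.tsv", path))
  } else report_paths(path)
  records <- read_report_table(paths$records)
  for (col in c("tpm_type", "statistic", "interval", "tissue_class")) {
    if (col %in% names(records))
      records[[col]] <- factor(records[[col]],
                               levels = switch(col,
                                               tpm_type = TPM_TYPES,
                                               statistic = TOI_STATISTICS,
                                               interval = INTERVALS,
                                               tissue_class = TISSUE_CLASSES))
  }
  tests <- if (file.exists(paths$tests)) read_report_table(paths$tests)
  stat_report(records, tests, header = read_report_header(paths$records))
}
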