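# Delimited-text readers/writers shared by the trainer and the CLI.
# Sample files: comma-separated, header row, input columns then one target
# column. Record files: the seven base-call columns. Both live in [0,1];
# out-of-range cells are clipped with a warning, non-numeric or non-finite
# cells are hard errors naming the line.

#' Read a supervised sample file
#'
#' Comma-separated with a header; every column but the last is an input, the
#' last is the target. Cells must parse to finite numbers (line-numbered
#' error otherwise); values outside `[0, 1]` are clipped with a warning.
#'
#' @param path CSV path.
#' @param name identifier for the resulting set; defaults to the file stem.
#' @return a [sample_set()].
#' @export
read_sample_file <- function(path, name = NULL) {
  if (!file.exists(path)) abort_validation("no such file: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 colClasses = "character", check.names = FALSE),
                 error = function(e) abort_validation("cannot parse %s: %s",
                                                      path, conditionMessage(e)))
  if (nrow(df) == 0L) abort_validation("%s: no data rows", path)
  if (ncol(df) < 2L)
    abort_validation("%s: need at least one input column and a target", path)
  mat <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, names(df)))
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad))
    abort_validation("%s line %d: column '%s' is not a finite number (got '%s')",
                     path, bad[1, 1] + 1L, names(df)[bad[1, 2]],
                     df[bad[1, 1], bad[1, 2]])
  out <- which(mat < 0 | mat > 1)
  if (length(out)) {
    warn_anfiscall("%s: %d value(s) outside [0,1] clipped", path, length(out))
    mat <- clip01(mat)
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  d <- ncol(mat)
  set <- sample_set(mat[, -d, drop = FALSE], mat[, d], name)
  message(sprintf("read %d record(s) from %s", nrow(mat), path))
  set
}

#' Write a supervised sample file
#'
#' Emits the dialect [read_sample_file()] reads, at full precision.
#'
#' @param set a [sample_set()].
#' @param path destination CSV path.
#' @param target_name header for the target column.
#' @return `path`, invisibly.
#' @export
write_sample_file <- function(set, path, target_name = "target") {
  stopifnot(inherits(set, "sample_set"))
  df <- as.data.frame(set$x)
  if (is.null(colnames(set$x)))
    names(df) <- paste0("x", seq_len(ncol(set$x)))
  df[[target_name]] <- set$y
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write base-call record files
#'
#' Record files carry one called base per row with the header
#' `base,NP_called,NP_2nd,NH_called,NH_2nd,dNS_next,dNS_prev`.
#'
#' @param path CSV path.
#' @param records data frame of base-call records.
#' @return `read_record_file()` a validated record data frame;
#'   `write_record_file()` the path, invisibly.
#' @export
read_record_file <- function(path) {
  if (!file.exists(path)) abort_validation("no such file: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort_validation("cannot parse %s: %s",
                                                      path, conditionMessage(e)))
  validate_records(df)
}

#' @rdname read_record_file
#' @export
write_record_file <- function(records, path) {
  records <- validate_records(records)
  utils::write.csv(format(records, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a confidence result file
#'
#' Output dialect: `base,NC_P,NC_H,NC_dS,NC_o` with three decimal places,
#' the precision of the reference report.
#'
#' @param results data frame as returned by [call_sequence()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_result_file <- function(results, path) {
  stopifnot(is.data.frame(results),
            all(c("base", "NC_P", "NC_H", "NC_dS", "NC_o") %in% names(results)))
  out <- results[c("base", "NC_P", "NC_H", "NC_dS", "NC_o")]
  for (col in c("NC_P", "NC_H", "NC_dS", "NC_o"))
    out[[col]] <- formatC(out[[col]], digits = 3, format = "f")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a key/value configuration file
#'
#' Plain-text lines of the form `key = value` (or `key: value`); `#` starts
#' a comment. Values that parse as numbers are returned numeric.
#'
#' @param path configuration file path.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_validation("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([A-Za-z0-9_.-]+)\\s*[=:]\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3L)
      abort_validation("%s: cannot parse configuration line '%s'", path, lines[i])
    key <- m[2]; val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
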