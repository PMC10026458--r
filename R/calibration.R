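## Calibration table: tube recipes and their measured relaxation times.

CALIBRATION_COLUMNS <- c("tube_id", "agarose_pct", "ni_mM",
                         "t1_1p4T_ms", "t1_1p5T_ms", "t1_3T_ms",
                         "t2_1p4T_ms", "t2_1p5T_ms", "t2_3T_ms")

FIELD_LABELS <- c("1.4T" = "1p4T", "1.5T" = "1p5T", "3T" = "3T")

field_columns <- function(field) {
  field <- match.arg(field, names(FIELD_LABELS))
  suffix <- FIELD_LABELS[[field]]
  c(t1 = paste0("t1_", suffix, "_ms"), t2 = paste0("t2_", suffix, "_ms"))
}

#' Benchmark calibration table for the nine-tube phantom
#'
#' Returns the packaged calibration table: per-tube agarose (% w/v) and
#' NiCl2 (mM) concentrations together with the measured T1 and T2 (ms) at
#' 1.4 T (bench relaxometer, 22 degC), 1.5 T and 3 T (clinical scanners,
#' inversion-recovery gradient echo and single-echo spin echo). The table
#' has nine tube rows (ids `A`-`I`) plus one `outer` row describing the
#' outer gel matrix fill, for which only the 1.4 T bench values exist.
#'
#' @return a `calibration_table` data frame with columns
#'   `r paste(CALIBRATION_COLUMNS, collapse = ", ")`.
#' @seealso [read_calibration()], [fit_relaxivity_model()]
#' @examples
#' cal <- calibration_fixture()
#' cal[cal$tube_id == "A", c("agarose_pct", "ni_mM", "t1_1p4T_ms")]
#' @export
calibration_fixture <- function() {
  path <- system.file("extdata", "table1_calibration.csv",
                      package = "phantomqa", mustWork = TRUE)
  read_calibration(path)
}

#' Read or write a calibration table CSV
#'
#' The CSV interchange format has header
#' `tube_id, agarose_pct, ni_mM, t1_1p4T_ms, t1_1p5T_ms, t1_3T_ms,
#' t2_1p4T_ms, t2_1p5T_ms, t2_3T_ms`; empty cells denote missing
#' measurements.
#'
#' @param path file path.
#' @param calibration a `calibration_table` data frame.
#' @return `read_calibration()` returns a `calibration_table` data frame;
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CALIBRATION_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("calibration CSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[CALIBRATION_COLUMNS]
  if (anyDuplicated(df$tube_id)) {
    stop("calibration table has duplicated tube ids")
  }
  num_cols <- setdiff(CALIBRATION_COLUMNS, "tube_id")
  df[num_cols] <- lapply(df[num_cols], as.numeric)
  if (any(df$agarose_pct < 0, na.rm = TRUE) ||
      any(df$ni_mM < 0, na.rm = TRUE)) {
    stop("ingredient concentrations must be non-negative")
  }
  class(df) <- c("calibration_table", "data.frame")
  df
}

#' @rdname read_calibration
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(is.data.frame(calibration))
  write.csv(calibration[CALIBRATION_COLUMNS], path, row.names = FALSE,
            na = "")
  invisible(path)
}

#' Printed benchmark tables: bSSFP vs spin-echo T2, and long-term repeats
#'
#' `table2_fixture()` returns the published per-tube comparison of
#' T2-prepared bSSFP T2 mapping against the long-TR single-echo spin-echo
#' reference at 1.5 T and 3 T (with the printed difference columns kept for
#' cross-checking). `table3_fixture()` returns the published baseline vs
#' 12-month repeat bSSFP T2 values per tube and field strength.
#'
#' @return a data frame; one row per tube per field strength.
#' @seealso [bias_table()], [reproducibility_table()], [reproduce_tables()]
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_bssfp_vs_se.csv",
                      package = "phantomqa", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname table2_fixture
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "table3_reproducibility.csv",
                      package = "phantomqa", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
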