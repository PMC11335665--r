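#' Read and write eddy-observation CSV files
#'
#' The on-disk interchange format for standalone risk runs is a plain CSV
#' (UTF-8, '.' decimal separator, one header row) with at least the columns
#' `reynolds` and `largest_eddy_mm`; `flow_rate_ml_min`, `condition` and
#' `surface` are carried through when present. [assess_eddy_csv()] is the
#' file-to-file convenience wrapper around [assess_risk()].
#'
#' @param path Path to a CSV file.
#' @return `read_eddy_csv()` returns a tibble of observations.
#' @examples
#' p <- system.file("extdata", "reference_eddies.csv", package = "eddyrisk")
#' head(read_eddy_csv(p))
#' @export
read_eddy_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("reynolds", "largest_eddy_mm")) {
    if (!col %in% names(df)) {
      abort(sprintf("`%s` is missing required column `%s`.", path, col),
            class = "eddyrisk_parse_error")
    }
    if (!is.numeric(df[[col]]) || anyNA(df[[col]])) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))[1]
      abort(sprintf("Column `%s` in `%s` is not numeric (first bad row: %s).",
                    col, path, bad %||% NA),
            class = "eddyrisk_parse_error")
    }
  }
  df
}

#' @rdname read_eddy_csv
#' @param in_path,out_path Input and output CSV paths.
#' @param thresholds A [risk_thresholds()] object.
#' @return `assess_eddy_csv()` invisibly returns the assessed tibble after
#'   writing it to `out_path`.
#' @export
assess_eddy_csv <- function(in_path, out_path,
                            thresholds = risk_thresholds()) {
  out <- assess_risk(read_eddy_csv(in_path), thresholds = thresholds)
  readr::write_csv(out, out_path)
  invisible(out)
}
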