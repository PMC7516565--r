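#' Read a modelling dataset from a delimited file
#'
#' Reads a CSV or TSV file with a header row; the column named `response`
#' is the binary response and every other numeric column is a predictor,
#' in file order.
#'
#' @param file Path to a CSV (default) or TSV file.
#' @param response Name of the response column. Default `"y"`.
#' @param standardize Passed to [ss_dataset()]. Default `TRUE`.
#' @param sep Field separator; inferred from the file extension when
#'   `NULL` (".tsv"/".tab" mean tab, otherwise comma).
#' @return An [ss_dataset()].
#' @export
read_ss_dataset <- function(file, response = "y", standardize = TRUE,
                            sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", file, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (!response %in% names(df)) {
    stop("response column '", response, "' not found.", call. = FALSE)
  }
  y <- df[[response]]
  preds <- df[setdiff(names(df), response)]
  num <- vapply(preds, is.numeric, TRUE)
  if (!all(num)) preds <- preds[num]
  ss_dataset(as.matrix(preds), y, standardize = standardize)
}

#' Write a simulated design to a delimited file
#'
#' Writes predictors `x1..xp` and the response column `y` as CSV, and the
#' ground truth as a sidecar JSON file (`<file>.truth.json`) when
#' jsonlite is available.
#'
#' @param sim An `"ss_sim"` from [simulate_m1()]/[simulate_m2()].
#' @param file Output CSV path.
#' @param truth_sidecar Write the sidecar truth file? Default `TRUE`.
#' @return `file`, invisibly.
#' @export
write_ss_sim <- function(sim, file, truth_sidecar = TRUE) {
  stopifnot(inherits(sim, "ss_sim"))
  df <- as.data.frame(sim$X)
  df$y <- sim$y
  utils::write.csv(df, file, row.names = FALSE)
  if (truth_sidecar && requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(unclass(sim$truth),
                         paste0(file, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
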