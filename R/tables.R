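#' Load the packaged calibration table (first patient)
#'
#' Calculated landmark stress under the 1 N retraction force at the start
#' of each month (T0..T3) and the clinical tooth movement measured over the
#' following month (T0-1 .. T3-4), for landmarks C1M, C1D, C2D of the first
#' patient.  These 12 points calibrate the quadratic movement law.
#'
#' @param path CSV path; NULL for the packaged fixture.
#' @return data.frame with columns `landmark`, `stress_period`, `stress`
#'   (N/mm^2), `movement_period`, `movement` (mm).
#' @export
load_calibration_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table2.csv",
                                package = "orthofem", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("landmark", "stress_period", "stress", "movement_period",
            "movement")
  if (!all(need %in% names(tab)))
    stop("calibration table schema mismatch: expected columns ",
         paste(need, collapse = ", "))
  if (any(tab$stress <= 0) || any(tab$movement < 0))
    stop("calibration table: stress must be > 0 and movement >= 0")
  tab
}

#' Load the packaged validation table (second patient)
#'
#' Calculated landmark stress, the printed predicted movement, and the
#' clinical movement for the second patient, whose movement was predicted
#' with the first patient's law.
#'
#' @param path CSV path; NULL for the packaged fixture.
#' @return data.frame with columns `landmark`, `stress_period`, `stress`,
#'   `movement_period`, `calculated`, `clinical`, `diff_printed`,
#'   `percent_printed`.
#' @export
load_validation_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table3.csv",
                                package = "orthofem", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("landmark", "stress_period", "stress", "movement_period",
            "calculated", "clinical")
  if (!all(need %in% names(tab)))
    stop("validation table schema mismatch: expected columns ",
         paste(need, collapse = ", "))
  tab
}
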