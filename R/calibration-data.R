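#' Shared HE4 calibration curve measured by six laboratories
#'
#' A ten-sample HE4 dilution series (samples A-J, prepared by progressive
#' dilution from roughly 1074 down to 30 pmol/L) that was distributed to six
#' Italian clinical laboratories and measured on each laboratory's own
#' immunoassay platform (Lumipulse CLEIA, Cobas ECLIA, Architect and Alinity
#' CMIA). Lab 1 is the reference laboratory that prepared the series. The
#' disagreement between columns is the analytical bias that
#' [fit_olp()] quantifies and [harmonize()] corrects.
#'
#' @return A data.frame with columns `sample_id` and `lab1` ... `lab6`,
#'   concentrations in pmol/L.
#' @seealso [read_calibration()] for loading the same layout from CSV,
#'   [fit_olp()] and [fit_all_labs()] for bias estimation.
#' @export
#' @examples
#' calib <- he4_calibration_curve()
#' fit_olp(calibration_series(calib$lab1, calib$lab3, lab_id = "lab3"))
he4_calibration_curve <- function() {
  data.frame(
    sample_id = LETTERS[1:10],
    lab1 = c(1074.4, 574.9, 384.1, 322.4, 219.6, 186.5, 121.9, 88.9, 68.0, 30.3),
    lab2 = c(981.4, 497.3, 326.4, 266.4, 183.3, 155.9, 105.2, 74.55, 56.55, 25.8),
    lab3 = c(927.1, 492.5, 282.4, 244.5, 163.4, 148.3, 88.8, 64.2, 51.7, 26.4),
    lab4 = c(1008.6, 513.2, 347.8, 293.8, 209.6, 175.7, 115.0, 82.7, 65.4, 26.4),
    lab5 = c(1049.0, 501.5, 314.4, 248.5, 174.4, 143.0, 95.6, 68.7, 53.2, 28.1),
    lab6 = c(1027.7, 532.1, 349.7, 239.7, 202.3, 169.4, 112.7, 82.9, 60.5, 26.8),
    stringsAsFactors = FALSE
  )
}

#' Read a calibration experiment from CSV
#'
#' Accepts either the wide layout (one `sample_id` column plus one column per
#' laboratory, as returned by [he4_calibration_curve()]) or the long layout
#' with columns `sample_id, lab_id, replicate, value`. Long-format replicate
#' readings are averaged per sample before the wide table is assembled.
#'
#' @param path Path to a CSV file.
#' @return A wide data.frame: `sample_id` plus one numeric column per lab.
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("lab_id", "value") %in% names(df))) {
    agg <- stats::aggregate(value ~ sample_id + lab_id, data = df, FUN = mean)
    wide <- stats::reshape(agg, idvar = "sample_id", timevar = "lab_id",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    rownames(wide) <- NULL
    # preserve original sample order
    wide <- wide[match(unique(df$sample_id), wide$sample_id), , drop = FALSE]
    rownames(wide) <- NULL
    return(wide)
  }
  if (!"sample_id" %in% names(df)) {
    stop("calibration CSV must contain a 'sample_id' column", call. = FALSE)
  }
  df
}
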