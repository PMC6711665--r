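#' Read and validate a trial table
#'
#' Reads a delimited text file of trial records (one row per trial), checks
#' the mandatory columns, coerces RT to seconds, normalizes the confidence
#' scale orientation to canonical (6 = certainly correct) for participants
#' who used a reversed scale, and attaches the three-level confidence
#' category. Validation failures are structured errors naming the offending
#' rows.
#'
#' @param path Path to a delimited text file with a header. The delimiter is
#'   taken from the extension (`.csv` comma, otherwise tab) unless given.
#' @param delim Field delimiter, overriding the guess.
#' @param rt_unit `"s"` (default) or `"ms"`; milliseconds are converted.
#' @param reversed_participants Participant ids whose confidence scale ran in
#'   reverse order (their ratings are remapped `r -> 7 - r`). Alternatively
#'   include a logical `scale_reversed` column in the file.
#' @return A validated tibble of trial records with `confidence_category`.
#' @export
read_trials <- function(path, delim = NULL, rt_unit = c("s", "ms"),
                        reversed_participants = NULL) {
  rt_unit <- match.arg(rt_unit)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) ","
                      else "\t"
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         comment = "#")
  need <- c("participant", "trial", "rt", "accuracy", "confidence_rating")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste("missing mandatory column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  bad_rt <- which(!is.finite(x$rt) | x$rt <= 0)
  if (length(bad_rt) > 0) {
    abort(paste("non-positive or missing RT in row(s):",
                paste(head(bad_rt, 20), collapse = ", ")))
  }
  if (rt_unit == "ms") x$rt <- x$rt / 1000
  bad_rating <- which(!x$confidence_rating %in% 1:6)
  if (length(bad_rating) > 0) {
    abort(paste("confidence rating outside 1..6 in row(s):",
                paste(head(bad_rating, 20), collapse = ", ")))
  }
  non_mono <- x |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$participant) |>
    filter(c(FALSE, diff(.data$trial) <= 0)) |>
    dplyr::pull(".row")
  if (length(non_mono) > 0) {
    abort(paste("non-monotone trial index in row(s):",
                paste(head(non_mono, 20), collapse = ", ")))
  }
  reversed <- rep(FALSE, nrow(x))
  if ("scale_reversed" %in% names(x)) reversed <- as.logical(x$scale_reversed)
  if (!is.null(reversed_participants)) {
    reversed <- reversed | x$participant %in% reversed_participants
  }
  x$confidence_rating <- ifelse(reversed, 7L - as.integer(x$confidence_rating),
                                as.integer(x$confidence_rating))
  x$confidence_category <- bin_confidence(x$confidence_rating)
  x
}

#' Write a trial table as tab-separated text
#'
#' @param trials Trial tibble.
#' @param path Output path.
#' @param header Optional comment lines (prefixed `#`) written before the
#'   table, e.g. provenance metadata.
#' @return The path, invisibly.
#' @export
write_trials <- function(trials, path, header = NULL) {
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_tsv(trials, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(trials, path)
  }
  invisible(path)
}
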