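#' Read a sample-metadata table
#'
#' Tab-separated text with a header; expected columns include `id`,
#' `population`, `site`, `building`, `sex`, `lat`, `lon`, `date_mean`,
#' `date_sd` (the layout written by [write_sim_dataset()]).
#'
#' @param path File path.
#' @return A tibble with unique ids and validated coordinates.
#' @export
read_sample_meta <- function(path) {
  m <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE,
                                   na.strings = c("NA", "")))
  if (!"id" %in% names(m)) stop_pk("metadata needs an id column")
  if (anyDuplicated(m$id)) stop_pk("duplicate metadata ids")
  if ("lat" %in% names(m) && any(abs(m$lat) > 90, na.rm = TRUE)) {
    stop_pk("latitude out of range")
  }
  if ("lon" %in% names(m) && any(abs(m$lon) > 180, na.rm = TRUE)) {
    stop_pk("longitude out of range")
  }
  m
}

#' Read a calibrated age grid
#'
#' Two-column tab-separated text (`year_calBCE`, `mass`).
#'
#' @param path File path.
#' @param normalize Rescale the masses to sum to 1.
#' @return An [age_distribution()].
#' @export
read_age_grid <- function(path, normalize = FALSE) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  age_distribution(d[[1]], d[[2]], normalize = normalize)
}
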