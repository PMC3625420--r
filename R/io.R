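#' Read visitation event logs and condition tables
#'
#' Thin CSV readers for the two plain-text dialects the pipeline consumes.
#' The event log has columns `time_s`, `bee_id`, `feeder_id`, `color`,
#' `concentration`, `rewarded` (plus optional `colony`, `day`); the condition
#' table has `day`, `conc_blue`, `conc_yellow` (plus optional `colony`).
#' Both are validated on read and returned as tibbles; the condition table
#' gains derived `intensity` and `sweeter_color` columns.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_visit_events <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("bee_id" %in% names(d)) d$bee_id <- as.character(d$bee_id)
  if ("rewarded" %in% names(d)) d$rewarded <- as.logical(d$rewarded)
  validate_events(d)
}

#' @rdname read_visit_events
#' @export
read_day_conditions <- function(path) {
  validate_conditions(utils::read.csv(path, stringsAsFactors = FALSE))
}
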