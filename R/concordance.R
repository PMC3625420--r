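#' Concordance between marked and pooled unmarked responses
#'
#' Spearman rank correlation between two daily response series — typically
#' the marked-bee and pooled unmarked-bee discrimination responses of one
#' colony — with midrank handling of ties. Also reports the rank-difference
#' statistic in the form `S = (1 - rho) * n * (n^2 - 1) / 6`, which reduces to
#' the classical sum of squared rank differences when there are no ties and
#' takes fractional values under midranks. Days on which either series is
#' missing are excluded pairwise.
#'
#' @param day_table Data frame with one row per day.
#' @param marked,unmarked Columns of `day_table` holding the two response
#'   series (tidy-eval; defaults `response_marked`, `response_unmarked`).
#' @return A tibble (one row per colony if a `colony` column is present) with
#'   `n_days`, `rho`, `s_statistic` and `p_value` (from [stats::cor.test()],
#'   AS 89 / t approximation).
#' @examples
#' marked_unmarked_concordance(colony_days())
#' @export
marked_unmarked_concordance <- function(day_table, marked = response_marked,
                                        unmarked = response_unmarked) {
  if (!is.data.frame(day_table)) abort("`day_table` must be a data frame.")
  day_table <- tibble::as_tibble(day_table)
  if (!"colony" %in% names(day_table)) day_table$colony <- 1L
  day_table %>%
    dplyr::group_by(.data$colony) %>%
    dplyr::group_modify(function(d, key) {
      x <- dplyr::pull(d, {{ marked }})
      y <- dplyr::pull(d, {{ unmarked }})
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      if (n < 3) abort("fewer than 3 complete day-pairs; concordance is undefined.")
      rho <- cor(x[ok], y[ok], method = "spearman")
      pv <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))$p.value
      tibble::tibble(n_days = n, rho = rho,
                     s_statistic = (1 - rho) * n * (n^2 - 1) / 6,
                     p_value = pv)
    }) %>%
    dplyr::ungroup()
}
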