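#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a deviation landscape
#'
#' @param x A [beta_landscape()].
#' @param ... Unused.
#' @return The landscape as a plain tibble, one row per (node, index).
#' @export
tidy.beta_landscape <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-line landscape summary
#'
#' @param x A [beta_landscape()].
#' @param alpha Significance level for the significant-cell fractions.
#' @param ... Unused.
#' @return A tibble with one row per index: grid size, mean delta, and the
#'   fraction of significant cells.
#' @export
glance.beta_landscape <- function(x, alpha = 0.05, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$index) |>
    dplyr::summarise(
      n_nodes = dplyr::n(),
      mean_delta = mean(.data$delta),
      prop_significant = mean(.data$p_value < alpha | .data$p_value > 1 - alpha),
      .groups = "drop"
    )
}

#' Tidy study results
#'
#' @param x A [run_study()] result.
#' @param what Which table: averaged `"landscape"`, per-stage `"profile"`,
#'   or stage `"comparisons"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.study_result <- function(x, what = c("landscape", "profile", "comparisons"),
                              ...) {
  what <- match.arg(what)
  tibble::as_tibble(x[[what]])
}

#' One row per stage summarizing a study
#'
#' @param x A [run_study()] result.
#' @param ... Unused.
#' @return The repetition-averaged per-stage profile tibble.
#' @export
glance.study_result <- function(x, ...) {
  x$profile
}

#' Export study tables as tidy CSVs
#'
#' Writes `profile.csv`, `profile_by_rep.csv`, `landscape.csv` and
#' `comparisons.csv` into a directory.
#'
#' @param x A [run_study()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_result <- function(x, dir) {
  stopifnot(inherits(x, "study_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(x$profile, file.path(dir, "profile.csv"))
  readr::write_csv(x$profile_by_rep, file.path(dir, "profile_by_rep.csv"))
  readr::write_csv(tibble::as_tibble(x$landscape), file.path(dir, "landscape.csv"))
  readr::write_csv(tibble::as_tibble(x$comparisons), file.path(dir, "comparisons.csv"))
  invisible(dir)
}
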