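# broom-style accessors for the report objects

#' Tidy a discrimination report
#'
#' @param x a `discrimination_report`.
#' @param ... unused.
#' @return a plain tibble of per-comparison rows.
#' @method tidy discrimination_report
#' @export
tidy.discrimination_report <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "reference") <- NULL
  out
}

#' One-row summary of a discrimination report
#'
#' @param x a `discrimination_report`.
#' @param ... unused.
#' @return tibble with the reference conformer, comparison count, and the
#'   count of each verdict.
#' @method glance discrimination_report
#' @export
glance.discrimination_report <- function(x, ...) {
  d <- as_tibble(x)
  tibble(reference = attr(x, "reference") %||% NA_character_,
         n_comparisons = nrow(d),
         n_indistinguishable = sum(d$verdict == "indistinguishable"),
         n_candidate_preferred = sum(d$verdict == "candidate_preferred"),
         n_reference_preferred = sum(d$verdict == "reference_preferred"))
}

#' Tidy a recovery experiment result
#'
#' @param x a `recovery_result`.
#' @param ... unused.
#' @return tibble with one row per decision rule.
#' @method tidy recovery_result
#' @export
tidy.recovery_result <- function(x, ...) as_tibble(x)

#' One-row summary of a recovery experiment
#'
#' @param x a `recovery_result`.
#' @param ... unused.
#' @return tibble with one column per decision rule plus `reps` and the
#'   chance level.
#' @method glance recovery_result
#' @export
glance.recovery_result <- function(x, ...) {
  d <- as_tibble(x)
  wide <- d |> select(all_of(c("rule", "recovery_rate"))) |>
    tidyr::pivot_wider(names_from = "rule", values_from = "recovery_rate")
  wide |> mutate(reps = d$reps[[1]], chance = 1 / d$n_conformers[[1]])
}
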