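# The agreement statistic between computed and experimental spectra is a
# mean-centered RMSD over per-nucleus deviations: centering removes any
# systematic offset (e.g. an imperfect TMS reference) before the spread is
# measured. Population normalization (divide by N) is used throughout.

#' Per-nucleus deviations of computed from experimental shifts
#'
#' Matches computed shifts to experimental assignments by nucleus label,
#' after restricting to the requested nucleus classes, and tabulates
#' `deviation = shift - shift_exp` per conformer and solvation model.
#' Labels present on only one side are never dropped silently: they are
#' recorded in the `unmatched` attribute.
#'
#' @param computed a shift table with `shift` filled in.
#' @param experimental an experimental table (`label`, `shift_exp`).
#' @param classes nucleus classes to keep; the three reporting modes are
#'   `c("OH","CHn")` (all protons), `"CHn"` (exchangeables excluded, as in
#'   D2O), and `"C"` (carbon-13).
#' @return tibble with columns `conformer`, `model`, `label`, `class`,
#'   `shift`, `shift_exp`, `deviation`, plus an `unmatched` attribute listing
#'   unmatched computed and experimental labels.
#' @export
shift_deviations <- function(computed, experimental,
                             classes = c("OH", "CHn", "C")) {
  bad <- setdiff(classes, NUCLEUS_CLASSES)
  if (length(bad) > 0L)
    abort(paste0("unknown nucleus class(es): ", paste(bad, collapse = ", ")))
  if (any(is.na(computed$shift)))
    abort("computed table has missing shifts; reference shieldings first")
  kept <- computed |> filter(.data$class %in% classes)
  matched <- kept |>
    inner_join(experimental |> select(all_of(c("label", "shift_exp"))),
               by = "label") |>
    mutate(deviation = .data$shift - .data$shift_exp) |>
    select(all_of(c("conformer", "model", "label", "class",
                    "shift", "shift_exp", "deviation")))
  if (nrow(matched) == 0L)
    abort("no matched nuclei between computed and experimental tables")
  out <- matched
  attr(out, "unmatched") <- list(
    computed = setdiff(unique(kept$label), unique(experimental$label)),
    experimental = setdiff(unique(experimental$label), unique(kept$label))
  )
  attr(out, "classes") <- classes
  out
}

#' Mean-centered RMSD of a deviation vector
#'
#' `sqrt(mean((d - mean(d))^2))`: the population standard deviation of the
#' deviations. Invariant under adding any constant to all deviations, which
#' makes the statistic insensitive to a uniform referencing offset.
#'
#' @param deviations numeric vector of per-nucleus deviations (ppm).
#' @return non-negative scalar, ppm.
#' @export
rmsd_centered <- function(deviations) {
  stopifnot(is.numeric(deviations), length(deviations) >= 1L)
  sqrt(mean((deviations - mean(deviations))^2))
}

#' Uncentered (raw) RMSD of a deviation vector
#'
#' `sqrt(mean(d^2))`, without removing the mean deviation. Larger than or
#' equal to [rmsd_centered()] by the Pythagorean decomposition
#' `raw^2 = centered^2 + mean(d)^2`; the difference measures the systematic
#' offset component.
#'
#' @inheritParams rmsd_centered
#' @return non-negative scalar, ppm.
#' @export
rmsd_raw <- function(deviations) {
  stopifnot(is.numeric(deviations), length(deviations) >= 1L)
  sqrt(mean(deviations^2))
}

#' RMSD summary per conformer and solvation model
#'
#' Reduces a deviation table to one row per conformer x model with the
#' nucleus count, mean deviation, and both RMSD variants.
#'
#' @param deviations output of [shift_deviations()].
#' @return tibble with columns `conformer`, `model`, `class_selection`, `n`,
#'   `mean_dev`, `rmsd_centered`, `rmsd_raw`.
#' @export
conformer_rmsd <- function(deviations) {
  sel <- paste(attr(deviations, "classes") %||% sort(unique(deviations$class)),
               collapse = "+")
  deviations |>
    group_by(.data$conformer, .data$model) |>
    summarise(class_selection = sel,
              n = dplyr::n(),
              mean_dev = mean(.data$deviation),
              rmsd_centered = rmsd_centered(.data$deviation),
              rmsd_raw = rmsd_raw(.data$deviation),
              .groups = "drop")
}

#' Relative RMSD of candidate conformers against a reference conformer
#'
#' For each solvation model, subtracts the reference conformer's RMSD from
#' every other conformer's: negative values mean the candidate fits the
#' experiment better than the reference.
#'
#' @param rmsd a tibble from [conformer_rmsd()].
#' @param reference conformer id to compare against.
#' @param statistic which column to difference, `"rmsd_centered"` (default)
#'   or `"rmsd_raw"`.
#' @return tibble with columns `candidate`, `model`, `class_selection`,
#'   `delta_rmsd` (candidate minus reference, ppm).
#' @export
delta_rmsd <- function(rmsd, reference, statistic = "rmsd_centered") {
  statistic <- match.arg(statistic, c("rmsd_centered", "rmsd_raw"))
  if (dplyr::n_distinct(rmsd$class_selection) > 1L)
    abort("delta_rmsd requires a single class selection; filter first")
  ref <- rmsd |> filter(.data$conformer == reference)
  if (nrow(ref) == 0L)
    abort(paste0("reference conformer '", reference, "' not present"))
  rmsd |>
    filter(.data$conformer != reference) |>
    inner_join(ref |>
                 select(all_of(c("model", statistic))) |>
                 rename(.ref = all_of(statistic)),
               by = "model") |>
    transmute(candidate = .data$conformer, model = .data$model,
              class_selection = .data$class_selection,
              delta_rmsd = .data[[statistic]] - .data$.ref)
}

#' Discriminate conformers with precision windows
#'
#' Applies the threshold-window rule to relative RMSD values: a candidate and
#' the reference are `indistinguishable` when `|delta| <= window` for the
#' nucleus family, `candidate_preferred` when `delta < -window`, and
#' `reference_preferred` when `delta > window`. Default windows are the
#' accepted accuracies of computed shifts: 0.1 ppm for 1H and 1.0 ppm for 13C.
#' The boundary `|delta| == window` counts as indistinguishable.
#'
#' @param deltas tibble with columns `candidate`, `family` (`"1H"` or
#'   `"13C"`), `delta_rmsd` (ppm), and optionally extra id columns carried
#'   through.
#' @param reference reference conformer id (annotation only).
#' @param windows named numeric vector of window widths per family, ppm.
#' @return a `discrimination_report` tibble with `window` and `verdict`
#'   columns appended.
#' @export
discriminate <- function(deltas, reference = NA_character_,
                         windows = c("1H" = 0.1, "13C" = 1.0)) {
  if (any(windows <= 0)) abort("windows must be positive")
  unknown <- setdiff(unique(deltas$family), names(windows))
  if (length(unknown) > 0L)
    abort(paste0("no window for nucleus family(ies): ",
                 paste(unknown, collapse = ", ")))
  out <- deltas |>
    mutate(window = unname(windows[.data$family]),
           verdict = dplyr::case_when(
             abs(.data$delta_rmsd) <= .data$window ~ "indistinguishable",
             .data$delta_rmsd < 0 ~ "candidate_preferred",
             TRUE ~ "reference_preferred"
           ))
  attr(out, "reference") <- reference
  class(out) <- c("discrimination_report", class(out))
  out
}

#' Sensitivity of results to the starting guess geometry (input A vs B)
#'
#' Pairs two result tables produced from independently built inputs of the
#' same systems and reports `delta_ab = value(B) - value(A)` for each key.
#' Used for both RMSDs (ppm) and relative energies (kcal/mol): shift-based
#' results are expected to be nearly input-independent while explicit-solvent
#' energies can move by tens of kcal/mol.
#'
#' @param results_a,results_b tibbles with identical key columns and one
#'   numeric value column.
#' @param value name of the value column (default: last numeric column shared
#'   by both tables).
#' @return tibble of the key columns plus `value_a`, `value_b`, `delta_ab`.
#' @export
input_sensitivity <- function(results_a, results_b, value = NULL) {
  if (is.null(value)) {
    num <- intersect(names(results_a)[vapply(results_a, is.numeric, TRUE)],
                     names(results_b)[vapply(results_b, is.numeric, TRUE)])
    if (length(num) == 0L) abort("no shared numeric value column")
    value <- num[length(num)]
  }
  keys <- setdiff(intersect(names(results_a), names(results_b)), value)
  keys <- keys[!vapply(results_a[keys], is.numeric, TRUE)]
  if (length(keys) == 0L) abort("no shared key columns to pair on")
  a <- results_a |> select(all_of(c(keys, value))) |> rename(value_a = all_of(value))
  b <- results_b |> select(all_of(c(keys, value))) |> rename(value_b = all_of(value))
  only_a <- anti_join(a, b, by = keys)
  only_b <- anti_join(b, a, by = keys)
  if (nrow(only_a) > 0L || nrow(only_b) > 0L) {
    fmt <- function(d) apply(d[keys], 1L, paste, collapse = "/")
    abort(paste0("unpaired entries - only in A: ",
                 paste(fmt(only_a), collapse = ", "), "; only in B: ",
                 paste(fmt(only_b), collapse = ", ")))
  }
  inner_join(a, b, by = keys) |>
    mutate(delta_ab = .data$value_b - .data$value_a)
}
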