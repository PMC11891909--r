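# TMS referencing: delta = sigma_ref(element) - sigma, the plain internal-
# reference conversion used with GIAO isotropic shieldings. The reference
# shieldings are whatever TMS gives at the same level of theory and solvent
# model, so they are user inputs, not constants.

#' Convert isotropic shieldings to TMS-referenced chemical shifts
#'
#' Applies `shift = sigma_ref(element) - shielding` to every record. The
#' shielding column is retained, so the conversion is invertible with the same
#' reference.
#'
#' @param shifts a shift table (see [read_shift_table()]) in which every row
#'   has a `shielding` value.
#' @param reference reference shieldings for TMS: a named numeric vector
#'   (`c(H = 31.8, C = 189.7)`), a two-column data frame (`element`,
#'   `sigma_ref`), or a path to such a CSV.
#' @return the shift table with `shift` filled in.
#' @export
shieldings_to_shifts <- function(shifts, reference) {
  ref <- as_reference(reference)
  if (any(is.na(shifts$shielding)))
    abort("every record needs a shielding value to be referenced")
  missing_el <- setdiff(unique(shifts$element), names(ref))
  if (length(missing_el) > 0L)
    abort(paste0("no reference shielding for element(s): ",
                 paste(missing_el, collapse = ", ")))
  shifts |> mutate(shift = unname(ref[.data$element]) - .data$shielding)
}

#' Recover shieldings from shifts with the same reference
#'
#' Inverse of [shieldings_to_shifts()]; useful for consistency checks.
#' @inheritParams shieldings_to_shifts
#' @return the table with `shielding` recomputed as `sigma_ref - shift`.
#' @export
shifts_to_shieldings <- function(shifts, reference) {
  ref <- as_reference(reference)
  missing_el <- setdiff(unique(shifts$element), names(ref))
  if (length(missing_el) > 0L)
    abort(paste0("no reference shielding for element(s): ",
                 paste(missing_el, collapse = ", ")))
  shifts |> mutate(shielding = unname(ref[.data$element]) - .data$shift)
}

as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L && file.exists(reference))
    reference <- read_delim_quiet(reference)
  if (is.data.frame(reference)) {
    missing_cols <- setdiff(c("element", "sigma_ref"), names(reference))
    if (length(missing_cols) > 0L)
      abort(paste0("reference table missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    reference <- setNames(as.numeric(reference$sigma_ref),
                          as.character(reference$element))
  }
  if (!is.numeric(reference) || is.null(names(reference)))
    abort("reference must be a named numeric vector, data frame, or CSV path")
  if (!all(is.finite(reference))) abort("reference shieldings must be finite")
  reference
}

#' Average equivalent nuclei into single signals
#'
#' Nuclei sharing an `equiv_group` (within one conformer and model) collapse
#' to one record whose shift (and shielding, when present) is the arithmetic
#' mean; the collapsed record takes the group name as label. Rows without a
#' group pass through untouched. This mirrors how methyl or otherwise
#' symmetry-equivalent protons give a single experimental signal.
#'
#' Grouping is explicit rather than inferred from connectivity, so nothing is
#' averaged that the user did not declare equivalent.
#'
#' @param shifts a shift table.
#' @return a shift table with each equivalence group reduced to one row.
#' @export
average_equivalent <- function(shifts) {
  grouped <- shifts |> filter(!is.na(.data$equiv_group))
  if (nrow(grouped) == 0L) return(shifts)
  mixed <- grouped |>
    group_by(.data$conformer, .data$model, .data$equiv_group) |>
    summarise(n_el = dplyr::n_distinct(.data$element),
              n_cl = dplyr::n_distinct(.data$class), .groups = "drop") |>
    filter(.data$n_el > 1L | .data$n_cl > 1L)
  if (nrow(mixed) > 0L)
    abort(paste0("equivalence group(s) mixing elements or classes: ",
                 paste(unique(mixed$equiv_group), collapse = ", ")))
  collapsed <- grouped |>
    group_by(.data$conformer, .data$model, .data$equiv_group) |>
    summarise(label = dplyr::first(.data$equiv_group),
              element = dplyr::first(.data$element),
              class = dplyr::first(.data$class),
              shielding = mean(.data$shielding),
              shift = mean(.data$shift), .groups = "drop") |>
    select(all_of(names(shifts)))
  bind_rows(shifts |> filter(is.na(.data$equiv_group)), collapsed) |>
    arrange(.data$conformer, .data$model)
}
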