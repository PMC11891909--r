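# End-to-end driver: shifts + experiment + energies in, the full report
# bundle out (RMSD tables, discrimination verdicts, relative energies,
# input-sensitivity deltas, optional ensemble average), with every numeric
# table also serializable as CSV/JSON at full precision.

#' Configuration for [run_pipeline()]
#'
#' @param shifts shift table (tibble) or path to one.
#' @param experimental experimental table (tibble) or path.
#' @param energies optional energy table (tibble) or path.
#' @param reference_conformer conformer id used as reference for relative
#'   RMSDs and relative energies (mandatory: no default is meaningful).
#' @param reference_shieldings optional TMS reference (see
#'   [shieldings_to_shifts()]); required when the shift table carries only
#'   shieldings.
#' @param families named list mapping nucleus family to the classes scored
#'   in it.
#' @param windows discrimination windows per family, ppm.
#' @param temperature kelvin, for Boltzmann weights.
#' @param ensemble `"none"`, `"boltzmann"` or `"equal"`: ensemble-average
#'   the computed spectra of `ensemble_model`.
#' @param ensemble_model model id whose spectra (and energies, for
#'   Boltzmann) are averaged; defaults to the first model present.
#' @param seed integer recorded in the log (the pipeline itself is
#'   deterministic).
#' @param out_dir optional directory; when set, all tables are written as
#'   CSV plus a single full-precision JSON bundle.
#' @return a `run_config` list.
#' @export
run_config <- function(shifts, experimental, energies = NULL,
                       reference_conformer,
                       reference_shieldings = NULL,
                       families = list("1H" = c("OH", "CHn"), "13C" = "C"),
                       windows = c("1H" = 0.1, "13C" = 1.0),
                       temperature = 298.15,
                       ensemble = c("none", "boltzmann", "equal"),
                       ensemble_model = NULL,
                       seed = 1L, out_dir = NULL) {
  if (missing(shifts) || is.null(shifts)) abort("missing input: shifts")
  if (missing(experimental) || is.null(experimental))
    abort("missing input: experimental")
  if (missing(reference_conformer)) abort("missing input: reference_conformer")
  if (any(windows <= 0)) abort("windows must be positive")
  structure(list(shifts = shifts, experimental = experimental,
                 energies = energies,
                 reference_conformer = reference_conformer,
                 reference_shieldings = reference_shieldings,
                 families = families, windows = windows,
                 temperature = temperature,
                 ensemble = match.arg(ensemble),
                 ensemble_model = ensemble_model,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

resolve_input <- function(x, reader, what) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) abort(paste0("missing input file for ", what, ": ", x))
    reader(x)
  } else if (is.data.frame(x)) as_tibble(x)
  else abort(paste0("missing or invalid input: ", what))
}

stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    abort(paste0("[", name, "] ", conditionMessage(e)))
  })
}

#' Run the full shift/energy analysis pipeline
#'
#' Wires the stages end to end: (optional) TMS referencing and equivalent-
#' nucleus averaging, per-family deviations and RMSD tables, relative RMSDs
#' and threshold-window discrimination against the reference conformer,
#' relative energies per solvation-model variant and input tag, the
#' input-A/B sensitivity table when both tags are present, and an
#' ensemble-averaged spectrum when requested. Deterministic for a fixed
#' config.
#'
#' @param config a [run_config()].
#' @return a `solvshift_report` list of tibbles: `rmsd`, `delta_rmsd`,
#'   `discrimination`, `relative_energies`, `input_sensitivity`, `ensemble`,
#'   `unmatched`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  shifts <- stage("chemio", resolve_input(config$shifts, read_shift_table, "shifts"))
  experimental <- stage("chemio", resolve_input(config$experimental,
                                                read_experimental_table, "experimental"))
  energies <- if (!is.null(config$energies))
    stage("chemio", resolve_input(config$energies, read_energy_table, "energies"))

  if (!is.null(config$reference_shieldings))
    shifts <- stage("referencing",
                    shieldings_to_shifts(shifts, config$reference_shieldings))
  if (any(is.na(shifts$shift)))
    abort("[referencing] shift table has missing shifts and no reference_shieldings given")
  shifts <- stage("referencing", average_equivalent(shifts))

  per_family <- lapply(setNames(names(config$families), names(config$families)),
                       function(fam) {
    classes <- config$families[[fam]]
    devs <- stage("nmr_stats", shift_deviations(shifts, experimental, classes))
    rmsd <- conformer_rmsd(devs) |> mutate(family = fam, .before = 1)
    deltas <- stage("nmr_stats",
                    delta_rmsd(rmsd |> select(-"family"),
                               config$reference_conformer)) |>
      mutate(family = fam, .before = 1)
    list(rmsd = rmsd, deltas = deltas,
         unmatched = tibble(family = fam,
                            side = rep(c("computed", "experimental"),
                                       lengths(attr(devs, "unmatched"))),
                            label = unlist(attr(devs, "unmatched"),
                                           use.names = FALSE)))
  })
  rmsd <- list_rbind(map(per_family, "rmsd"))
  deltas <- list_rbind(map(per_family, "deltas"))
  unmatched <- list_rbind(map(per_family, "unmatched"))
  discrimination <- stage("nmr_stats",
                          discriminate(deltas, config$reference_conformer,
                                       config$windows))

  rel_energies <- NULL
  sensitivity <- NULL
  if (!is.null(energies)) {
    rel_energies <- stage("energetics", {
      energies |>
        group_by(.data$model, .data$variant, .data$input_tag) |>
        group_split() |>
        map(~ relative_energies(.x, config$reference_conformer)) |>
        list_rbind()
    })
    tags <- unique(energies$input_tag)
    if (all(c("A", "B") %in% tags)) {
      sensitivity <- stage("nmr_stats", {
        a <- rel_energies |> filter(.data$input_tag == "A") |>
          select(all_of(c("conformer", "model", "variant", "delta_e")))
        b <- rel_energies |> filter(.data$input_tag == "B") |>
          select(all_of(c("conformer", "model", "variant", "delta_e")))
        input_sensitivity(a, b, value = "delta_e")
      })
    }
  }

  ensemble <- NULL
  if (config$ensemble != "none") {
    ens_model <- config$ensemble_model %||% shifts$model[[1]]
    ens_shifts <- shifts |> filter(.data$model == ens_model)
    weights <- if (config$ensemble == "equal") {
      equal_weights(unique(ens_shifts$conformer))
    } else {
      if (is.null(rel_energies))
        abort("[energetics] Boltzmann ensemble requested but no energies given")
      rel_m <- rel_energies |> filter(.data$model == ens_model)
      if (nrow(rel_m) == 0L)
        abort(paste0("[energetics] no energies for ensemble model ", ens_model))
      boltzmann_weights(rel_m |> distinct(.data$conformer, .data$delta_e),
                        config$temperature)
    }
    ensemble <- stage("energetics", ensemble_average(ens_shifts, weights)) |>
      mutate(weighting = config$ensemble)
  }

  log <- tibble(
    package_version = as.character(utils::packageVersion("solvshift")),
    seed = config$seed,
    reference_conformer = config$reference_conformer,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
  )
  report <- structure(list(rmsd = rmsd, delta_rmsd = deltas,
                           discrimination = discrimination,
                           relative_energies = rel_energies,
                           input_sensitivity = sensitivity,
                           ensemble = ensemble, unmatched = unmatched,
                           log = log),
                      class = "solvshift_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a report bundle to disk
#'
#' Each table goes to `<name>.csv`; the whole bundle is additionally written
#' as `report.json` at full precision (display rounding never reaches the
#' files). Rerunning the same config overwrites with byte-identical content.
#'
#' @param report a `solvshift_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- report[!vapply(report, is.null, TRUE)]
  for (nm in names(tables))
    readr::write_csv(as_tibble(tables[[nm]]), file.path(dir, paste0(nm, ".csv")))
  jsonlite::write_json(map(tables, ~ as.data.frame(.x)),
                       file.path(dir, "report.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(dir)
}

#' @export
print.solvshift_report <- function(x, ...) {
  cat("solvshift analysis report\n")
  cat("  reference conformer:", x$log$reference_conformer, "\n\n")
  cat("RMSD vs experiment (ppm, 2 dp):\n")
  print(x$rmsd |>
          mutate(across(c("mean_dev", "rmsd_centered", "rmsd_raw"),
                        ~ round(.x, 2))), n = 20)
  cat("\nDiscrimination verdicts:\n")
  print(x$discrimination |> mutate(delta_rmsd = round(.data$delta_rmsd, 2)),
        n = 20)
  if (!is.null(x$relative_energies)) {
    cat("\nRelative energies (kcal/mol, 1 dp):\n")
    print(x$relative_energies |> mutate(delta_e = round(.data$delta_e, 1)),
          n = 20)
  }
  invisible(x)
}
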