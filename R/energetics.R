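# Energy bookkeeping: relative conformer energies per solvation-model variant,
# Boltzmann / equal weighting, ensemble-averaged spectra, solute-only cluster
# extraction for fragment single points, and the cube-volume "molecular
# concentration" estimate for supermolecule clusters.

#' Relative conformer energies in kcal/mol
#'
#' Converts total energies (hartree) to energies relative to a declared
#' reference conformer, in kcal/mol (1 hartree = 627.5095 kcal/mol). All
#' records must share the same solvation model, variant and input tag:
#' energies from different variants are never comparable and mixing them is
#' an error, not a warning. The reference conformer is a mandatory argument
#' because no default choice is universally meaningful.
#'
#' @param energies tibble of energy records (see [read_energy_table()]).
#' @param reference conformer id whose energy defines zero.
#' @return tibble with columns `conformer`, `model`, `variant`, `input_tag`,
#'   `energy`, `delta_e` (kcal/mol relative to `reference`).
#' @export
relative_energies <- function(energies, reference) {
  for (col in c("model", "variant", "input_tag")) {
    if (dplyr::n_distinct(energies[[col]]) > 1L)
      abort(paste0("records mix several values of '", col,
                   "' (", paste(unique(energies[[col]]), collapse = ", "),
                   "); relative energies are only defined within one"))
  }
  ref <- energies |> filter(.data$conformer == reference)
  if (nrow(ref) == 0L)
    abort(paste0("reference conformer '", reference, "' not present"))
  energies |>
    mutate(delta_e = (.data$energy - ref$energy[[1]]) * HARTREE_TO_KCAL)
}

#' Boltzmann weights from relative energies
#'
#' `w_j` is proportional to `exp(-delta_e_j / (kB * T))` with
#' `kB = 1.987204e-3 kcal/(mol K)`, normalized to sum to 1. Invariant to
#' shifting all energies by a constant, so it does not matter which conformer
#' was used as reference.
#'
#' @param rel a tibble with columns `conformer` and `delta_e` (kcal/mol), as
#'   from [relative_energies()].
#' @param temperature absolute temperature in kelvin (default 298.15).
#' @return tibble with columns `conformer`, `weight`; temperature stored as
#'   an attribute.
#' @export
boltzmann_weights <- function(rel, temperature = 298.15) {
  if (temperature <= 0) abort("temperature must be positive (kelvin)")
  # subtract the minimum before exponentiating for numerical stability
  e <- rel$delta_e - min(rel$delta_e)
  w <- exp(-e / (KB_KCAL * temperature))
  out <- tibble(conformer = rel$conformer, weight = w / sum(w))
  attr(out, "temperature") <- temperature
  out
}

#' Equal weights over a conformer set
#'
#' The "equal Boltzmann weight" limit used to probe what ensemble averaging
#' does to a spectrum when the true populations are unknown.
#'
#' @param conformers character vector of conformer ids.
#' @return tibble with columns `conformer`, `weight` (each `1/n`).
#' @export
equal_weights <- function(conformers) {
  if (length(conformers) < 1L) abort("need at least one conformer")
  tibble(conformer = as.character(conformers),
         weight = 1 / length(conformers))
}

#' Ensemble-average computed spectra over conformers
#'
#' Experimental signals are averages over the conformers populated in
#' solution; this computes the corresponding weighted average of computed
#' shifts, per nucleus label, within one solvation model. All conformer
#' tables must carry the same label set.
#'
#' @param shifts a shift table containing the conformers to average (one
#'   `model` value).
#' @param weights tibble (`conformer`, `weight`) from [boltzmann_weights()]
#'   or [equal_weights()]; weights must cover every conformer present.
#' @param id conformer id given to the averaged pseudo-spectrum.
#' @return a shift table with a single conformer `id`.
#' @export
ensemble_average <- function(shifts, weights, id = "ensemble") {
  if (dplyr::n_distinct(shifts$model) > 1L)
    abort("ensemble_average expects a single solvation model; filter first")
  confs <- unique(shifts$conformer)
  missing_w <- setdiff(confs, weights$conformer)
  if (length(missing_w) > 0L)
    abort(paste0("no weight for conformer(s): ", paste(missing_w, collapse = ", ")))
  label_sets <- shifts |>
    group_by(.data$conformer) |>
    summarise(labs = list(sort(unique(.data$label))), .groups = "drop")
  all_labs <- sort(unique(shifts$label))
  off <- label_sets |>
    mutate(diff = map(.data$labs, ~ c(setdiff(all_labs, .x), setdiff(.x, all_labs)))) |>
    filter(lengths(.data$diff) > 0L)
  if (nrow(off) > 0L)
    abort(paste0("conformers carry different label sets; offending labels: ",
                 paste(unique(unlist(off$diff)), collapse = ", ")))
  w <- weights |> filter(.data$conformer %in% confs)
  w$weight <- w$weight / sum(w$weight)
  shifts |>
    inner_join(w, by = "conformer") |>
    group_by(.data$model, .data$label, .data$element, .data$class) |>
    summarise(shielding = sum(.data$weight * .data$shielding),
              shift = sum(.data$weight * .data$shift),
              equiv_group = dplyr::first(.data$equiv_group),
              .groups = "drop") |>
    mutate(conformer = id) |>
    select(all_of(c("conformer", "model", "label", "element", "class",
                    "shielding", "shift", "equiv_group")))
}

#' Remove explicit solvent fragments from a cluster
#'
#' Returns the solute-only structure — coordinates untouched, atom order
#' preserved — for single-point energies on the bare solute, plus optionally
#' each individual solute fragment. Fragments `0 .. n_solute_fragments - 1`
#' are solute, everything above is solvent.
#'
#' @param cluster an `xyz_tbl` structure with fragment indices.
#' @param n_solute_fragments number of solute molecules in the cluster.
#' @param each_fragment also return every solute fragment as its own
#'   structure.
#' @return list with `solute` (structure) and, when requested, `fragments`
#'   (list of structures).
#' @export
strip_solvent <- function(cluster, n_solute_fragments = 1L, each_fragment = FALSE) {
  if (n_solute_fragments < 1L) abort("need at least one solute fragment")
  frags <- sort(unique(cluster$fragment))
  if (n_solute_fragments > length(frags))
    abort(sprintf("requested %d solute fragments but cluster has only %d fragment(s)",
                  n_solute_fragments, length(frags)))
  solute_ids <- frags[seq_len(n_solute_fragments)]
  solute <- cluster |> filter(.data$fragment %in% solute_ids)
  attr(solute, "title") <- attr(cluster, "title") %||% ""
  attr(solute, "exempt_pairs") <- NULL
  attr(solute, "audit") <- NULL
  class(solute) <- class(cluster)
  out <- list(solute = solute)
  if (each_fragment) {
    out$fragments <- map(solute_ids, function(fid) {
      s <- cluster |> filter(.data$fragment == fid)
      attr(s, "title") <- sprintf("%s [fragment %d]",
                                  attr(cluster, "title") %||% "", fid)
      class(s) <- class(cluster)
      s
    })
  }
  out
}

#' Molecular concentration of a cluster model
#'
#' Approximates the simulated system by a cube whose edge is the largest
#' interatomic distance in the cluster, and reports the molarity
#' `n_solute / (N_A * V)` that this volume implies. This is the back-of-
#' envelope check that a supermolecule model represents a plausibly dilute
#' solution.
#'
#' @param cluster an `xyz_tbl` structure (at least 2 atoms).
#' @param n_solute number of solute molecules in the cluster.
#' @param solute_only measure the edge over solute atoms only (default FALSE:
#'   all atoms including solvent, matching measurement on the full input).
#' @param n_solute_fragments with `solute_only = TRUE`, how many fragments
#'   are solute.
#' @return tibble with columns `edge_A` (largest interatomic distance,
#'   Angstrom), `volume_m3` (cube volume), `concentration_M` (mol/L).
#' @export
cluster_concentration <- function(cluster, n_solute, solute_only = FALSE,
                                  n_solute_fragments = 1L) {
  atoms <- if (solute_only) {
    strip_solvent(cluster, n_solute_fragments)$solute
  } else cluster
  if (nrow(atoms) < 2L) abort("need at least two atoms to measure a distance")
  edge <- max(dist(as.matrix(atoms[, c("x", "y", "z")])))
  if (edge <= 0) abort("degenerate geometry: all atoms coincide")
  volume_m3 <- (edge * 1e-10)^3
  conc <- n_solute / (AVOGADRO * volume_m3 * 1000)  # m^3 -> L
  tibble(edge_A = edge, volume_m3 = volume_m3, concentration_M = conc)
}
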