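# Structures are tibbles of atoms (element, x, y, z, fragment) with a "title"
# attribute; shift/experimental/energy tables are plain long tibbles. Every
# downstream module consumes only these shapes.

# IUPAC element symbols, H..Lr; enough for any quantum-chemistry output
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr"
)

NUCLEUS_CLASSES <- c("OH", "CHn", "C")
ENERGY_VARIANTS <- c("PCM-DisRepCav", "PCM-default", "SMD", "vacuum",
                     "fragment-solute-only")
INPUT_TAGS <- c("A", "B", "unspecified")

#' Build a molecular structure tibble
#'
#' A structure is a tibble with one row per atom and columns `element`, `x`,
#' `y`, `z` (Cartesian coordinates in Angstrom) and `fragment` (integer
#' fragment index: solute molecules take `0 .. k-1`, explicit solvent
#' molecules `k .. m`). A `title` attribute carries the comment line of the
#' originating XYZ file.
#'
#' @param element character vector of element symbols.
#' @param x,y,z numeric coordinate vectors, Angstrom.
#' @param fragment integer fragment index per atom (default all 0 = one solute).
#' @param title comment string stored with the structure.
#' @return a tibble of class `xyz_tbl`.
#' @examples
#' water <- new_structure(c("O", "H", "H"),
#'                        x = c(0, 0.9572, -0.24), y = c(0, 0, 0.9266),
#'                        z = c(0, 0, 0), title = "water")
#' @export
new_structure <- function(element, x, y, z, fragment = 0L, title = "") {
  n <- length(element)
  if (n == 0L) abort("a structure must contain at least one atom")
  if (!length(fragment) %in% c(1L, n))
    abort("fragment index must have length 1 or one entry per atom")
  fragment <- rep_len(as.integer(fragment), n)
  bad <- setdiff(unique(element), ELEMENT_SYMBOLS)
  if (length(bad) > 0L)
    abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  coords <- c(x, y, z)
  if (length(x) != n || length(y) != n || length(z) != n)
    abort("coordinate vectors must match the number of atoms")
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  out <- tibble(element = as.character(element),
                x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                fragment = fragment)
  attr(out, "title") <- as.character(title)
  class(out) <- c("xyz_tbl", class(out))
  out
}

#' @export
print.xyz_tbl <- function(x, ...) {
  cat(sprintf("# structure: %d atoms, %d fragment(s)%s\n",
              nrow(x), dplyr::n_distinct(x$fragment),
              if (nzchar(attr(x, "title") %||% "")) paste0(" - ", attr(x, "title")) else ""))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an XYZ structure file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `element x y z` line per atom. A trailing integer field per atom line, if
#' present, is parsed as the fragment index; without it all atoms are assigned
#' fragment 0.
#'
#' @param path path to an XYZ file.
#' @return an `xyz_tbl` structure (see [new_structure()]).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) abort(sprintf("'%s': not an XYZ file (fewer than 2 lines)", path))
  n <- suppressWarnings(as.integer(trimws(lines[[1]])))
  if (is.na(n) || n < 1L)
    abort(sprintf("'%s' line 1: expected a positive atom count, got '%s'", path, lines[[1]]))
  if (length(lines) < 2L + n)
    abort(sprintf("'%s': header declares %d atoms but only %d atom lines present",
                  path, n, max(0L, length(lines) - 2L)))
  title <- lines[[2]]
  atom_lines <- lines[seq(3L, 2L + n)]
  fields <- strsplit(trimws(atom_lines), "\\s+")
  nfield <- lengths(fields)
  bad <- which(nfield < 4L)
  if (length(bad) > 0L)
    abort(sprintf("'%s' line %d: malformed atom line '%s'", path, bad[1] + 2L,
                  atom_lines[[bad[1]]]))
  has_frag <- all(nfield >= 5L)
  el <- map_chr(fields, 1L)
  num <- function(k) {
    v <- suppressWarnings(as.numeric(map_chr(fields, k)))
    if (anyNA(v))
      abort(sprintf("'%s' line %d: non-numeric coordinate", path, which(is.na(v))[1] + 2L))
    v
  }
  frag <- if (has_frag) {
    f <- suppressWarnings(as.integer(map_chr(fields, 5L)))
    if (anyNA(f))
      abort(sprintf("'%s' line %d: non-integer fragment field", path, which(is.na(f))[1] + 2L))
    f
  } else 0L
  new_structure(el, num(2L), num(3L), num(4L), fragment = frag, title = title)
}

#' Write a structure to an XYZ file
#'
#' Coordinates are written to 6 decimals; the fragment column is appended only
#' when more than one fragment is present, so single-molecule files remain
#' plain XYZ. `read_xyz(write_xyz(s, p))` reproduces elements, coordinates and
#' fragment indices.
#'
#' @param structure an `xyz_tbl` structure.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path) {
  stopifnot(is.data.frame(structure))
  if (nrow(structure) == 0L) abort("refusing to write an empty structure")
  multi <- dplyr::n_distinct(structure$fragment) > 1L
  body <- if (multi) {
    sprintf("%-3s %14.6f %14.6f %14.6f %4d", structure$element,
            structure$x, structure$y, structure$z, structure$fragment)
  } else {
    sprintf("%-3s %14.6f %14.6f %14.6f", structure$element,
            structure$x, structure$y, structure$z)
  }
  writeLines(c(as.character(nrow(structure)),
               attr(structure, "title") %||% "", body), con = path)
  invisible(path)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_quiet <- function(path) {
  readr::read_delim(path, delim = detect_delim(path), show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

check_duplicate_labels <- function(tbl, keys, what) {
  dup <- tbl |>
    count(across(all_of(keys)), name = "n_rows") |>
    filter(.data$n_rows > 1L)
  if (nrow(dup) > 0L) {
    offenders <- dup |>
      mutate(row = do.call(paste, c(pick(all_of(keys)), sep = "/"))) |>
      pull(.data$row)
    abort(paste0("duplicate ", what, ": ", paste(offenders, collapse = ", ")))
  }
  invisible(tbl)
}

#' Read a computed shift/shielding table
#'
#' Delimited text (comma or tab, auto-detected from the header) with columns
#' `conformer`, `model`, `label`, `element`, `class` and at least one of
#' `shielding` / `shift` (ppm). `class` must be one of `OH`, `CHn`, `C`; an
#' optional `equiv_group` column names groups of equivalent nuclei (e.g.
#' methyl protons) for [average_equivalent()].
#'
#' @param path path to the delimited file.
#' @return a long tibble, one row per nucleus per conformer per solvation model.
#' @export
read_shift_table <- function(path) {
  tbl <- read_delim_quiet(path)
  need <- c("conformer", "model", "label", "element", "class")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0L)
    abort(paste0("'", path, "': missing column(s) ", paste(missing_cols, collapse = ", ")))
  if (!any(c("shielding", "shift") %in% names(tbl)))
    abort(paste0("'", path, "': need a 'shielding' or 'shift' column"))
  if (!"shielding" %in% names(tbl)) tbl$shielding <- NA_real_
  if (!"shift" %in% names(tbl)) tbl$shift <- NA_real_
  if (!"equiv_group" %in% names(tbl)) tbl$equiv_group <- NA_character_
  tbl <- tbl |>
    mutate(across(c("conformer", "model", "label", "element", "class"), as.character),
           equiv_group = as.character(.data$equiv_group),
           shielding = as.numeric(.data$shielding),
           shift = as.numeric(.data$shift)) |>
    select(all_of(c("conformer", "model", "label", "element", "class",
                    "shielding", "shift", "equiv_group")))
  validate_shift_table(tbl, path = path)
}

validate_shift_table <- function(tbl, path = "shift table") {
  bad_class <- setdiff(unique(tbl$class), NUCLEUS_CLASSES)
  if (length(bad_class) > 0L)
    abort(sprintf("'%s': unknown nucleus class(es) %s; allowed: %s", path,
                  paste(bad_class, collapse = ", "),
                  paste(NUCLEUS_CLASSES, collapse = ", ")))
  mismatch <- tbl |> filter((.data$class == "C") != (.data$element == "C"))
  if (nrow(mismatch) > 0L)
    abort(sprintf("'%s': nucleus class inconsistent with element for label(s) %s",
                  path, paste(unique(mismatch$label), collapse = ", ")))
  if (any(is.na(tbl$shielding) & is.na(tbl$shift)))
    abort(sprintf("'%s': rows with neither shielding nor shift", path))
  check_duplicate_labels(tbl, c("conformer", "model", "label"),
                         "nucleus label(s) within a table")
  tbl
}

#' Read an experimental assignment table
#'
#' Columns: `label`, `shift_exp` (delta in ppm) and optionally `solvent`.
#'
#' @param path path to the delimited file.
#' @return tibble with columns `label`, `shift_exp`, `solvent`.
#' @export
read_experimental_table <- function(path) {
  tbl <- read_delim_quiet(path)
  missing_cols <- setdiff(c("label", "shift_exp"), names(tbl))
  if (length(missing_cols) > 0L)
    abort(paste0("'", path, "': missing column(s) ", paste(missing_cols, collapse = ", ")))
  if (!"solvent" %in% names(tbl)) tbl$solvent <- NA_character_
  tbl <- tbl |>
    mutate(label = as.character(.data$label),
           shift_exp = as.numeric(.data$shift_exp),
           solvent = as.character(.data$solvent)) |>
    select(all_of(c("label", "shift_exp", "solvent")))
  if (!all(is.finite(tbl$shift_exp)))
    abort(paste0("'", path, "': non-finite experimental shifts"))
  check_duplicate_labels(tbl, c("label"), "experimental label(s)")
  tbl
}

#' Read a total-energy table
#'
#' Columns: `conformer`, `model`, `variant`, `energy` (hartree) and optionally
#' `input_tag` (`A`/`B`; defaults to `unspecified`). `variant` is a closed
#' enumeration (`PCM-DisRepCav`, `PCM-default`, `SMD`, `vacuum`,
#' `fragment-solute-only`) so energies from incompatible solvation treatments
#' can never be compared silently.
#'
#' @param path path to the delimited file.
#' @return tibble of energy records.
#' @export
read_energy_table <- function(path) {
  tbl <- read_delim_quiet(path)
  missing_cols <- setdiff(c("conformer", "model", "variant", "energy"), names(tbl))
  if (length(missing_cols) > 0L)
    abort(paste0("'", path, "': missing column(s) ", paste(missing_cols, collapse = ", ")))
  if (!"input_tag" %in% names(tbl)) tbl$input_tag <- "unspecified"
  tbl <- tbl |>
    mutate(across(c("conformer", "model", "variant", "input_tag"), as.character),
           energy = as.numeric(.data$energy)) |>
    select(all_of(c("conformer", "model", "variant", "input_tag", "energy")))
  bad_var <- setdiff(unique(tbl$variant), ENERGY_VARIANTS)
  if (length(bad_var) > 0L)
    abort(sprintf("'%s': unknown variant(s) %s; allowed: %s", path,
                  paste(bad_var, collapse = ", "),
                  paste(ENERGY_VARIANTS, collapse = ", ")))
  bad_tag <- setdiff(unique(tbl$input_tag), INPUT_TAGS)
  if (length(bad_tag) > 0L)
    abort(sprintf("'%s': unknown input tag(s) %s; allowed: %s", path,
                  paste(bad_tag, collapse = ", "), paste(INPUT_TAGS, collapse = ", ")))
  if (!all(is.finite(tbl$energy)))
    abort(paste0("'", path, "': non-finite energies"))
  tbl
}

#' Read all tabular inputs of a study in one call
#'
#' @param shift_paths,experimental_paths,energy_paths character vectors of
#'   file paths (any may be empty).
#' @return list with elements `shifts`, `experimental`, `energies`, each a
#'   tibble row-bound over its input files.
#' @export
read_tables <- function(shift_paths = character(),
                        experimental_paths = character(),
                        energy_paths = character()) {
  list(
    shifts = map(shift_paths, read_shift_table) |> list_rbind(),
    experimental = map(experimental_paths, read_experimental_table) |> list_rbind(),
    energies = map(energy_paths, read_energy_table) |> list_rbind()
  )
}
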