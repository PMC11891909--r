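# Distances, hydrogen-bond tables, shortest solute-solvent contacts, and
# torsion angles with periodic deviations. H-bond rows are specification-
# driven (explicit atom triples): printed tables include contacts out to
# ~3.7 A, so no universal cutoff reproduces a curated row selection. A
# cutoff-based detector is provided for exploration only.

coords_matrix <- function(structure) as.matrix(structure[, c("x", "y", "z")])

#' Euclidean distance between two atoms
#'
#' @param structure an `xyz_tbl` structure.
#' @param i,j atom indices (1-based).
#' @return distance in Angstrom.
#' @export
atom_distance <- function(structure, i, j) {
  n <- nrow(structure)
  if (any(c(i, j) < 1L) || any(c(i, j) > n))
    abort(sprintf("atom index out of range 1..%d", n))
  sqrt(sum((coords_matrix(structure)[i, ] - coords_matrix(structure)[j, ])^2))
}

#' Hydrogen-bond distance table from explicit specs
#'
#' Each spec row names a donor heavy atom, its hydrogen, and the acceptor;
#' the reported quantity is the H...acceptor distance. A contact of 0 length
#' is flagged as unphysical rather than silently reported.
#'
#' @param structure an `xyz_tbl` structure.
#' @param specs tibble with integer columns `donor`, `h`, `acceptor` and an
#'   optional `description` column (e.g. `"C6-OH...N"`).
#' @return tibble with one row per spec, in input order: `description`,
#'   `donor`, `h`, `acceptor`, `distance_A`, `unphysical`.
#' @export
hbond_table <- function(structure, specs) {
  need <- c("donor", "h", "acceptor")
  missing_cols <- setdiff(need, names(specs))
  if (length(missing_cols) > 0L)
    abort(paste0("spec table missing column(s): ", paste(missing_cols, collapse = ", ")))
  n <- nrow(structure)
  idx <- unlist(specs[need])
  if (any(idx < 1L) || any(idx > n))
    abort(sprintf("spec atom index out of range 1..%d", n))
  bad_h <- which(structure$element[specs$h] != "H")
  if (length(bad_h) > 0L)
    abort(paste0("donor hydrogen is not element H in spec row(s): ",
                 paste(bad_h, collapse = ", ")))
  same <- which(specs$donor == specs$h | specs$h == specs$acceptor |
                  specs$donor == specs$acceptor)
  if (length(same) > 0L)
    abort(paste0("spec row(s) with repeated atom indices: ",
                 paste(same, collapse = ", ")))
  d <- map_dbl(seq_len(nrow(specs)),
               ~ atom_distance(structure, specs$h[.x], specs$acceptor[.x]))
  tibble(
    description = if ("description" %in% names(specs)) specs$description
                  else sprintf("%s%d-%s%d...%s%d",
                               structure$element[specs$donor], specs$donor,
                               structure$element[specs$h], specs$h,
                               structure$element[specs$acceptor], specs$acceptor),
    donor = specs$donor, h = specs$h, acceptor = specs$acceptor,
    distance_A = d,
    unphysical = d < 0.5
  )
}

#' Detect candidate hydrogen bonds by distance cutoff
#'
#' Exploratory helper: all O-H / N-H donors (from [find_donor_sites()]) whose
#' hydrogen lies within `cutoff` of an O or N acceptor outside the donor
#' bond. Curated report tables should use [hbond_table()] with explicit
#' specs instead.
#'
#' @param structure an `xyz_tbl` structure.
#' @param cutoff maximum H...acceptor distance, Angstrom (default 2.5).
#' @return tibble in [hbond_table()] layout.
#' @export
detect_hbonds <- function(structure, cutoff = 2.5) {
  sites <- find_donor_sites(structure)
  acceptors <- which(structure$element %in% c("O", "N"))
  if (nrow(sites) == 0L || length(acceptors) == 0L)
    return(hbond_table(structure, tibble(donor = integer(), h = integer(),
                                         acceptor = integer())))
  rows <- purrr::pmap(sites, function(heavy, h, ...) {
    acc <- setdiff(acceptors, heavy)
    d <- map_dbl(acc, ~ atom_distance(structure, h, .x))
    keep <- which(d <= cutoff)
    tibble(donor = heavy, h = h, acceptor = acc[keep])
  }) |> list_rbind()
  hbond_table(structure, rows)
}

#' Shortest contact between an atom group and partner fragments
#'
#' Minimum distance over all pairs formed by the group atoms and the atoms of
#' the partner fragments (e.g. an OH hydrogen against all solvent
#' molecules). Ties are broken deterministically toward the lowest index
#' pair.
#'
#' @param structure an `xyz_tbl` structure.
#' @param group integer vector of atom indices.
#' @param partner_fragments fragment indices to search against.
#' @return tibble with `distance_A`, `group_atom`, `partner_atom`.
#' @export
shortest_contact <- function(structure, group, partner_fragments) {
  if (length(group) == 0L) abort("group must be non-empty")
  partners <- which(structure$fragment %in% partner_fragments)
  partners <- setdiff(partners, group)
  if (length(partners) == 0L)
    abort("no partner atoms in the requested fragments")
  xyz <- coords_matrix(structure)
  best <- list(d = Inf, g = NA_integer_, p = NA_integer_)
  for (g in sort(group)) {
    d <- sqrt(colSums((t(xyz[partners, , drop = FALSE]) - xyz[g, ])^2))
    k <- which(d < best$d - 1e-12)
    if (length(k) > 0L) {
      kk <- k[which.min(d[k])]
      # strict improvement only, so earlier (lower-index) pairs win ties
      best <- list(d = d[kk], g = g, p = partners[kk])
    }
  }
  tibble(distance_A = best$d, group_atom = best$g, partner_atom = best$p)
}

#' Torsion (dihedral) angle of four atoms
#'
#' IUPAC sign convention: looking from atom `j` to atom `k`, a clockwise
#' rotation of the far bond relative to the near bond is positive. Result in
#' degrees in `(-180, 180]`.
#'
#' @param structure an `xyz_tbl` structure.
#' @param i,j,k,l atom indices defining the i-j-k-l dihedral.
#' @return angle in degrees.
#' @export
torsion <- function(structure, i, j, k, l) {
  idx <- c(i, j, k, l)
  if (length(unique(idx)) != 4L) abort("torsion atom indices must be distinct")
  n <- nrow(structure)
  if (any(idx < 1L) || any(idx > n))
    abort(sprintf("atom index out of range 1..%d", n))
  xyz <- coords_matrix(structure)
  b1 <- xyz[j, ] - xyz[i, ]
  b2 <- xyz[k, ] - xyz[j, ]
  b3 <- xyz[l, ] - xyz[k, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    abort("collinear atoms: torsion undefined")
  y <- sum(cross3(n1, n2) * b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion angles for a table of quadruples
#'
#' @param structure an `xyz_tbl` structure.
#' @param specs tibble with integer columns `i`, `j`, `k`, `l` and an
#'   optional `name` column (e.g. `"phi32"`).
#' @return tibble with `name` and `angle_deg` per spec row.
#' @export
torsion_table <- function(structure, specs) {
  missing_cols <- setdiff(c("i", "j", "k", "l"), names(specs))
  if (length(missing_cols) > 0L)
    abort(paste0("spec table missing column(s): ", paste(missing_cols, collapse = ", ")))
  tibble(
    name = if ("name" %in% names(specs)) specs$name
           else sprintf("t%d", seq_len(nrow(specs))),
    angle_deg = map_dbl(seq_len(nrow(specs)),
                        ~ torsion(structure, specs$i[.x], specs$j[.x],
                                  specs$k[.x], specs$l[.x]))
  )
}

#' Smallest angular difference between two torsions
#'
#' Periodic deviation on the circle, in `[0, 180]` degrees: 170 vs -170
#' differ by 20, not 340. This is the quantity used to compare optimized
#' torsions against a crystallographic reference. Vectorized.
#'
#' @param value_a,value_b angles in degrees in `(-180, 180]`.
#' @return absolute deviation(s) in degrees.
#' @export
torsion_deviation <- function(value_a, value_b) {
  if (any(value_a <= -180 | value_a > 180 | value_b <= -180 | value_b > 180))
    abort("angles must lie in (-180, 180]")
  d <- abs(value_a - value_b) %% 360
  pmin(d, 360 - d)
}

#' Torsion deviations of a structure from a reference structure
#'
#' @param structure,reference `xyz_tbl` structures with identical atom order.
#' @param specs torsion spec table (see [torsion_table()]).
#' @return tibble with `name`, `angle_deg`, `angle_ref_deg`, `deviation_deg`.
#' @export
torsion_deviation_table <- function(structure, reference, specs) {
  a <- torsion_table(structure, specs)
  b <- torsion_table(reference, specs)
  a |>
    rename(angle_deg = "angle_deg") |>
    mutate(angle_ref_deg = b$angle_deg,
           deviation_deg = torsion_deviation(.data$angle_deg, b$angle_deg))
}
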