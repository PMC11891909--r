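# Seeded microsolvation: rigid solvent templates are placed sequentially at
# O-H / N-H donor sites (then in a second shell) with a hydrogen-bond-length
# target and a van-der-Waals clash rejection loop. This makes the manual
# "place a few solvent molecules at each OH group" protocol reproducible:
# identical seed and inputs give bit-identical clusters.

# Bondi van der Waals radii (Angstrom); 1.70 fallback for uncommon elements
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
               P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Rigid solvent templates
#'
#' Fixed internal geometries for the three solvents handled by the cluster
#' builder. The anchor atom is the one aimed at the donor hydrogen: the
#' oxygen for water and DMSO (hydrogen-bond acceptor), the proton for
#' chloroform (weak C-H donor pointed back at the solute site).
#'
#' @param name `"water"`, `"chloroform"` or `"dmso"`.
#' @return list with `name`, `atoms` (an `xyz_tbl` in local coordinates) and
#'   `anchor` (atom index within the template).
#' @export
solvent_template <- function(name = c("water", "chloroform", "dmso")) {
  name <- match.arg(name)
  atoms <- switch(
    name,
    water = {
      # r(OH) = 0.9572 A, HOH angle 104.52 deg
      ang <- 104.52 * pi / 180
      new_structure(c("O", "H", "H"),
                    x = c(0, 0.9572, 0.9572 * cos(ang)),
                    y = c(0, 0, 0.9572 * sin(ang)),
                    z = c(0, 0, 0), title = "water template")
    },
    chloroform = {
      # C-H 1.09 A along +z, C-Cl 1.76 A tetrahedral
      ct <- -1 / 3                      # cos(109.47 deg)
      st <- sqrt(1 - ct^2)
      phi <- c(0, 2, 4) * pi / 3
      new_structure(c("C", "H", "Cl", "Cl", "Cl"),
                    x = c(0, 0, 1.76 * st * cos(phi)),
                    y = c(0, 0, 1.76 * st * sin(phi)),
                    z = c(0, 1.09, rep(1.76 * ct, 3)),
                    title = "chloroform template")
    },
    dmso = dmso_template()
  )
  list(name = name, atoms = atoms,
       anchor = switch(name, water = 1L, chloroform = 2L, dmso = 2L))
}

dmso_template <- function() {
  # S at origin, S=O 1.50 A along +z; S-C 1.80 A, C-S-O ~106.7 deg,
  # C-S-C ~97 deg; methyl H built tetrahedrally pointing away from S
  theta <- 106.7 * pi / 180
  cphi <- (cos(97 * pi / 180) - cos(theta)^2) / sin(theta)^2
  phi <- acos(max(-1, min(1, cphi))) / 2
  cdir <- function(p) c(sin(theta) * cos(p), sin(theta) * sin(p), -cos(theta))
  c1 <- 1.80 * cdir(phi)
  c2 <- 1.80 * cdir(-phi)
  methyl_h <- function(cpos) {
    d <- cpos / sqrt(sum(cpos^2))      # S->C direction
    e1 <- cross3(d, c(0, 0, 1)); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(d, e1)
    ct <- cos((180 - 109.47) * pi / 180)
    st <- sin((180 - 109.47) * pi / 180)
    t(vapply(c(0, 2, 4) * pi / 3, function(a) {
      cpos + 1.09 * (ct * -d + st * (cos(a) * e1 + sin(a) * e2))
    }, numeric(3)))
  }
  h1 <- methyl_h(c1); h2 <- methyl_h(c2)
  pos <- rbind(c(0, 0, 0), c(0, 0, 1.50), c1, c2, h1, h2)
  new_structure(c("S", "O", "C", "C", rep("H", 6)),
                x = pos[, 1], y = pos[, 2], z = pos[, 3],
                title = "dmso template")
}

#' Placement configuration for the cluster builder
#'
#' @param d0 target donor-H to anchor distance, Angstrom (default 1.9, the
#'   middle of typical H-bond contact ranges).
#' @param dd half-width of the accepted distance band (default 0.3, giving
#'   contacts in 1.6-2.2 A).
#' @param clash_factor fraction of the vdW-radius sum below which an
#'   intermolecular contact counts as a clash (default 0.8).
#' @param second_shell_band anchor-to-partner distance range for molecules
#'   beyond the first shell, Angstrom.
#' @param max_attempts sampling attempts per molecule before giving up.
#' @param seed integer seed anchoring all placement randomness.
#' @return list of class `placement_config`.
#' @export
placement_config <- function(d0 = 1.9, dd = 0.3, clash_factor = 0.8,
                             second_shell_band = c(2.7, 3.3),
                             max_attempts = 200L, seed = 1L) {
  if (d0 <= 0) abort("d0 must be positive")
  if (clash_factor <= 0 || clash_factor > 1) abort("clash_factor must be in (0, 1]")
  if (max_attempts < 1L) abort("max_attempts must be >= 1")
  structure(list(d0 = d0, dd = dd, clash_factor = clash_factor,
                 second_shell_band = second_shell_band,
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "placement_config")
}

#' Find hydrogen-bond donor sites
#'
#' All O-H and N-H pairs with a bond length below 1.2 Angstrom, ordered by
#' atom index. These are the sites solvent molecules are aimed at.
#'
#' @param structure an `xyz_tbl` structure.
#' @return tibble with columns `heavy`, `h` (atom indices), `element` (of
#'   the heavy atom), `bond_A`.
#' @export
find_donor_sites <- function(structure) {
  heavies <- which(structure$element %in% c("O", "N"))
  hydrogens <- which(structure$element == "H")
  if (length(heavies) == 0L || length(hydrogens) == 0L)
    return(tibble(heavy = integer(), h = integer(),
                  element = character(), bond_A = numeric()))
  xyz <- coords_matrix(structure)
  rows <- purrr::map(heavies, function(a) {
    d <- sqrt(colSums((t(xyz[hydrogens, , drop = FALSE]) - xyz[a, ])^2))
    keep <- which(d < 1.2)
    tibble(heavy = a, h = hydrogens[keep],
           element = structure$element[a], bond_A = d[keep])
  }) |> list_rbind()
  rows |> arrange(.data$heavy, .data$h)
}

#' Scan a cluster for van der Waals clashes
#'
#' Brute-force check of every intermolecular atom pair (atoms in different
#' fragments) against `clash_factor * (vdW_i + vdW_j)`. Designated
#' hydrogen-bond contacts are exempt: an H-bond is precisely a contact
#' shorter than the vdW sum, so the pairs a placement deliberately created
#' (recorded in the structure's audit) must not be counted as clashes.
#'
#' @param structure an `xyz_tbl` structure.
#' @param clash_factor clash threshold as a fraction of the vdW sum.
#' @param exempt two-column matrix/data frame of atom index pairs to skip;
#'   defaults to the `exempt_pairs` attribute left by [place_solvent()].
#' @return tibble of violations (`i`, `j`, `distance_A`, `limit_A`); zero
#'   rows means the cluster is clash-free.
#' @export
clash_scan <- function(structure, clash_factor = 0.8, exempt = NULL) {
  if (is.null(exempt)) exempt <- attr(structure, "exempt_pairs")
  xyz <- coords_matrix(structure)
  radii <- vdw_radius(structure$element)
  frag <- structure$fragment
  n <- nrow(structure)
  exempt_key <- character()
  if (!is.null(exempt) && NROW(exempt) > 0L) {
    e <- as.matrix(as.data.frame(exempt)[, 1:2])
    exempt_key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  }
  viol <- list()
  for (i in seq_len(n - 1L)) {
    js <- which(frag[(i + 1L):n] != frag[i]) + i
    if (length(js) == 0L) next
    d <- sqrt(colSums((t(xyz[js, , drop = FALSE]) - xyz[i, ])^2))
    lim <- clash_factor * (radii[i] + radii[js])
    hit <- which(d < lim)
    if (length(hit) > 0L) {
      key <- paste(i, js[hit])
      keep <- !(key %in% exempt_key)
      if (any(keep))
        viol[[length(viol) + 1L]] <- tibble(i = i, j = js[hit][keep],
                                            distance_A = d[hit][keep],
                                            limit_A = lim[hit][keep])
    }
  }
  if (length(viol) == 0L)
    tibble(i = integer(), j = integer(),
           distance_A = numeric(), limit_A = numeric())
  else list_rbind(viol)
}

unit <- function(v) v / sqrt(sum(v^2))

random_unit <- function() unit(rnorm(3))

# rotation matrix taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  v <- cross3(a, b)
  s2 <- sum(v^2)
  c_ <- sum(a * b)
  if (s2 < 1e-14) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(cross3(a, p))
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s2)
}

rotation_about <- function(axis, angle) {
  axis <- unit(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  vx <- matrix(c(0, axis[3], -axis[2],
                 -axis[3], 0, axis[1],
                 axis[2], -axis[1], 0), 3, 3)
  c_ * diag(3) + s_ * vx + (1 - c_) * outer(axis, axis)
}

#' Build a microsolvated cluster around a solute
#'
#' Places `n` rigid copies of a solvent template around the solute: one per
#' donor site in index order (first shell), then near already-placed solvent
#' molecules (second shell) once every site is occupied. Each first-shell
#' anchor lands within `d0 +/- dd` of its donor hydrogen along the X-H
#' direction; the spin about that axis, a small tilt, and the exact distance
#' are drawn from a generator seeded by `config$seed`, and candidate poses
#' are rejected until the cluster passes [clash_scan()]. Solute coordinates
#' are never modified.
#'
#' @param solute an `xyz_tbl` structure (fragment indices preserved; solvent
#'   fragments are numbered above the existing maximum).
#' @param template a [solvent_template()] (or a solvent name).
#' @param n number of solvent molecules to add.
#' @param config a [placement_config()].
#' @return the cluster as an `xyz_tbl`, with attributes `audit` (per-molecule
#'   site, shell, anchor index, achieved distance, attempts) and
#'   `exempt_pairs` (the designated H-bond contacts, for [clash_scan()]).
#' @export
place_solvent <- function(solute, template = "water", n,
                          config = placement_config()) {
  if (is.character(template)) template <- solvent_template(template)
  if (n < 0L) abort("n must be non-negative")
  if (n == 0L) return(solute)
  sites <- find_donor_sites(solute)
  if (nrow(sites) == 0L)
    abort("solute has no O-H or N-H donor sites to solvate")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  cluster <- solute
  tmpl_xyz <- coords_matrix(template$atoms)
  tmpl_xyz <- sweep(tmpl_xyz, 2, tmpl_xyz[template$anchor, ])  # anchor at origin
  rest <- setdiff(seq_len(nrow(tmpl_xyz)), template$anchor)
  axis_local <- unit(colMeans(tmpl_xyz[rest, , drop = FALSE]))
  next_frag <- max(solute$fragment) + 1L
  solute_centroid <- colMeans(coords_matrix(solute))
  audit <- list()
  exempt <- attr(solute, "exempt_pairs") %||%
    matrix(integer(), ncol = 2, dimnames = list(NULL, c("i", "j")))
  anchors_placed <- integer()          # global indices of placed anchors

  for (m in seq_len(n)) {
    first_shell <- m <= nrow(sites)
    placed <- FALSE
    tightest <- NULL
    for (attempt in seq_len(config$max_attempts)) {
      if (first_shell) {
        site <- sites[m, ]
        h_pos <- as.numeric(coords_matrix(cluster)[site$h, ])
        u0 <- unit(h_pos - as.numeric(coords_matrix(cluster)[site$heavy, ]))
        # small random tilt (< 20 deg) off the X-H axis, random in-band distance
        tilt <- rotation_about(random_unit(), runif(1, 0, 20 * pi / 180))
        u <- as.numeric(tilt %*% u0)
        d_target <- runif(1, config$d0 - config$dd, config$d0 + config$dd)
        target <- h_pos + d_target * u
        partner_idx <- site$h
      } else {
        partner_idx <- anchors_placed[sample.int(length(anchors_placed), 1L)]
        p_pos <- as.numeric(coords_matrix(cluster)[partner_idx, ])
        u <- random_unit()
        if (sum(u * (p_pos - solute_centroid)) < 0) u <- -u  # point outward
        d_target <- runif(1, config$second_shell_band[1], config$second_shell_band[2])
        target <- p_pos + d_target * u
      }
      spin <- rotation_about(u, runif(1, 0, 2 * pi))
      rot <- spin %*% rotation_between(axis_local, u)
      pos <- t(rot %*% t(tmpl_xyz)) + rep(target, each = nrow(tmpl_xyz))
      mol <- new_structure(template$atoms$element, pos[, 1], pos[, 2], pos[, 3],
                           fragment = next_frag)
      trial <- bind_rows(cluster, mol)
      class(trial) <- class(cluster)
      anchor_global <- nrow(cluster) + template$anchor
      ex_trial <- rbind(exempt, c(partner_idx, anchor_global))
      viol <- clash_scan(trial, config$clash_factor, exempt = ex_trial)
      if (nrow(viol) == 0L) {
        cluster <- trial
        attr(cluster, "title") <- attr(solute, "title") %||% ""
        exempt <- ex_trial
        anchors_placed <- c(anchors_placed, anchor_global)
        audit[[m]] <- tibble(
          molecule = m, shell = if (first_shell) 1L else 2L,
          site_heavy = if (first_shell) site$heavy else NA_integer_,
          site_h = if (first_shell) site$h else NA_integer_,
          partner_atom = partner_idx, anchor_atom = anchor_global,
          distance_A = d_target, attempts = attempt
        )
        next_frag <- next_frag + 1L
        placed <- TRUE
        break
      } else {
        worst <- viol |> mutate(gap = .data$limit_A - .data$distance_A) |>
          arrange(desc(.data$gap)) |> head(1)
        if (is.null(tightest) ||
            worst$gap[1] > (tightest$limit_A - tightest$distance_A))
          tightest <- worst
      }
    }
    if (!placed)
      abort(sprintf(
        "failed to place solvent molecule %d after %d attempts; tightest clash: atoms %d-%d at %.2f A (limit %.2f A)",
        m, config$max_attempts, tightest$i, tightest$j,
        tightest$distance_A, tightest$limit_A))
  }
  attr(cluster, "audit") <- list_rbind(audit)
  attr(cluster, "exempt_pairs") <- exempt
  cluster
}
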