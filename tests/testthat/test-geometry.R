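test_that("pairwise distances are Euclidean with index validation", {
  s <- new_structure(c("C", "C", "C"), x = c(0, 2, 1), y = c(0, 0, 1),
                     z = c(0, 0, 1))
  expect_equal(atom_distance(s, 1, 2), 2)
  expect_equal(atom_distance(s, 1, 1), 0)
  expect_equal(atom_distance(s, 1, 3), sqrt(3))
  expect_error(atom_distance(s, 1, 9), "out of range")
})

test_that("hydrogen-bond tables report H-to-acceptor distances in spec order", {
  # O-H donor with the acceptor N placed at the printed 1.78 A contact
  s <- new_structure(c("O", "H", "N", "O", "H"),
                     x = c(-0.96, 0, 1.78, 3, 3.96),
                     y = c(0, 0, 0, 1, 1), z = c(0, 0, 0, 0, 0))
  specs <- tibble::tibble(donor = c(1L, 4L), h = c(2L, 5L), acceptor = c(3L, 1L),
                          description = c("C6-OH...N", "arm2"))
  out <- hbond_table(s, specs)
  expect_equal(out$description, c("C6-OH...N", "arm2"))
  expect_equal(round(out$distance_A[1], 2), 1.78)
  expect_false(any(out$unphysical))
  # coincident acceptor is flagged unphysical
  s2 <- new_structure(c("O", "H", "N"), x = c(-0.96, 0, 0), y = c(0, 0, 0),
                      z = c(0, 0, 0))
  out2 <- hbond_table(s2, tibble::tibble(donor = 1L, h = 2L, acceptor = 3L))
  expect_true(out2$unphysical)
  expect_error(hbond_table(s, tibble::tibble(donor = 1L, h = 3L, acceptor = 2L)),
               "not element H")
})

test_that("shortest contacts minimize over partner fragments with low-index tie-break", {
  s <- new_structure(c("H", "O", "O", "O"),
                     x = c(0, 1.9, -1.9, 2.5), y = c(0, 0, 0, 0),
                     z = c(0, 0, 0, 0),
                     fragment = c(0L, 1L, 2L, 3L))
  out <- shortest_contact(s, group = 1L, partner_fragments = 1:3)
  expect_equal(out$distance_A, 1.9)
  expect_equal(out$partner_atom, 2L)  # atom 3 is equally close; lower index wins
  expect_error(shortest_contact(s, 1L, partner_fragments = 9L), "no partner")
})

test_that("torsions follow the sign convention on constructed geometries", {
  cis <- new_structure(rep("C", 4), x = c(1, 0, 0, 1), y = c(0, 0, 1, 1),
                       z = c(0, 0, 0, 0))
  expect_equal(torsion(cis, 1, 2, 3, 4), 0)
  trans <- new_structure(rep("C", 4), x = c(1, 0, 0, -1), y = c(0, 0, 1, 1),
                         z = c(0, 0, 0, 0))
  expect_equal(torsion(trans, 1, 2, 3, 4), 180)
  # quarter twists: the two handednesses give +90 and -90
  up <- new_structure(rep("C", 4), x = c(1, 0, 0, 0), y = c(0, 0, 1, 1),
                      z = c(0, 0, 0, -1))
  down <- new_structure(rep("C", 4), x = c(1, 0, 0, 0), y = c(0, 0, 1, 1),
                        z = c(0, 0, 0, 1))
  expect_equal(torsion(up, 1, 2, 3, 4), 90)
  expect_equal(torsion(down, 1, 2, 3, 4), -90)
  collinear <- new_structure(rep("C", 4), x = 0:3, y = rep(0, 4), z = rep(0, 4))
  expect_error(torsion(collinear, 1, 2, 3, 4), "collinear")
  expect_error(torsion(cis, 1, 2, 3, 3), "distinct")
})

test_that("torsions agree with an independent dihedral implementation", {
  skip_if_not_installed("bio3d")
  set.seed(21)
  for (k in 1:20) {
    s <- random_structure(4)
    ours <- torsion(s, 1, 2, 3, 4)
    xyz <- as.vector(t(as.matrix(s[, c("x", "y", "z")])))
    theirs <- bio3d::torsion.xyz(xyz, atm.inc = 4)
    expect_equal(ours, unname(theirs), tolerance = 1e-6)
  }
})

test_that("distances and torsions are invariant under rigid motions", {
  set.seed(31)
  s <- random_structure(6)
  d0 <- atom_distance(s, 1, 5)
  t0 <- torsion(s, 1, 2, 3, 4)
  for (k in 1:25) {
    m <- apply_rigid_motion(s)
    expect_equal(atom_distance(m, 1, 5), d0, tolerance = 1e-9)
    expect_equal(torsion(m, 1, 2, 3, 4), t0, tolerance = 1e-9)
  }
})

test_that("torsion deviations are periodic, symmetric and triangle-consistent", {
  expect_equal(torsion_deviation(170, -170), 20)
  expect_equal(torsion_deviation(45, 45), 0)
  expect_equal(torsion_deviation(0, 180), 180)
  expect_error(torsion_deviation(190, 0), "180")
  set.seed(5)
  a <- runif(50, -179.99, 180); b <- runif(50, -179.99, 180)
  cc <- runif(50, -179.99, 180)
  expect_equal(torsion_deviation(a, b), torsion_deviation(b, a))
  expect_true(all(torsion_deviation(a, cc) <=
                    torsion_deviation(a, b) + torsion_deviation(b, cc) + 1e-9))
  expect_true(all(torsion_deviation(a, b) >= 0 & torsion_deviation(a, b) <= 180))
})

test_that("torsion deviation tables compare a structure against a reference", {
  s <- new_structure(rep("C", 4), x = c(1, 0, 0, 0), y = c(0, 0, 1, 1),
                     z = c(0, 0, 0, -1))
  r <- new_structure(rep("C", 4), x = c(1, 0, 0, 1), y = c(0, 0, 1, 1),
                     z = c(0, 0, 0, 0))
  out <- torsion_deviation_table(s, r, tibble::tibble(i = 1L, j = 2L, k = 3L,
                                                      l = 4L, name = "phi32"))
  expect_equal(out$deviation_deg, 90)
  expect_equal(out$name, "phi32")
})

test_that("the exploratory H-bond detector honours its cutoff", {
  s <- new_structure(c("O", "H", "O", "O"),
                     x = c(-0.96, 0, 2.0, 4.0), y = c(0, 0, 0, 0),
                     z = c(0, 0, 0, 0))
  hits <- detect_hbonds(s, cutoff = 2.5)
  expect_equal(hits$acceptor, 3L)   # 4.0 A oxygen is beyond the cutoff
  expect_equal(nrow(detect_hbonds(s, cutoff = 1.0)), 0L)
})
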