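toy_energies <- function() {
  tibble::tibble(conformer = c("I", "II"), model = "PCM-0CHCl3",
                 variant = "PCM-default", input_tag = "unspecified",
                 energy = c(-1000.000000, -999.990000))
}

test_that("relative energies convert hartree gaps to kcal/mol against the reference", {
  rel <- relative_energies(toy_energies(), reference = "I")
  expect_equal(rel$delta_e[rel$conformer == "I"], 0)
  expect_equal(rel$delta_e[rel$conformer == "II"], 6.275095, tolerance = 1e-6)
})

test_that("mixed variants and absent references are refused", {
  mixed <- toy_energies() |>
    dplyr::mutate(variant = c("PCM-DisRepCav", "SMD"))
  expect_error(relative_energies(mixed, "I"), "variant")
  expect_error(relative_energies(toy_energies(), "XX"), "not present")
})

test_that("Boltzmann weights follow the closed form and normalize", {
  rel <- tibble::tibble(conformer = c("a", "b"), delta_e = c(0, 0))
  expect_equal(boltzmann_weights(rel)$weight, c(0.5, 0.5))
  rel1 <- tibble::tibble(conformer = c("a", "b"), delta_e = c(0, 1))
  w <- boltzmann_weights(rel1, temperature = 298.15)
  expect_equal(round(w$weight, 3), c(0.844, 0.156))
  relbig <- tibble::tibble(conformer = c("a", "b"), delta_e = c(0, 50))
  expect_lt(boltzmann_weights(relbig)$weight[2], 1e-30)
  expect_error(boltzmann_weights(rel, temperature = 0), "positive")
})

test_that("weights sum to one and are invariant to a constant energy shift", {
  set.seed(3)
  for (k in 1:25) {
    rel <- tibble::tibble(conformer = paste0("c", 1:5),
                          delta_e = runif(5, 0, 10))
    w <- boltzmann_weights(rel, temperature = runif(1, 100, 600))
    expect_equal(sum(w$weight), 1, tolerance = 1e-12)
    shifted <- rel |> dplyr::mutate(delta_e = delta_e + runif(1, -100, 100))
    expect_equal(boltzmann_weights(shifted)$weight,
                 boltzmann_weights(rel)$weight, tolerance = 1e-12)
  }
})

test_that("equal weights are 1/n", {
  expect_equal(equal_weights(c("III", "IV"))$weight, c(0.5, 0.5))
  expect_equal(equal_weights("only")$weight, 1)
  expect_equal(equal_weights(paste0("c", 1:4))$weight, rep(0.25, 4))
  expect_error(equal_weights(character()), "at least one")
})

test_that("ensemble averaging is the weighted per-label mean", {
  tbl <- toy_shift_tbl()
  avg <- ensemble_average(tbl, equal_weights(c("confA", "confB")))
  expect_equal(avg$shift[avg$label == "H1"], 1.3)
  expect_equal(unique(avg$conformer), "ensemble")
  # delta weighting returns the first table's values
  w10 <- tibble::tibble(conformer = c("confA", "confB"), weight = c(1, 0))
  avg10 <- ensemble_average(tbl, w10)
  a <- tbl |> dplyr::filter(conformer == "confA") |> dplyr::arrange(label)
  expect_equal(avg10 |> dplyr::arrange(label) |> dplyr::pull(shift), a$shift)
})

test_that("ensemble averaging with equal weights equals the plain mean and commutes with permutation", {
  tbl <- toy_shift_tbl()
  perm <- tbl[sample(nrow(tbl)), ]
  w <- equal_weights(c("confA", "confB"))
  a1 <- ensemble_average(tbl, w) |> dplyr::arrange(label)
  a2 <- ensemble_average(perm, w) |> dplyr::arrange(label)
  expect_equal(a1$shift, a2$shift)
  by_hand <- tbl |> dplyr::group_by(label) |>
    dplyr::summarise(m = mean(shift)) |> dplyr::arrange(label)
  expect_equal(a1$shift, by_hand$m)
})

test_that("ensemble averaging requires matching label sets and known weights", {
  tbl <- toy_shift_tbl()
  expect_error(ensemble_average(tbl[-1, ], equal_weights(c("confA", "confB"))),
               "H1")
  expect_error(ensemble_average(tbl, equal_weights("confA")), "confB")
})

test_that("strip_solvent removes solvent fragments without touching coordinates", {
  solute <- make_pentol()
  cluster <- place_solvent(solute, "water", 5, placement_config(seed = 1))
  out <- strip_solvent(cluster, n_solute_fragments = 1, each_fragment = TRUE)
  expect_equal(nrow(out$solute), nrow(solute))
  expect_identical(out$solute$x, solute$x)  # bit-exact
  expect_identical(out$solute$y, solute$y)
  expect_identical(out$solute$z, solute$z)
  expect_equal(nrow(out$solute) + 5 * 3, nrow(cluster))
  expect_length(out$fragments, 1L)
  # zero solvent fragments: identity
  same <- strip_solvent(solute, 1)$solute
  expect_equal(as.data.frame(same), as.data.frame(solute))
  expect_error(strip_solvent(solute, 3), "only 1 fragment")
})

test_that("cluster concentration reproduces the cube-volume worked example", {
  dimer <- new_structure(c("C", "C"), x = c(0, 31), y = c(0, 0), z = c(0, 0))
  out <- cluster_concentration(dimer, n_solute = 2)
  expect_equal(round(out$volume_m3 * 1e26, 2), 2.98)
  expect_equal(round(out$concentration_M, 2), 0.11)
  two <- new_structure(c("He", "He"), x = c(0, 10), y = c(0, 0), z = c(0, 0))
  expect_equal(cluster_concentration(two, 1)$concentration_M, 1.66054,
               tolerance = 1e-4)
  degenerate <- new_structure(c("C", "C"), x = c(1, 1), y = c(1, 1), z = c(1, 1))
  expect_error(cluster_concentration(degenerate, 1), "degenerate")
})

test_that("concentration scales as the inverse cube of the edge", {
  set.seed(9)
  for (k in 1:10) {
    L <- runif(1, 5, 40)
    s1 <- new_structure(c("C", "C"), x = c(0, L), y = c(0, 0), z = c(0, 0))
    s2 <- new_structure(c("C", "C"), x = c(0, 2 * L), y = c(0, 0), z = c(0, 0))
    c1 <- cluster_concentration(s1, 1)$concentration_M
    c2 <- cluster_concentration(s2, 1)$concentration_M
    expect_equal(c1 / c2, 8, tolerance = 1e-9)
  }
})
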