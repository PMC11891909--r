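test_that("deviations match computed to experimental by label, reporting the unmatched", {
  devs <- shift_deviations(toy_shift_tbl(), toy_experimental_tbl(),
                           classes = c("OH", "CHn"))
  a <- devs |> dplyr::filter(.data$conformer == "confA")
  expect_equal(nrow(a), 3L)
  expect_equal(a$deviation[a$label == "H1"], 0.2)
  expect_equal(a$deviation[a$label == "H2"], 0.0)
  # an experimental-only label is logged, not dropped silently
  exp2 <- dplyr::bind_rows(toy_experimental_tbl(),
                           tibble::tibble(label = "H99", shift_exp = 9.9,
                                          solvent = "chloroform"))
  devs2 <- shift_deviations(toy_shift_tbl(), exp2, classes = c("OH", "CHn"))
  expect_equal(nrow(devs2), nrow(devs))
  expect_true("H99" %in% attr(devs2, "unmatched")$experimental)
})

test_that("empty selections and unknown classes error", {
  all_h <- toy_shift_tbl() |> dplyr::filter(element == "H")
  expect_error(shift_deviations(all_h, toy_experimental_tbl(), classes = "C"),
               "no matched nuclei")
  expect_error(shift_deviations(all_h, toy_experimental_tbl(), classes = "XH"),
               "unknown nucleus class")
})

test_that("centered RMSD annihilates constants and matches hand values", {
  expect_equal(rmsd_centered(c(0.3, 0.3, 0.3)), 0)
  expect_equal(rmsd_centered(c(0.7)), 0)
  expect_equal(rmsd_centered(c(0.1, -0.1, 0.3, -0.3)), sqrt(0.05))
  expect_equal(rmsd_raw(c(0.3, 0.3, 0.3)), 0.3)
  expect_equal(rmsd_raw(0), 0)
  expect_equal(rmsd_raw(c(0.1, -0.1, 0.3, -0.3)), sqrt(0.05))
})

test_that("centered RMSD is offset-invariant, equals the two-pass sd, and never exceeds raw", {
  set.seed(11)
  for (k in 1:50) {
    v <- rnorm(sample(2:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0, 1))
    cc <- runif(1, -5, 5)
    expect_equal(rmsd_centered(v + cc), rmsd_centered(v), tolerance = 1e-12)
    expect_equal(rmsd_centered(v), two_pass_sd(v), tolerance = 1e-12)
    expect_lte(rmsd_centered(v), rmsd_raw(v) + 1e-15)
    # Pythagoras: raw^2 = centered^2 + mean^2
    expect_equal(rmsd_raw(v)^2, rmsd_centered(v)^2 + mean(v)^2, tolerance = 1e-12)
  }
})

test_that("relative RMSDs reproduce printed chloroform comparisons", {
  rmsd <- tibble::tibble(
    conformer = c("AZM-III", "AZM-IV"), model = "PCM-50CHCl3",
    class_selection = "OH+CHn", n = 35,
    mean_dev = 0, rmsd_centered = c(0.39, 0.36), rmsd_raw = c(0.39, 0.36)
  )
  d <- delta_rmsd(rmsd, reference = "AZM-III")
  expect_equal(d$delta_rmsd, -0.03)
  # carbon-13 analogue: 3.3 vs 3.8 ppm
  rmsd_c <- rmsd |> dplyr::mutate(class_selection = "C",
                                  rmsd_centered = c(3.8, 3.3))
  expect_equal(delta_rmsd(rmsd_c, "AZM-III")$delta_rmsd, -0.5)
  # self-comparison drops out; mismatched selections refuse to difference
  expect_equal(nrow(delta_rmsd(rmsd, "AZM-IV")), 1L)
  expect_error(delta_rmsd(dplyr::bind_rows(rmsd, rmsd_c), "AZM-III"),
               "single class selection")
  expect_error(delta_rmsd(rmsd, "AZM-IX"), "not present")
})

test_that("discrimination verdicts partition the delta axis exactly at the windows", {
  cases <- tibble::tibble(
    candidate = "cand",
    family = c("1H", "1H", "1H", "1H", "1H", "13C", "13C", "13C"),
    delta_rmsd = c(-0.25, -0.1, -0.03, 0.1, 0.11, -0.5, -1.0, 1.2)
  )
  rep <- discriminate(cases, reference = "ref")
  expect_equal(rep$verdict,
               c("candidate_preferred", "indistinguishable", "indistinguishable",
                 "indistinguishable", "reference_preferred",
                 "indistinguishable", "indistinguishable", "reference_preferred"))
  expect_error(discriminate(tibble::tibble(candidate = "c", family = "15N",
                                           delta_rmsd = 0.1)), "15N")
  expect_error(discriminate(cases, windows = c("1H" = -0.1, "13C" = 1)),
               "positive")
})

test_that("input-sensitivity pairing differences B minus A and flags unpaired rows", {
  a <- tibble::tibble(conformer = c("III", "IV"), family = "1H",
                      rmsd = c(0.30, 0.31))
  b <- tibble::tibble(conformer = c("III", "IV"), family = "1H",
                      rmsd = c(0.32, 0.31))
  out <- input_sensitivity(a, b, value = "rmsd")
  expect_equal(out$delta_ab[out$conformer == "III"], 0.02)
  expect_equal(out$delta_ab[out$conformer == "IV"], 0.0)
  expect_error(input_sensitivity(a[1, ], b, value = "rmsd"), "IV")
})
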