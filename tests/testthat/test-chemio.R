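test_that("XYZ files round-trip losslessly, including fragment indices", {
  set.seed(101)
  for (k in 1:5) {
    n <- sample(3:40, 1)
    s <- new_structure(sample(c("C", "H", "O", "N", "Cl"), n, replace = TRUE),
                       x = round(rnorm(n, sd = 8), 6),
                       y = round(rnorm(n, sd = 8), 6),
                       z = round(rnorm(n, sd = 8), 6),
                       fragment = sort(sample(0:2, n, replace = TRUE)),
                       title = paste("case", k))
    p <- withr::local_tempfile(fileext = ".xyz")
    write_xyz(s, p)
    r <- read_xyz(p)
    expect_equal(r$element, s$element)
    expect_equal(r$fragment, s$fragment)
    expect_true(max(abs(as.matrix(r[, c("x", "y", "z")]) -
                          as.matrix(s[, c("x", "y", "z")]))) < 1e-6)
  }
})

test_that("single-fragment structures are written as plain XYZ and read back as fragment 0", {
  s <- new_structure(c("O", "H", "H"),
                     x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = c(0, 0, 0),
                     title = "water")
  p <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(s, p)
  lines <- readLines(p)
  expect_length(strsplit(trimws(lines[3]), "\\s+")[[1]], 4L)  # no fragment column
  r <- read_xyz(p)
  expect_equal(r$fragment, c(0L, 0L, 0L))
  expect_equal(nrow(r), 3L)
})

test_that("malformed XYZ input is rejected with a line reference", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("4", "title", "O 0 0 0", "H 1 0 0", "H 0 1 0"), p)
  expect_error(read_xyz(p), "4 atoms")
  writeLines(c("2", "title", "O 0 0 0", "H 1 zero 0"), p)
  expect_error(read_xyz(p), "line 4")
  writeLines(c("1", "title", "Xx 0 0 0"), p)
  expect_error(read_xyz(p), "unknown element")
  expect_error(write_xyz(toy_shift_tbl()[0, ], withr::local_tempfile()), "empty")
})

test_that("structure construction validates elements, coordinates and fragments", {
  expect_error(new_structure("Q", 0, 0, 0), "unknown element")
  expect_error(new_structure("C", Inf, 0, 0), "finite")
  expect_error(new_structure(c("C", "C"), c(0, 1), c(0, 0), c(0, 0),
                             fragment = c(0L, 1L, 2L)), "fragment")
  expect_error(new_structure(character(), numeric(), numeric(), numeric()),
               "at least one atom")
})

test_that("shift tables read from comma and tab dialects with validation", {
  rows <- c("conformer,model,label,element,class,shift",
            "c1,PCM-0,H1,H,CHn,1.2", "c1,PCM-0,H2,H,CHn,3.0",
            "c1,PCM-0,C1,C,C,70.1", "c1,PCM-0,C2,C,C,20.5")
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(rows, p)
  tbl <- read_shift_table(p)
  expect_equal(nrow(tbl), 4L)
  expect_true(all(is.na(tbl$shielding)))

  ptab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(gsub(",", "\t", rows), ptab)
  expect_equal(read_shift_table(ptab)$shift, tbl$shift)

  writeLines(c(rows, "c1,PCM-0,H9,H,XH,2.2"), p)
  expect_error(read_shift_table(p), "OH, CHn, C")
  # class C on a proton is inconsistent
  writeLines(c(rows[1], "c1,PCM-0,H1,H,C,1.2"), p)
  expect_error(read_shift_table(p), "inconsistent")
})

test_that("duplicate labels are rejected and all offenders reported", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("conformer,model,label,element,class,shift",
               "c1,PCM-0,H1,H,CHn,1.2", "c1,PCM-0,H1,H,CHn,1.3",
               "c1,PCM-0,H2,H,CHn,2.0", "c1,PCM-0,H2,H,CHn,2.1"), p)
  err <- tryCatch(read_shift_table(p), error = conditionMessage)
  expect_match(err, "H1")
  expect_match(err, "H2")
  pe <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,shift_exp", "H1,1.0", "H1,1.1"), pe)
  expect_error(read_experimental_table(pe), "duplicate")
})

test_that("energy tables enforce the closed variant and tag enumerations", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("conformer,model,variant,input_tag,energy",
               "c1,PCM-50CHCl3,PCM-DisRepCav,A,-1000.0",
               "c1,PCM-50CHCl3,vacuum,A,-999.5"), p)
  tbl <- read_energy_table(p)
  expect_equal(nrow(tbl), 2L)
  expect_setequal(tbl$variant, c("PCM-DisRepCav", "vacuum"))
  writeLines(c("conformer,model,variant,energy", "c1,m,COSMO,-1.0"), p)
  expect_error(read_energy_table(p), "allowed")
  writeLines(c("conformer,model,variant,input_tag,energy",
               "c1,m,vacuum,Z,-1.0"), p)
  expect_error(read_energy_table(p), "input tag")
})

test_that("read_tables binds multiple files per input kind", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("conformer,model,label,element,class,shift", "c1,PCM-0,H1,H,CHn,1.2"), p1)
  writeLines(c("conformer,model,label,element,class,shift", "c2,PCM-0,H1,H,CHn,1.4"), p2)
  out <- read_tables(shift_paths = c(p1, p2))
  expect_equal(nrow(out$shifts), 2L)
  expect_equal(nrow(out$experimental), 0L)
})
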