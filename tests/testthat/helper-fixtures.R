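# fixtures are built in code: a 5-hydroxyl toy solute, random structures,
# rigid motions, and an independent two-pass standard deviation oracle

# toy polyol: five C-O-H arms on a ring, all in the xy plane
make_pentol <- function() {
  ang <- seq(0, 2 * pi, length.out = 6)[1:5]
  el <- character(); x <- numeric(); y <- numeric(); z <- numeric()
  for (a in ang) {
    cx <- 3 * cos(a); cy <- 3 * sin(a)
    el <- c(el, "C", "O", "H")
    x <- c(x, cx, cx + 1.4 * cos(a), cx + (1.4 + 0.96) * cos(a))
    y <- c(y, cy, cy + 1.4 * sin(a), cy + (1.4 + 0.96) * sin(a))
    z <- c(z, 0, 0, 0)
  }
  new_structure(el, x, y, z, title = "toy pentol")
}

random_structure <- function(n = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  new_structure(sample(c("C", "H", "O", "N"), n, replace = TRUE),
                x = rnorm(n, sd = 3), y = rnorm(n, sd = 3), z = rnorm(n, sd = 3))
}

# random rotation (QR of a Gaussian matrix, det +1) plus translation
apply_rigid_motion <- function(structure) {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  t0 <- rnorm(3, sd = 5)
  xyz <- as.matrix(structure[, c("x", "y", "z")]) %*% t(q)
  out <- structure
  out$x <- xyz[, 1] + t0[1]; out$y <- xyz[, 2] + t0[2]; out$z <- xyz[, 3] + t0[3]
  out
}

# independent two-pass population standard deviation
two_pass_sd <- function(v) {
  m <- sum(v) / length(v)
  acc <- 0
  for (vi in v) acc <- acc + (vi - m)^2
  sqrt(acc / length(v))
}

# tiny in-memory shift table over two conformers
toy_shift_tbl <- function() {
  tibble::tibble(
    conformer = rep(c("confA", "confB"), each = 4),
    model = "PCM-0CHCl3",
    label = rep(c("H1", "H2", "HO1", "C1"), 2),
    element = rep(c("H", "H", "H", "C"), 2),
    class = rep(c("CHn", "CHn", "OH", "C"), 2),
    shielding = NA_real_,
    shift = c(1.2, 3.0, 4.5, 70.0, 1.4, 3.1, 5.0, 72.0),
    equiv_group = NA_character_
  )
}

toy_experimental_tbl <- function() {
  tibble::tibble(label = c("H1", "H2", "HO1", "C1"),
                 shift_exp = c(1.0, 3.0, 4.6, 70.5),
                 solvent = "chloroform")
}
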