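# Coordinate handling: PDB reading, NH-vector extraction, superposition,
# value maps.

# hand-written 3-residue fixture with known coordinates (one proline)
tiny_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  H   ALA A   1       0.000   0.000   1.020  1.00  0.00           H",
    "ATOM      3  CA  ALA A   1       1.400   0.000   0.000  1.00  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.300   0.000  1.00  0.00           C",
    "ATOM      5  N   PRO A   2       3.300   1.300   0.000  1.00  0.00           N",
    "ATOM      6  CA  PRO A   2       4.100   2.400   0.000  1.00  0.00           C",
    "ATOM      7  C   PRO A   2       5.500   2.000   0.000  1.00  0.00           C",
    "ATOM      8  N   GLY A   3       6.300   3.000   0.000  1.00  0.00           N",
    "ATOM      9  H   GLY A   3       6.900   3.600   0.600  1.00  0.00           H",
    "ATOM     10  CA  GLY A   3       7.700   3.000   0.000  1.00  0.00           C",
    "ATOM     11  C   GLY A   3       8.300   4.300   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

test_that("PDB fixtures round-trip atoms, models, and parse errors", {
  p <- tempfile(fileext = ".pdb")
  tiny_pdb(p)
  s <- read_structure(p)
  expect_equal(nrow(s$pdb$atom), 11)
  expect_equal(s$n_models, 1)
  expect_equal(unname(relaxfit:::.model_xyz(s)[3, ]), c(1.4, 0, 0))

  pm <- tempfile(fileext = ".pdb")
  write_synthetic_structure(pm, n_residues = 6, n_models = 3, perturb = 0.2)
  sm <- read_structure(pm)
  expect_equal(sm$n_models, 3)

  bad <- tempfile(fileext = ".pdb")
  file.create(bad)
  expect_error(read_structure(bad), "empty|parse")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("NH vectors match hand geometry, are unit length, and skip prolines", {
  p <- tempfile(fileext = ".pdb")
  tiny_pdb(p)
  s <- read_structure(p)
  nh <- extract_nh_vectors(s)
  expect_equal(nh$residue_id, c(1L, 3L))       # proline 2 omitted
  expect_equal(c(nh$x[1], nh$y[1], nh$z[1]), c(0, 0, 1), tolerance = 1e-9)
  hand <- c(0.6, 0.6, 0.6) / sqrt(3 * 0.36)
  expect_equal(c(nh$x[2], nh$y[2], nh$z[2]), hand, tolerance = 1e-9)
  norms <- sqrt(nh$x^2 + nh$y^2 + nh$z^2)
  expect_equal(norms, rep(1, 2), tolerance = 1e-9)
})

test_that("structures without amide protons error unless idealized", {
  p <- tempfile(fileext = ".pdb")
  lines <- readLines(tiny_pdb(p))
  writeLines(grep(" H  ", lines, invert = TRUE, value = TRUE), p)
  s <- read_structure(p)
  expect_error(extract_nh_vectors(s), "idealize")
  nh <- extract_nh_vectors(s, idealize = TRUE)
  # residue 1 has no preceding carbonyl; only residue 3 is constructible
  expect_equal(nh$residue_id, 3L)
  expect_equal(sqrt(nh$x^2 + nh$y^2 + nh$z^2), 1, tolerance = 1e-9)
  # ideal H lies along the bisector of C'(i-1)->N and CA->N directions
  u1 <- c(6.3 - 5.5, 3 - 2, 0); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(6.3 - 7.7, 0, 0); u2 <- u2 / sqrt(sum(u2^2))
  v <- (u1 + u2) / sqrt(sum((u1 + u2)^2))
  expect_equal(c(nh$x, nh$y, nh$z), v, tolerance = 1e-9)
})

test_that("superposition RMSD: identity, rigid motion, symmetry", {
  p <- tempfile(fileext = ".pdb")
  write_synthetic_structure(p, n_residues = 8, n_models = 2, perturb = 0.4)
  s <- read_structure(p)
  expect_equal(superpose_rmsd(s, s, "backbone"), 0, tolerance = 1e-9)

  # rigidly rotated + translated copy
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- relaxfit:::.model_xyz(s, 1)
  moved <- sweep(xyz %*% t(R), 2, c(5, -3, 11), "+")
  s2 <- s
  s2$pdb$xyz <- as.vector(t(moved))
  expect_equal(superpose_rmsd(s, s2), 0, tolerance = 1e-9)

  # symmetry between perturbed conformers
  r_ab <- superpose_rmsd(s, s, model_a = 1, model_b = 2)
  r_ba <- superpose_rmsd(s, s, model_a = 2, model_b = 1)
  expect_gt(r_ab, 0)
  expect_equal(r_ab, r_ba, tolerance = 1e-9)
  expect_equal(ensemble_rmsd(s), r_ab, tolerance = 1e-12)
})

test_that("Kabsch agrees with the brute-force superposition oracle", {
  set.seed(12)
  P <- matrix(rnorm(12, sd = 3), 4, 3)
  Q <- P + matrix(rnorm(12, sd = 0.5), 4, 3)
  expect_equal(relaxfit:::.kabsch_rmsd(P, Q), oracle_superpose_rmsd(P, Q),
               tolerance = 1e-4)
  # bio3d as a second, independent implementation
  fit <- bio3d::fit.xyz(as.vector(t(Q)), as.vector(t(P)),
                        fixed.inds = 1:12, mobile.inds = 1:12)
  rb <- sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - Q)^2)))
  expect_equal(relaxfit:::.kabsch_rmsd(P, Q), rb, tolerance = 1e-6)
})

test_that("value maps round-trip through the B column with sentinel and clamp", {
  p <- tempfile(fileext = ".pdb")
  tiny_pdb(p)
  s <- read_structure(p)
  out <- tempfile(fileext = ".pdb")
  write_value_map(s, c("1" = 0.9, "2" = 0.5), out)
  back <- read_value_map(out)
  expect_equal(unname(back[c("1", "2")]), c(0.9, 0.5), tolerance = 1e-2)
  expect_equal(unname(back["3"]), -1, tolerance = 1e-6)  # sentinel
  expect_match(readLines(out)[1], "SENTINEL")

  # complete map: no sentinel anywhere
  write_value_map(s, c("1" = 1, "2" = 2, "3" = 3), out)
  expect_false(any(read_value_map(out) == -1))

  # clamping to the fixed-width column
  expect_warning(write_value_map(s, c("1" = 5e4, "2" = 1, "3" = 1), out),
                 "clamped")
  expect_equal(unname(read_value_map(out)["1"]), 999.99, tolerance = 1e-6)
})
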