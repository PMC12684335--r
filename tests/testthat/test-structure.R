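fixture_pdb <- function() {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END")
  p <- tempfile(fileext = ".pdb")
  writeLines(lines, p)
  p
}

test_that("PDB fixtures parse to exact coordinates", {
  p <- fixture_pdb()
  s <- read_structure(p)
  expect_equal(nrow(s), 3)
  expect_equal(s$x, c(0, 1.458, 2.009))
  expect_equal(s$elety, c("N", "CA", "C"))
  unlink(p)
  expect_error(read_structure("/nonexistent.pdb"), "no such file")
})

test_that("altloc A is retained under the default policy", {
  lines <- c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "END")
  p <- tempfile(fileext = ".pdb")
  writeLines(lines, p)
  s <- read_structure(p)
  expect_equal(nrow(s), 1)
  expect_equal(s$x, 1.0)
  unlink(p)
})

test_that("structures round-trip through PDB at coordinate precision", {
  tp <- make_toy_structure_pair(20, 8:12, 5, seed = 2, methyl_at = 10)
  p <- tempfile(fileext = ".pdb")
  write_structure(tp$ref, p)
  back <- read_structure(p)
  expect_equal(nrow(back), nrow(tp$ref))
  expect_lt(max(abs(back$x - tp$ref$x)), 1e-3)
  expect_lt(max(abs(back$z - tp$ref$z)), 1e-3)
  expect_equal(back$elety[back$resno == 10 & back$elety == "CD1"], "CD1")
  unlink(p)
})

test_that("self-superposition is the identity", {
  tp <- make_toy_structure_pair(30, 10:15, 4, seed = 3)
  sup <- superpose(tp$ref, tp$ref)
  expect_equal(sup$rmsd_fit, 0, tolerance = 1e-10)
  expect_equal(sup$R, diag(3), tolerance = 1e-8)
  expect_equal(sup$t, c(0, 0, 0), tolerance = 1e-8)
})

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

test_that("a planted rigid transform is recovered exactly", {
  tp <- make_toy_structure_pair(40, 15:20, 0, seed = 4)
  R <- rot_z(37); tvec <- c(3, -2, 7)
  mob <- tp$ref
  xyz <- as.matrix(mob[, c("x", "y", "z")]) %*% t(R)
  mob$x <- xyz[, 1] + tvec[1]
  mob$y <- xyz[, 2] + tvec[2]
  mob$z <- xyz[, 3] + tvec[3]
  sup <- superpose(tp$ref, mob)
  expect_lt(sup$rmsd_fit, 1e-6)
  expect_equal(sup$R %*% R, diag(3), tolerance = 1e-6)
  expect_true(abs(det(sup$R) - 1) < 1e-8)
  expect_lt(max(abs(sup$R %*% t(sup$R) - diag(3))), 1e-8)
  # rmsd of any fit is invariant under rigid pre-transforms of the mobile
  tp2 <- make_toy_structure_pair(40, 15:20, 6, seed = 5)
  sup_a <- superpose(tp2$ref, tp2$mobile,
                     atom_selection(residues = c(1:14, 21:40)))
  mob2 <- tp2$mobile
  xyz2 <- as.matrix(mob2[, c("x", "y", "z")]) %*% t(rot_z(63))
  mob2$x <- xyz2[, 1] + 11; mob2$y <- xyz2[, 2] - 4; mob2$z <- xyz2[, 3]
  sup_b <- superpose(tp2$ref, mob2,
                     atom_selection(residues = c(1:14, 21:40)))
  expect_equal(sup_a$rmsd_fit, sup_b$rmsd_fit, tolerance = 1e-9)
})

test_that("planted loop shifts appear in deviations, rmsd and displacement", {
  loop <- 30:40
  tp <- make_toy_structure_pair(60, loop, 8, seed = 6,
                                methyl_at = 35, pair_at = 20)
  frame <- atom_selection(residues = setdiff(1:60, loop), atoms = "CA")
  sup <- superpose(tp$ref, tp$mobile, frame)
  expect_lt(sup$rmsd_fit, 1e-9)
  dev <- per_residue_ca_deviation(tp$ref, tp$mobile, sup)
  expect_equal(max(dev$deviation), 8, tolerance = 0.01)
  expect_true(dev$resno[which.max(dev$deviation)] %in% loop)
  expect_true(all(dev$deviation[!dev$resno %in% loop] < 1e-9))
  expect_equal(selection_rmsd(tp$ref, tp$mobile, sup,
                              atom_selection(residues = loop, atoms = "CA")),
               8, tolerance = 1e-6)
  expect_equal(atom_displacement_between_states(
    tp$ref, tp$mobile, sup, c(resno = 35, elety = "CD1")), 8,
    tolerance = 1e-6)
  # zero-displacement control
  tp0 <- make_toy_structure_pair(60, loop, 0, seed = 6)
  sup0 <- superpose(tp0$ref, tp0$mobile, frame)
  dev0 <- per_residue_ca_deviation(tp0$ref, tp0$mobile, sup0)
  expect_lt(max(dev0$deviation), 1e-9)
  # deviations are symmetric under swapping reference and mobile
  sup_rev <- superpose(tp$mobile, tp$ref, frame)
  dev_rev <- per_residue_ca_deviation(tp$mobile, tp$ref, sup_rev)
  expect_equal(dev_rev$deviation, dev$deviation, tolerance = 1e-6)
})

test_that("superposition agrees with the bio3d reference implementation", {
  tp <- make_toy_structure_pair(50, 20:28, 7, seed = 9)
  frame <- setdiff(1:50, 20:28)
  sel <- atom_selection(residues = frame, atoms = "CA")
  sup <- superpose(tp$ref, tp$mobile, sel)
  ref_xyz <- as.matrix(tp$ref[tp$ref$resno %in% frame, c("x", "y", "z")])
  mob_xyz <- as.matrix(tp$mobile[tp$mobile$resno %in% frame, c("x", "y", "z")])
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.numeric(t(ref_xyz)),
                   matrix(as.numeric(t(mob_xyz)), nrow = 1)))
  rmsd_bio3d <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) - ref_xyz)^2)))
  expect_equal(sup$rmsd_fit, rmsd_bio3d, tolerance = 1e-6)
})

test_that("atom distances and selections behave", {
  tp <- make_toy_structure_pair(30, 10:12, 3, seed = 7, methyl_at = 11,
                                pair_at = 20)
  expect_equal(atom_distance(tp$ref, c(resno = 5, elety = "CA"),
                             c(resno = 5, elety = "CA")), 0)
  d12 <- atom_distance(tp$ref, c(resno = 20, elety = "CG1"),
                       c(resno = 20, elety = "CG2"))
  expect_gt(d12, 0)
  expect_error(atom_distance(tp$ref, c(resno = 99, elety = "CA"),
                             c(resno = 1, elety = "CA")), "not found")
  expect_error(apply_selection(tp$ref, atom_selection(residues = 999)),
               "zero atoms")
  # the shipped barrel selection resolves to 58 residues
  sel <- barrel_selection()
  expect_equal(length(sel$residues), 58)
  expect_equal(sel$atoms, "CA")
  # loop definitions do not overlap the barrel frame
  expect_length(intersect(unlist(loop_definitions()), sel$residues), 0)
})
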