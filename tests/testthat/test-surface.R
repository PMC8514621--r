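test_that("an isolated atom samples a full probe-inflated sphere", {
  s <- toy_structure(matrix(c(0, 0, 0), 1), radius = 1.7)
  cl <- sample_sas(s, probe = 1.4, points_per_atom = 256)
  expect_equal(nrow(cl), 256)
  d <- sqrt(cl$x^2 + cl$y^2 + cl$z^2)
  expect_equal(d, rep(3.1, 256), tolerance = 1e-10)
  # closed-form area: 4 pi (3.1 A)^2 = 1.2076 nm^2
  sasa <- residue_sasa(s, probe = 1.4)
  expect_equal(unname(sasa), 4 * pi * 3.1^2 / 100, tolerance = 1e-10)
})

test_that("two-sphere SASA matches the analytic cap formula", {
  # two atoms, closed-form accessible area per sphere:
  # A_i = 2 pi R_i^2 (1 + cos(alpha_i)), cos(alpha_i) = (d^2 + R_i^2 - R_j^2) / (2 d R_i)
  r1 <- 1.7; r2 <- 1.4; probe <- 1.4; d <- 3.2
  R1 <- r1 + probe; R2 <- r2 + probe
  s <- toy_structure(rbind(c(0, 0, 0), c(d, 0, 0)),
                     radius = c(r1, r2), resnum = 1:2)
  sasa <- residue_sasa(s, probe = probe, points_per_atom = 2000)
  a1 <- 2 * pi * R1^2 * (1 + (d^2 + R1^2 - R2^2) / (2 * d * R1)) / 100
  a2 <- 2 * pi * R2^2 * (1 + (d^2 + R2^2 - R1^2) / (2 * d * R2)) / 100
  expect_equal(unname(sasa["A:1:"]), a1, tolerance = 0.02)
  expect_equal(unname(sasa["A:2:"]), a2, tolerance = 0.02)
  # each overlapping atom retains strictly fewer points than when isolated
  cl <- sample_sas(s, probe = probe, points_per_atom = 256)
  expect_lt(sum(cl$residue_key == "A:1:"), 256)
  expect_lt(sum(cl$residue_key == "A:2:"), 256)
  expect_lt(sum(sasa), (4 * pi * R1^2 + 4 * pi * R2^2) / 100)
})

test_that("every residue of a short helix-like chain reaches the surface", {
  t <- seq(0, 4 * pi / 1.6, length.out = 5)
  xyz <- cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * t / (2 * pi) * 5.4)
  s <- toy_structure(xyz, resnum = 1:5)
  cl <- sample_sas(s)
  expect_setequal(unique(cl$residue_key), zern3d:::make_residue_key("A", 1:5, ""))
})

test_that("a fully buried atom reports zero SASA", {
  shell <- zern3d:::fibonacci_sphere(60) * 3.4
  s <- toy_structure(rbind(c(0, 0, 0), shell), radius = c(1.7, rep(1.9, 60)),
                     resnum = 1:61)
  sasa <- residue_sasa(s)
  expect_equal(unname(sasa["A:1:"]), 0)
  # relative SASA of the buried residue is 0 too
  rs <- relative_sasa(s)
  expect_equal(unname(rs["A:1:"]), 0)
})

test_that("total SASA decreases as atoms are added around a fixed core", {
  core <- matrix(c(0, 0, 0), 1)
  s1 <- toy_structure(core)
  s2 <- toy_structure(rbind(core, c(3.4, 0, 0)), resnum = 1:2)
  s3 <- toy_structure(rbind(core, c(3.4, 0, 0), c(-3.4, 0, 0)), resnum = 1:3)
  a1 <- residue_sasa(s1)["A:1:"]
  a2 <- residue_sasa(s2)["A:1:"]
  a3 <- residue_sasa(s3)["A:1:"]
  expect_gt(a1, a2)
  expect_gt(a2, a3)
})

test_that("per-residue SASA is invariant under rigid motion", {
  tc <- toy_complex_cached()
  ag <- tc$antigen
  s1 <- residue_sasa(ag)
  R <- rand_rotation_seeded(11)
  atoms <- ag$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + 7.3; atoms$y <- xyz[, 2] - 2.1; atoms$z <- xyz[, 3] + 40
  s2 <- residue_sasa(zern3d:::new_structure(atoms))
  # the deterministic spiral is fixed in the lab frame, so individual
  # residues fluctuate by a few percent under rotation while the total
  # area is tightly conserved
  expect_equal(sum(s2), sum(s1), tolerance = 0.02)
  expect_equal(unname(s2[names(s1)]), unname(s1), tolerance = 0.15)
})

test_that("relative SASA scales by the reference table and flags unknowns", {
  s <- toy_structure(matrix(c(0, 0, 0), 1), resname = "ALA", radius = 1.7)
  sasa <- residue_sasa(s)
  rs <- relative_sasa(s)
  expect_equal(unname(rs), unname(sasa) / 1.29, tolerance = 1e-10)
  s_mse <- toy_structure(matrix(c(0, 0, 0), 1), resname = "MSE")
  expect_error(relative_sasa(s_mse), "MSE")
  rs2 <- relative_sasa(s_mse, unknown_res_ref = 200)
  expect_equal(unname(rs2), unname(residue_sasa(s_mse)) / 2, tolerance = 1e-10)
})

test_that("screened-Coulomb residue potentials follow sign and formula", {
  # all charges zero -> all es zero
  s0 <- toy_structure(rbind(c(0, 0, 0), c(6, 0, 0)), resnum = 1:2, charge = 0)
  cl0 <- assign_electrostatics(sample_sas(s0), s0)
  expect_true(all(cl0$es == 0))

  # single positive charge -> positive es everywhere
  s1 <- toy_structure(matrix(c(0, 0, 0), 1), charge = 1)
  cl1 <- assign_electrostatics(sample_sas(s1), s1)
  expect_true(all(cl1$es > 0))

  # +1 at residue A, -1 at residue B -> es(A) > 0 > es(B), and the values
  # match a direct evaluation of the screened Coulomb sum
  xyz <- rbind(c(0, 0, 0), c(8, 0, 0))
  s2 <- toy_structure(xyz, resnum = 1:2, charge = c(1, -1))
  cl2 <- assign_electrostatics(sample_sas(s2), s2, epsilon = 80, screen = 8)
  esA <- unique(cl2$es[cl2$residue_key == "A:1:"])
  esB <- unique(cl2$es[cl2$residue_key == "A:2:"])
  expect_length(esA, 1)  # per-residue constancy is exact
  expect_length(esB, 1)
  expect_gt(esA, 0)
  expect_lt(esB, 0)
  # direct evaluation: self term at the 1 A distance floor plus the
  # opposite charge at 8 A
  expected <- exp(-1 / 8) / (80 * 1) - exp(-8 / 8) / (80 * 8)
  expect_equal(esA, expected, tolerance = 1e-12)
  expect_equal(esB, -esA, tolerance = 1e-12)

  # per-point mode attaches user values verbatim and checks the length
  vals <- seq_len(nrow(cl2))
  cl3 <- assign_electrostatics(cl2, mode = "per_point_file", values = vals)
  expect_equal(cl3$es, as.numeric(vals))
  expect_error(assign_electrostatics(cl2, mode = "per_point_file",
                                     values = 1:3), "per point")
})
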