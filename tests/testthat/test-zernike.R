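test_that("descriptor length follows the closed form", {
  expect_identical(descriptor_length(20), 121L)
  expect_identical(descriptor_length(10), 36L)
  expect_identical(descriptor_length(0), 1L)
  expect_error(descriptor_length(-1), "non-negative")
})

test_that("moments vanish for zero fields and odd orders of symmetric fields", {
  z <- array(0, c(16, 16, 16))
  m0 <- zernike_moments(z, 6)
  expect_true(all(Mod(m0$values) == 0))
  expect_true(all(invariants(m0) == 0))

  # centrally symmetric field: f(-r) = f(r) kills all odd-n moments
  d <- 32
  cc <- -1 + (seq_len(d) - 0.5) * (2 / d)
  r2 <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
  g <- exp(-4 * r2) + outer(outer(cc^2, cc * 0, "+"), cc * 0, "+")
  ms <- zernike_moments(g, 7)
  odd <- ms$index$n %% 2 == 1
  expect_lt(max(Mod(ms$values[odd])), 1e-12 * max(Mod(ms$values)))
})

test_that("fast moments agree with the Riemann-sum oracle", {
  set.seed(123)
  g <- array(runif(16^3), c(16, 16, 16))
  mf <- zernike_moments(g, 6)
  mo <- moments_oracle(g, 6)
  expect_equal(mf$index, mo$index)
  rel <- Mod(mf$values - mo$values) / Mod(mo$values)
  expect_lt(max(rel), 1e-8)
})

test_that("moments obey conjugate symmetry for real fields", {
  set.seed(5)
  g <- array(runif(16^3), c(16, 16, 16))
  m <- zernike_moments(g, 8)
  idx <- m$index
  for (i in which(idx$m > 0)) {
    j <- which(idx$n == idx$n[i] & idx$l == idx$l[i] & idx$m == -idx$m[i])
    expect_lt(Mod(m$values[j] - (-1)^idx$m[i] * Conj(m$values[i])), 1e-10)
  }
})

test_that("invariants are the Euclidean norm over m", {
  # single nonzero moment C_220 = 3 + 4i -> D_22 = 5
  idx <- zern3d:::zernike_index_table(2)
  vals <- complex(nrow(idx))
  vals[idx$n == 2 & idx$l == 2 & idx$m == 0] <- 3 + 4i
  m <- structure(list(index = idx, values = vals, order_max = 2L,
                      channel = "shape"), class = "zernike_moments")
  d <- invariants(m)
  expect_equal(unname(d["D2.2"]), 5)
  expect_equal(unname(d[c("D0.0", "D1.1", "D2.0")]), c(0, 0, 0))

  # random moment set vs direct summation
  set.seed(9)
  vals2 <- complex(real = rnorm(nrow(idx)), imaginary = rnorm(nrow(idx)))
  m2 <- structure(list(index = idx, values = vals2, order_max = 2L,
                       channel = "shape"), class = "zernike_moments")
  d2 <- invariants(m2)
  for (k in seq_along(d2)) {
    nl <- attr(d2, "nl")[k, ]
    sel <- idx$n == nl$n & idx$l == nl$l
    expect_equal(unname(d2[k]), sqrt(sum(Mod(vals2[sel])^2)), tolerance = 1e-12)
  }
})

test_that("expansion order beyond the stability bound is refused", {
  g <- array(0, c(8, 8, 8))
  expect_error(zernike_moments(g, 47), "stability")
})

test_that("a full sphere shell concentrates energy in l = 0", {
  sph <- make_patch("sphere_cap", cap_angle = 180, n_points = 2000, seed = 4)
  d <- shape_desc(sph, dim = 48, order_max = 10)
  nl <- attr(d, "nl")
  e_l0 <- sum(d[nl$l == 0]^2)
  e_rest <- sum(d[nl$l > 0]^2)
  expect_lt(e_rest / e_l0, 0.01)
})

test_that("neutral patches give identically zero electrostatic descriptors", {
  p <- make_patch("bumpy", seed = 10, charge_pattern = "neutral")
  tr <- describe_patch(p, order_max = 8, dim = 32)
  expect_true(all(tr$elec_pos == 0))
  expect_true(all(tr$elec_neg == 0))
  expect_gt(sum(tr$shape), 0)
})

test_that("describe_patch is deterministic", {
  p <- make_patch("bumpy", seed = 12, charge_pattern = "dipolar")
  t1 <- describe_patch(p, order_max = 10, dim = 32)
  t2 <- describe_patch(p, order_max = 10, dim = 32)
  expect_identical(t1$shape, t2$shape)
  expect_identical(t1$elec_pos, t2$elec_pos)
})

test_that("descriptors are invariant under rotation, translation and scaling", {
  for (seed in c(31, 32, 33)) {
    p <- make_patch("bumpy", seed = seed, bump_amplitude = 1.2)
    xyz <- as.matrix(p$points[, c("x", "y", "z")])
    d0 <- invariants(zernike_moments(
      voxelize_shape(fit_to_unit_sphere(xyz)$points, 48), 12))
    # translation and scaling: exact (normalisation removes them)
    d_ts <- invariants(zernike_moments(
      voxelize_shape(fit_to_unit_sphere(sweep(xyz, 2, c(12, -7, 3)) * 3.1)$points,
                     48), 12))
    expect_equal(as.numeric(d_ts), as.numeric(d0), tolerance = 1e-10)
    # rotation: voxelization noise only
    R <- rand_rotation_seeded(seed + 100)
    d_rot <- invariants(zernike_moments(
      voxelize_shape(fit_to_unit_sphere(xyz %*% t(R))$points, 48), 12))
    rel <- sqrt(sum((d_rot - d0)^2)) / sqrt(sum(d0^2))
    expect_lt(rel, 0.05)
  }
})

test_that("cumulative descriptor energy is non-decreasing in order", {
  p <- make_patch("bumpy", seed = 14)
  g <- voxelize_shape(fit_to_unit_sphere(p)$points, 32)
  d <- invariants(zernike_moments(g, 12))
  nl <- attr(d, "nl")
  energy <- sapply(0:12, function(o) sum(d[nl$n <= o]^2))
  expect_true(all(diff(energy) >= 0))
})

test_that("truncation equals direct computation at the lower order", {
  p <- make_patch("bumpy", seed = 15)
  g <- voxelize_shape(fit_to_unit_sphere(p)$points, 32)
  d12 <- invariants(zernike_moments(g, 12))
  d5 <- invariants(zernike_moments(g, 5))
  tr <- truncate_descriptor(d12, 5)
  expect_equal(as.numeric(tr), as.numeric(d5), tolerance = 1e-10)
  expect_identical(length(tr), descriptor_length(5))
  expect_error(truncate_descriptor(d5, 12), "higher order")
})
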