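test_that("CDR patch collects exactly the Chothia-range residues", {
  tc <- toy_complex_cached()
  ab_cloud <- sample_sas(tc$antibody)
  cdr <- cdr_patch(tc$antibody, ab_cloud)
  got <- patch_residues(cdr)
  a <- tc$antibody$atoms
  rng <- chothia_cdr_ranges()
  expected <- character(0)
  for (r in seq_len(nrow(rng))) {
    ch <- if (rng$role[r] == "heavy") "H" else "L"
    in_r <- a$chain == ch & a$resnum >= rng$start[r] & a$resnum <= rng$end[r]
    expected <- c(expected, zern3d:::residue_keys(tc$antibody)[in_r])
  }
  # a CDR residue buried at the chain-chain interface has no surface
  # points and cannot appear in the patch
  expected <- intersect(unique(expected), unique(ab_cloud$residue_key))
  expect_setequal(got, expected)
})

test_that("single-chain antibodies warn and non-Chothia numbering errors", {
  tc <- toy_complex_cached()
  a <- tc$antibody$atoms
  nano <- assign_chain_roles(
    zern3d:::new_structure(a[a$chain == "H", , drop = FALSE]), heavy = "H")
  cl <- sample_sas(nano)
  expect_warning(p <- cdr_patch(nano, cl), "heavy chain")
  expect_true(all(grepl("^H:", patch_residues(p))))

  # renumber everything outside the CDR ranges -> error
  a2 <- a
  a2$resnum <- seq_len(nrow(a2)) + 500
  bad <- assign_chain_roles(zern3d:::new_structure(a2), heavy = "H", light = "L")
  cl2 <- sample_sas(bad)
  expect_error(cdr_patch(bad, cl2), "Chothia")
})

test_that("native epitope matches a brute-force distance scan", {
  tc <- toy_complex_cached()
  cl <- toy_antigen_cloud_cached()
  ne <- native_epitope(tc$complex, cl, cutoff = 6)
  # O(N^2) oracle: all-pairs atom distances
  ab <- tc$complex$atoms[tc$complex$atoms$chain %in% c("H", "L"), ]
  ag <- tc$complex$atoms[tc$complex$atoms$chain == "A", ]
  keys <- zern3d:::make_residue_key(ag$chain, ag$resnum, ag$icode)
  hits <- character(0)
  for (k in unique(keys)) {
    sub <- ag[keys == k, , drop = FALSE]
    dmin <- Inf
    for (i in seq_len(nrow(sub)))
      dmin <- min(dmin, sqrt((sub$x[i] - ab$x)^2 + (sub$y[i] - ab$y)^2 +
                               (sub$z[i] - ab$z)^2))
    if (dmin < 6) hits <- c(hits, k)
  }
  expect_setequal(patch_residues(ne), hits)
  expect_false(is.na(ne$pivot))

  # cutoff monotonicity: larger cutoff gives a superset
  ne15 <- native_epitope(tc$complex, cl, cutoff = 15, kind = "epitope_elec")
  expect_true(all(patch_residues(ne) %in% patch_residues(ne15)))
  expect_equal(ne15$kind, "epitope_elec")
})

test_that("separated chains give the no-contact error", {
  xyz_ab <- rbind(c(0, 0, 0), c(4, 0, 0))
  xyz_ag <- rbind(c(100, 0, 0), c(104, 0, 0))
  atoms <- rbind(toy_structure(xyz_ab, chain = "H", resnum = 1:2)$atoms,
                 toy_structure(xyz_ag, chain = "A", resnum = 1:2)$atoms)
  s <- assign_chain_roles(zern3d:::new_structure(atoms),
                          heavy = "H", antigen = "A")
  cl <- sample_sas(zern3d:::structure_subset(s, "antigen"))
  expect_error(native_epitope(s, cl, cutoff = 6), "no contact")
})

test_that("pivot residue is the mean-distance minimiser", {
  # three collinear equally spaced residues -> middle one
  s3 <- toy_structure(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)), resnum = 1:3)
  cl3 <- sample_sas(s3)
  p3 <- zern3d:::new_patch(as.data.frame(cl3), kind = "epitope_geom")
  expect_equal(pivot_residue(p3, s3), "A:2:")

  # single-residue patch -> that residue
  p1 <- zern3d:::new_patch(as.data.frame(cl3[cl3$residue_key == "A:3:", ]),
                           kind = "epitope_geom")
  expect_equal(pivot_residue(p1, s3), "A:3:")

  # random 8-residue fixture vs exhaustive computation
  xyz <- zern3d:::with_seed(5, matrix(runif(24, 0, 15), 8))
  s8 <- toy_structure(xyz, resnum = 1:8)
  cl8 <- sample_sas(s8)
  p8 <- zern3d:::new_patch(as.data.frame(cl8), kind = "epitope_geom")
  D <- as.matrix(dist(xyz))
  expected <- zern3d:::make_residue_key("A", which.min(rowMeans(D)), "")
  expect_equal(pivot_residue(p8, s8), expected)
})

test_that("decoys satisfy the pivot-window, SASA-growth and overlap rules", {
  tc <- toy_complex_cached()
  cl <- toy_antigen_cloud_cached()
  ne <- native_epitope(tc$complex, cl, cutoff = 6)
  sasa <- residue_sasa(tc$antigen)
  native_sasa <- sum(sasa[patch_residues(ne)])
  pars <- decoy_params()
  lo <- pars$pivot_sasa_mean - 0.5 * pars$pivot_sasa_sd
  hi <- pars$pivot_sasa_mean + 0.5 * pars$pivot_sasa_sd
  dec <- generate_decoys(tc$antigen, cl, ne, pars, n_decoys = 10, seed = 7)
  expect_length(dec, 10)
  for (d in dec) {
    expect_true(sasa[d$pivot] >= lo && sasa[d$pivot] <= hi)
    dsasa <- sum(sasa[patch_residues(d)])
    expect_gte(dsasa, native_sasa)
    expect_lte(abs(dsasa - native_sasa) / native_sasa, 0.25)
    expect_lte(d$overlap_with_native, pars$max_overlap)
    expect_equal(d$overlap_with_native,
                 length(intersect(patch_residues(d), patch_residues(ne))) /
                   length(patch_residues(ne)))
  }
  # determinism under the seed
  dec2 <- generate_decoys(tc$antigen, cl, ne, pars, n_decoys = 10, seed = 7)
  expect_identical(lapply(dec2, patch_residues), lapply(dec, patch_residues))
})

test_that("decoy generation errors are informative", {
  tc <- toy_complex_cached()
  cl <- toy_antigen_cloud_cached()
  ne <- native_epitope(tc$complex, cl, cutoff = 6)
  # impossible pivot window
  pars <- decoy_params(pivot_sasa_mean = 50, pivot_sasa_sd = 0.01)
  expect_error(generate_decoys(tc$antigen, cl, ne, pars, n_decoys = 2, seed = 1),
               "pivot window")
  # native covering (almost) the whole surface with zero overlap tolerance
  ne_all <- native_epitope(tc$complex, cl, cutoff = 1e6, kind = "epitope_elec")
  pars0 <- decoy_params(max_overlap = 1e-9)
  expect_error(generate_decoys(tc$antigen, cl, ne_all, pars0,
                               n_decoys = 2, seed = 1, max_attempts = 20),
               "budget|SASA")
})

test_that("a unique in-window residue is every decoy's pivot", {
  tc <- toy_complex_cached()
  cl <- toy_antigen_cloud_cached()
  ne <- native_epitope(tc$complex, cl, cutoff = 6)
  sasa <- residue_sasa(tc$antigen)
  # centre a tiny window on one exposed residue far from the epitope;
  # sampled SASA is quantised (retained-point counts), so insist on a
  # residue whose value is unique in the structure
  uniq <- !(duplicated(sasa) | duplicated(sasa, fromLast = TRUE))
  cand <- names(sasa)[uniq & sasa > 0.4]
  far <- setdiff(cand, patch_residues(ne))[1]
  expect_false(is.na(far))
  pars <- decoy_params(pivot_sasa_mean = unname(sasa[far]), pivot_sasa_sd = 1e-6)
  dec <- generate_decoys(tc$antigen, cl, ne, pars, n_decoys = 3, seed = 2)
  expect_true(all(vapply(dec, `[[`, character(1), "pivot") == far))
})

test_that("electrostatic extension adds residues by pivot distance", {
  tc <- toy_complex_cached()
  cl <- toy_antigen_cloud_cached()
  ne <- native_epitope(tc$complex, cl, cutoff = 6)
  dec <- generate_decoys(tc$antigen, cl, ne, n_decoys = 1, seed = 3)[[1]]
  # radius 0 keeps the geometric decoy unchanged
  e0 <- electrostatic_extension(dec, tc$antigen, cl, radius = 0)
  expect_setequal(patch_residues(e0), patch_residues(dec))
  expect_equal(e0$kind, "decoy_elec")
  # huge radius includes every antigen residue with surface points
  eall <- electrostatic_extension(dec, tc$antigen, cl, radius = 1e6)
  expect_setequal(patch_residues(eall), unique(cl$residue_key))
  # finite radius matches a direct distance scan over representative atoms
  e15 <- electrostatic_extension(dec, tc$antigen, cl, radius = 15)
  reps <- zern3d:::representative_atoms(tc$antigen)
  d <- sqrt(rowSums(sweep(reps, 2, reps[dec$pivot, ])^2))
  expected <- union(patch_residues(dec),
                    intersect(rownames(reps)[d <= 15], unique(cl$residue_key)))
  expect_setequal(patch_residues(e15), expected)
})

test_that("paratope shells are nested, ordered and centred correctly", {
  tc <- toy_complex_cached()
  ab_cloud <- sample_sas(tc$antibody)
  cdr <- cdr_patch(tc$antibody, ab_cloud)
  b <- interface_centerpoint(tc$complex)

  # centerpoint is the centroid of the 10 antibody atoms nearest the antigen
  ab <- tc$complex$atoms[tc$complex$atoms$chain %in% c("H", "L"), ]
  ag <- tc$complex$atoms[tc$complex$atoms$chain == "A", ]
  dmin <- sapply(seq_len(nrow(ab)), function(i)
    min(sqrt((ab$x[i] - ag$x)^2 + (ab$y[i] - ag$y)^2 + (ab$z[i] - ag$z)^2)))
  sel <- order(dmin)[1:10]
  expect_equal(b, colMeans(as.matrix(ab[sel, c("x", "y", "z")])),
               tolerance = 1e-12)

  expect_error(shell_patch(cdr, b, 0), "fraction")
  expect_error(shell_patch(cdr, b, 1.2), "fraction")

  full <- shell_patch(cdr, b, 1)
  expect_equal(nrow(full$points), nrow(cdr$points))

  s02 <- shell_patch(cdr, b, 0.2)
  expect_equal(nrow(s02$points), ceiling(0.2 * nrow(cdr$points)))
  # every retained point is closer to b than every excluded point
  d_all <- sqrt((cdr$points$x - b[1])^2 + (cdr$points$y - b[2])^2 +
                  (cdr$points$z - b[3])^2)
  d_in <- sqrt((s02$points$x - b[1])^2 + (s02$points$y - b[2])^2 +
                 (s02$points$z - b[3])^2)
  expect_lte(max(d_in), min(d_all[rank(d_all) > length(d_in)]))

  # monotone nesting over a fraction ladder
  fracs <- c(0.1, 0.3, 0.6, 1)
  shells <- lapply(fracs, function(f) shell_patch(cdr, b, f))
  for (i in 1:3) {
    a_pts <- do.call(paste, shells[[i]]$points[c("x", "y", "z")])
    b_pts <- do.call(paste, shells[[i + 1]]$points[c("x", "y", "z")])
    expect_true(all(a_pts %in% b_pts))
  }
})
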