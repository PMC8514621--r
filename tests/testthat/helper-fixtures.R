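# Shared helpers: tiny structures and deterministic rotations built in code.

rand_rotation_seeded <- function(seed) {
  zern3d:::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# data frame of single-atom residues -> zern_structure
toy_structure <- function(xyz, chain = "A", resnum = seq_len(nrow(xyz)),
                          radius = 1.9, charge = 0, resname = "ALA",
                          name = "CA") {
  atoms <- data.frame(serial = seq_len(nrow(xyz)), name = name,
                      element = "C", resname = resname, chain = chain,
                      resnum = resnum, icode = "",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      charge = charge, radius = radius, het = FALSE,
                      stringsAsFactors = FALSE)
  zern3d:::new_structure(atoms)
}

# inline PQR text fixture
write_pqr_text <- function(lines, path = tempfile(fileext = ".pqr")) {
  writeLines(lines, path)
  path
}

# shape-only descriptor at modest resolution for fast tests
shape_desc <- function(patch, dim = 48, order_max = 12) {
  describe_patch(patch, order_max = order_max, dim = dim,
                 channels = "shape")$shape
}

# cached toy complex shared across test files (built once per run)
toy_complex_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_complex(seed = 1)
    cache
  }
})

toy_antigen_cloud_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tc <- toy_complex_cached()
      cache <<- assign_electrostatics(sample_sas(tc$antigen), tc$antigen)
    }
    cache
  }
})
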